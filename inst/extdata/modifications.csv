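name,formula,mod_class
hexosyl,C6H10O5,glycosyl
deoxyhexosyl,C6H10O4,glycosyl
coumaroyl,C9H6O2,acyl
malonyl,C3H2O3,acyl
acetyl,C2H2O,acyl
methyl,CH2,methyl
H2O,H2O,small_loss
CO,CO,small_loss
CH3,CH3,small_loss
OCH3,CH3O,small_loss
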
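name,formula,compound_class
quercetin,C15H10O7,flavonol
kaempferol,C15H10O6,flavonol
isorhamnetin,C16H12O7,flavonol
myricetin,C15H10O8,flavonol
catechin,C15H14O6,flavanol
naringenin,C15H12O5,other
cyanidin,C15H11O6,anthocyanidin
oleanolic acid,C30H48O3,triterpenoid
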
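BEGIN IONS
TITLE=quercetin_coumaroyl_diglucoside
PEPMASS=773.192000
RTINSECONDS=326.760000
303.049600 1000.000000
465.102700 450.000000
611.139000 620.000000
END IONS

BEGIN IONS
TITLE=oleanolic_acid
PEPMASS=457.366900
RTINSECONDS=644.220000
95.086000 240.000000
109.101600 210.000000
119.085800 300.000000
189.163800 180.000000
203.179400 260.000000
393.350800 520.000000
457.366900 1000.000000
END IONS
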
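"solvent","side_ratio"
"DEF",0.78
"DMAC",0.70
"ace",0.62
"NMP",0.54
"DEAC",0.46
"DMF",0.38
"MeCN",0.30
"DMSO",0.22
"MEF",0.10
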
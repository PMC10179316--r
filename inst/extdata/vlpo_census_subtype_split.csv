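genotype_tag,nonREMS/REMS-max,nonREMS-max,REMS-active,wake-max,wake/REMS-max,state-indifferent
VGAT,96,24,32,116,16,19
UNID,33,6,19,22,15,11
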
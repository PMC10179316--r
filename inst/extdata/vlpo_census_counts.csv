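animal_id,genotype_tag,nrem_sleep_active,REMS-active,wake-max,wake/REMS-max,state-indifferent
VGAT7,VGAT,7,5,7,3,1
VGAT8,VGAT,11,0,8,0,2
VGAT11,VGAT,21,13,32,3,2
VGAT12,VGAT,15,3,6,1,1
VGAT14,VGAT,21,1,22,5,3
VGAT15,VGAT,13,9,29,2,6
VGAT16,VGAT,32,1,12,2,4
UNID17,UNID,22,8,7,2,7
UNID1,UNID,5,6,13,3,2
UNID24,UNID,12,5,2,10,2
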
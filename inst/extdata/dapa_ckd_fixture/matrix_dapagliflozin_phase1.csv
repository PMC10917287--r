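state,ckd1,ckd2,ckd3a,ckd3b,ckd4,ckd5,dialysis,tx_init,tx_maint,dead
ckd1,0.99354,0.00366,0,0,0,0,0,0,0,0.0028
ckd2,0,0.99243,0.00427,0,0,0,0,0,0,0.0033
ckd3a,0,0,0.99001,0.00549,0,0,0,0,0,0.0045
ckd3b,0,0,0,0.98679,0.00671,0,0,0,0,0.0065
ckd4,0,0,0,0,0.98157,0.00793,0,0,0,0.0105
ckd5,0,0,0,0,0,0.9642,0.0183,0,0,0.0175
dialysis,0,0,0,0,0,0,0.968,0.0045,0,0.0275
tx_init,0,0,0,0,0,0,0,0,0.9775,0.0225
tx_maint,0,0,0,0,0,0,0.002,0,0.9917,0.0063
dead,0,0,0,0,0,0,0,0,0,1
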
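state,ckd1,ckd2,ckd3a,ckd3b,ckd4,ckd5,dialysis,tx_init,tx_maint,dead
ckd1,0.9912,0.006,0,0,0,0,0,0,0,0.0028
ckd2,0,0.9897,0.007,0,0,0,0,0,0,0.0033
ckd3a,0,0,0.9865,0.009,0,0,0,0,0,0.0045
ckd3b,0,0,0,0.9825,0.011,0,0,0,0,0.0065
ckd4,0,0,0,0,0.9765,0.013,0,0,0,0.0105
ckd5,0,0,0,0,0,0.9525,0.03,0,0,0.0175
dialysis,0,0,0,0,0,0,0.968,0.0045,0,0.0275
tx_init,0,0,0,0,0,0,0,0,0.9775,0.0225
tx_maint,0,0,0,0,0,0,0.002,0,0.9917,0.0063
dead,0,0,0,0,0,0,0,0,0,1
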
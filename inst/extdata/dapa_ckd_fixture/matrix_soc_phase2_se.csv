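state,ckd1,ckd2,ckd3a,ckd3b,ckd4,ckd5,dialysis,tx_init,tx_maint,dead
ckd1,0.00208836778370095,0.0017268468374468,0,0,0,0,0,0,0,0.0011815582931028
ckd2,0,0.00225764368313514,0.00186426929385215,0,0,0,0,0,0,0.00128240204304266
ckd3a,0,0,0.00258047960658479,0.00211175282644537,0,0,0,0,0,0.00149662119455793
ckd3b,0,0,0,0.00293204280323463,0.00233227356885937,0,0,0,0,0.00179690706493129
ckd4,0,0,0,0,0.0033873108803297,0.00253288373203351,0,0,0,0.00227922684259378
ckd5,0,0,0,0,0,0.00475624589355933,0.00381444622455213,0,0,0.00293204280323463
dialysis,0,0,0,0,0,0,0.00393547964039963,0.00149662119455793,0,0.00365675744341896
tx_init,0,0,0,0,0,0,0,0,0.00331615364541512,0.00331615364541512
tx_maint,0,0,0,0,0,0,0.000998999499499374,0,0.00202868307036855,0.00176922440634307
dead,0,0,0,0,0,0,0,0,0,0
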
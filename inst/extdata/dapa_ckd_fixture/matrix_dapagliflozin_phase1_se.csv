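state,ckd1,ckd2,ckd3a,ckd3b,ckd4,ckd5,dialysis,tx_init,tx_maint,dead
ckd1,0.001791405649204,0.00135029707842386,0,0,0,0,0,0,0,0.0011815582931028
ckd2,0,0.00193812991050651,0.00145804099736599,0,0,0,0,0,0,0.00128240204304266
ckd3a,0,0,0.00222375806912532,0.00165224996595551,0,0,0,0,0,0.00149662119455793
ckd3b,0,0,0,0.00255298804345026,0.00182551032590889,0,0,0,0,0.00179690706493129
ckd4,0,0,0,0,0.00300751850368372,0.00198331983048625,0,0,0,0.00227922684259378
ckd5,0,0,0,0,0,0.00415441692659752,0.00299709108970682,0,0,0.00293204280323463
dialysis,0,0,0,0,0,0,0.00393547964039963,0.00149662119455793,0,0.00365675744341896
tx_init,0,0,0,0,0,0,0,0,0.00331615364541512,0.00331615364541512
tx_maint,0,0,0,0,0,0,0.000998999499499374,0,0.00202868307036855,0.00176922440634307
dead,0,0,0,0,0,0,0,0,0,0
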
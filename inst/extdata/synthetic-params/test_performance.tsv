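modality	measure	value
fit	sens_nonadv_adenoma	0.10000000000000001
fit	sens_adv_adenoma	0.25
fit	sens_preclin_crc	0.75
fit	specificity	0.95999999999999996
colonoscopy	sens_nonadv_adenoma	0.75
colonoscopy	sens_adv_adenoma	0.94999999999999996
colonoscopy	sens_preclin_crc	0.97999999999999998
colonoscopy	specificity	1
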
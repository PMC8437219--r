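mode	years_since_dx	value
symptom	0	0.16
symptom	1	0.12460812529142479
symptom	2	0.097044905554021343
symptom	3	0.075578648438562351
symptom	4	0.058860710587430774
symptom	5	0.045840767497630414
symptom	6	0.035700825623748773
symptom	7	0.027803830952071222
symptom	8	0.021653645317858034
symptom	9	0.016863875929898294
symptom	10	0.013133599779823809
symptom	11	0.010228457793073211
symptom	12	0.007965930938858232
symptom	13	0.0062038732530755218
screen	0	0.072000000000000008
screen	1	0.056073656381141153
screen	2	0.043670207499309603
screen	3	0.03401039179735306
screen	4	0.026487319764343847
screen	5	0.020628345373933685
screen	6	0.016065371530686948
screen	7	0.012511723928432051
screen	8	0.0097441403930361159
screen	9	0.0075887441684542329
screen	10	0.005910119900920714
screen	11	0.0046028060068829448
screen	12	0.0035846689224862047
screen	13	0.002791742963883985
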
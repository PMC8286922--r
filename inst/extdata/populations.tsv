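name	size	bg_rate_hz	bg_weight_pA
CTX_RS	800	600	220
CTX_FS	200	400	150
D1_MSN	200	350	300
D2_MSN	200	2600	200
GPe	100	300	150
GPi	100	100	100
STN	100	300	200
TC	100	600	250
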
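source	target	sign	p	weight_mean	weight_sd	w_max_abs	delay_ms	plastic	da_mod	stdp_profile
CTX_RS	CTX_RS	1	0.05	80	20	200	2	TRUE	none	cortical
CTX_RS	CTX_FS	1	0.10	40	10	150	1	TRUE	none	cortical
CTX_FS	CTX_RS	-1	0.10	120	25	400	1	FALSE	none	none
CTX_FS	CTX_FS	-1	0.10	100	20	300	1	FALSE	none	none
CTX_RS	D1_MSN	1	0.10	55	14	160	10	TRUE	d1	corticostriatal
CTX_RS	D2_MSN	1	0.10	60	15	300	10	FALSE	d2	none
CTX_RS	STN	1	0.05	250	60	600	3	FALSE	none	none
CTX_RS	TC	1	0.05	80	20	250	8	FALSE	none	none
D1_MSN	GPi	-1	0.33	60	15	200	7	FALSE	none	none
D2_MSN	GPe	-1	0.33	120	30	400	7	FALSE	none	none
GPe	STN	-1	0.33	40	10	300	6	FALSE	none	none
STN	GPe	1	0.33	60	15	300	6	FALSE	none	none
STN	GPi	1	0.5	200	50	500	3	FALSE	none	none
GPe	GPi	-1	0.33	20	5	150	3	FALSE	none	none
GPe	GPe	-1	0.10	40	10	150	1	FALSE	none	none
GPi	TC	-1	0.33	350	80	900	5	FALSE	none	none
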
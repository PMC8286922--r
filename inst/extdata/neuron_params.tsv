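cell_type	capacitance_pF	quad_gain	resting_mV	threshold_mV	peak_mV	reset_mV	recovery_rate	recovery_sens	after_spike_pA	bias_pA	slow2_rate	slow2_sens	slow2_jump_pA	da_d_scale	da_hyper_pA
D1_MSN	50	1	-80	-50	40	-55	0.02	-9	176	0	0	0	0	0.8	0
D2_MSN	50	1	-80	-50	40	-55	0.02	-9	150	0	0	0	0	0	240
GPe	40	1	-55	-45	25	-50	0.2	2	20	90	0	0	0	0	0
GPi	40	1	-55	-45	25	-50	0.2	2	20	85	0	0	0	0	0
STN	60	0.7	-60	-45	30	-52	0.01	8	30	120	0	0	0	0	0
CTX_RS	100	0.7	-60	-40	35	-50	0.03	-2	100	0	0	0	0	0	0
CTX_FS	20	1	-55	-40	25	-45	0.2	2	10	0	0	0	0	0	0
TC	70	1	-63	-52	35	-53	0.02	-3	2	0	0.003	17	15	0	0
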
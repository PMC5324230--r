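category	case_mean	case_se	control_mean	control_se
rand36_physical_functioning	40.6	3.9	95.3	1.4
rand36_role_physical	7.7	3.1	96.9	2.2
rand36_pain	55.9	3.6	90.0	1.8
rand36_general_health	25.2	2.3	81.8	2.4
rand36_energy	16.9	2.3	71.7	2.5
rand36_social_functioning	33.0	3.7	91.9	2.4
rand36_role_emotional	71.4	5.9	84.5	5.4
rand36_emotion	73.2	2.4	80.6	2.6
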
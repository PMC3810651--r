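site	n	tr_s	n_volumes	field_t	mean_age	age_min	age_max
Aachen-a	47	2.2	250	3	36.5	19	59
Aachen-b	28	2.2	270	3	63.4	55	72
Juelich-a	51	2.2	250	3	28.3	18	59
Juelich-b	100	2.2	300	3	45.1	21	71
ICBM	41	2.0	256	1.5	40.6	19	78
NKI	132	2.5	260	3	42.3	18	85
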
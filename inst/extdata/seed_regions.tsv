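name	x_mm	y_mm	z_mm	radius_mm	system	max_distance_mm
L 7A	-29	-66	57	5	visual-attention	6.9
R 7A	32	-66	56	5	visual-attention	7.1
L OP4	-44	-17	12	5	sensorimotor	7.3
R OP4	50	-14	11	5	sensorimotor	7.4
L dPMC	-41	2	50	5	visual-attention	5.7
R dPMC	35	6	60	5	visual-attention	7.8
SMAr	2	0	56	5	task-general	NA
L AIC	-32	20	6	5	task-general	NA
R AIC	36	18	4	5	task-general	NA
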
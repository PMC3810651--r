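region_i	region_j	mean_r_young	mean_r_old	rho_s	sig_young	sig_old
L 7A	L OP4	-0.164	-0.087	0.15	TRUE	TRUE
L 7A	SMAr	-0.111	-0.004	0.22	TRUE	FALSE
R 7A	L OP4	-0.175	-0.093	0.20	TRUE	TRUE
R 7A	R OP4	-0.151	-0.071	0.16	TRUE	TRUE
R 7A	SMAr	-0.077	0.019	0.20	TRUE	FALSE
L AIC	R AIC	0.515	0.445	-0.18	TRUE	TRUE
L dPMC	SMAr	-0.022	0.067	0.19	FALSE	TRUE
R dPMC	SMAr	-0.041	0.042	0.16	FALSE	FALSE
L OP4	R OP4	0.472	0.322	-0.24	TRUE	TRUE
L OP4	SMAr	0.107	0.025	-0.16	TRUE	FALSE
R OP4	SMAr	0.154	0.078	-0.17	TRUE	TRUE
SMAr	L AIC	0.289	0.200	-0.14	TRUE	TRUE
SMAr	R AIC	0.314	0.212	-0.16	TRUE	TRUE
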
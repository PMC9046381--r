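family	edges	positive_edges	negative_edges	vertices	connectance	average_degree	average_path_length	diameter	clustering_coefficient	clusters	centralization_degree	centralization_betweenness	centralization_closeness
Peltoperlidae	244	169	75	84	0.070	5.810	4.318	9.509	0.727	5	0.075	0.111	0.018
Nemouridae	30	30	0	41	0.037	1.463	1.171	2.457	0.750	17	0.038	0.004	0.003
Styloperlidae	179	167	12	90	0.045	3.978	2.337	6.010	0.892	15	0.045	0.025	0.004
Leuctridae	77	76	1	71	0.031	2.169	2.043	5.175	0.664	19	0.069	0.009	0.003
Perlodidae	215	143	72	92	0.051	4.674	3.752	10.084	0.490	8	0.124	0.126	0.015
Capniidae	832	548	284	91	0.203	18.286	1.000	1.000	1.000	6	0.097	0	0.003
Perlidae	80	80	0	72	0.031	2.222	1.255	2.534	0.844	23	0.053	0.002	0.001
Choloroperlidae	549	356	193	101	0.109	10.871	2.731	7.628	0.629	7	0.161	0.060	0.014
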
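# SYNTHETIC stand-in for the MOFF 20x20 contact-strength matrix eps_ij
# (kJ/mol).  Values are generated from the deterministic recipe
#   eps_ij = -3.0 * lambda_KR_i * lambda_KR_j + 0.8
# and are NOT the published maximum-entropy-optimized values.
code	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-0.799	0.8	-0.146	-0.028	-0.503	-0.326	-0.205	-0.621	-0.326	-1.331	-1.331	-0.326	-1.035	-1.39	-1.39	-0.503	-0.68	-1.272	-1.094	-1.153
R	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8
N	-0.146	0.8	0.24	0.31	0.029	0.134	0.205	-0.041	0.134	-0.461	-0.461	0.134	-0.286	-0.496	-0.496	0.029	-0.076	-0.426	-0.321	-0.356
D	-0.028	0.8	0.31	0.371	0.125	0.217	0.279	0.064	0.217	-0.303	-0.303	0.217	-0.15	-0.334	-0.334	0.125	0.033	-0.273	-0.181	-0.212
C	-0.503	0.8	0.029	0.125	-0.262	-0.117	-0.019	-0.358	-0.117	-0.937	-0.937	-0.117	-0.696	-0.985	-0.985	-0.262	-0.407	-0.889	-0.744	-0.792
Q	-0.326	0.8	0.134	0.217	-0.117	0.007	0.092	-0.201	0.007	-0.7	-0.7	0.007	-0.492	-0.742	-0.742	-0.117	-0.242	-0.659	-0.534	-0.575
E	-0.205	0.8	0.205	0.279	-0.019	0.092	0.168	-0.094	0.092	-0.54	-0.54	0.092	-0.354	-0.577	-0.577	-0.019	-0.131	-0.503	-0.391	-0.428
G	-0.621	0.8	-0.041	0.064	-0.358	-0.201	-0.094	-0.464	-0.201	-1.094	-1.094	-0.201	-0.832	-1.147	-1.147	-0.358	-0.516	-1.042	-0.884	-0.937
H	-0.326	0.8	0.134	0.217	-0.117	0.007	0.092	-0.201	0.007	-0.7	-0.7	0.007	-0.492	-0.742	-0.742	-0.117	-0.242	-0.659	-0.534	-0.575
I	-1.331	0.8	-0.461	-0.303	-0.937	-0.7	-0.54	-1.094	-0.7	-2.04	-2.04	-0.7	-1.646	-2.119	-2.119	-0.937	-1.173	-1.961	-1.725	-1.804
L	-1.331	0.8	-0.461	-0.303	-0.937	-0.7	-0.54	-1.094	-0.7	-2.04	-2.04	-0.7	-1.646	-2.119	-2.119	-0.937	-1.173	-1.961	-1.725	-1.804
K	-0.326	0.8	0.134	0.217	-0.117	0.007	0.092	-0.201	0.007	-0.7	-0.7	0.007	-0.492	-0.742	-0.742	-0.117	-0.242	-0.659	-0.534	-0.575
M	-1.035	0.8	-0.286	-0.15	-0.696	-0.492	-0.354	-0.832	-0.492	-1.646	-1.646	-0.492	-1.307	-1.714	-1.714	-0.696	-0.899	-1.578	-1.375	-1.442
F	-1.39	0.8	-0.496	-0.334	-0.985	-0.742	-0.577	-1.147	-0.742	-2.119	-2.119	-0.742	-1.714	-2.2	-2.2	-0.985	-1.228	-2.038	-1.795	-1.876
P	-1.39	0.8	-0.496	-0.334	-0.985	-0.742	-0.577	-1.147	-0.742	-2.119	-2.119	-0.742	-1.714	-2.2	-2.2	-0.985	-1.228	-2.038	-1.795	-1.876
S	-0.503	0.8	0.029	0.125	-0.262	-0.117	-0.019	-0.358	-0.117	-0.937	-0.937	-0.117	-0.696	-0.985	-0.985	-0.262	-0.407	-0.889	-0.744	-0.792
T	-0.68	0.8	-0.076	0.033	-0.407	-0.242	-0.131	-0.516	-0.242	-1.173	-1.173	-0.242	-0.899	-1.228	-1.228	-0.407	-0.571	-1.118	-0.954	-1.009
W	-1.272	0.8	-0.426	-0.273	-0.889	-0.659	-0.503	-1.042	-0.659	-1.961	-1.961	-0.659	-1.578	-2.038	-2.038	-0.889	-1.118	-1.885	-1.655	-1.731
Y	-1.094	0.8	-0.321	-0.181	-0.744	-0.534	-0.391	-0.884	-0.534	-1.725	-1.725	-0.534	-1.375	-1.795	-1.795	-0.744	-0.954	-1.655	-1.445	-1.515
V	-1.153	0.8	-0.356	-0.212	-0.792	-0.575	-0.428	-0.937	-0.575	-1.804	-1.804	-0.575	-1.442	-1.876	-1.876	-0.792	-1.009	-1.731	-1.515	-1.587
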
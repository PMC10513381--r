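# SYNTHETIC stand-in for the Mpipi 24x24 Wang-Frenkel epsilon matrix (kJ/mol)
# covering the 20 amino acids plus RNA nucleotides rA/rC/rG/rU.
# Generated from a documented hydropathy-based recipe with cation-pi and
# pi-pi bonuses; NOT the published PMF-calibrated values.
code	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V	rA	rC	rG	rU
A	1.526	1.477	1.51	1.126	1.574	1.477	0.2	1.494	1.694	1.635	1.65	1.256	1.605	1.75	1.688	1.51	1.51	1.908	1.818	1.593	1.821	1.821	1.821	1.821
R	1.477	1.429	1.461	1.092	1.523	1.429	0.2	1.445	1.638	1.582	1.596	1.217	1.553	2.492	1.633	1.461	1.461	2.645	2.558	1.541	2.56	2.56	2.56	2.56
N	1.51	1.461	1.494	1.115	1.557	1.461	0.2	1.478	1.676	1.618	1.632	1.243	1.588	1.731	1.67	1.494	1.494	1.887	1.798	1.576	1.801	1.801	1.801	1.801
D	1.126	1.092	1.115	0.847	1.16	1.092	0.2	1.104	1.243	1.202	1.213	0.938	1.181	1.283	1.239	1.115	1.115	1.393	1.33	1.173	1.332	1.332	1.332	1.332
C	1.574	1.523	1.557	1.16	1.624	1.523	0.2	1.54	1.748	1.687	1.702	1.294	1.656	1.806	1.742	1.557	1.557	1.97	1.876	1.643	1.879	1.879	1.879	1.879
Q	1.477	1.429	1.461	1.092	1.523	1.429	0.2	1.445	1.638	1.582	1.596	1.217	1.553	1.692	1.633	1.461	1.461	1.845	1.758	1.541	1.76	1.76	1.76	1.76
E	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2
G	1.494	1.445	1.478	1.104	1.54	1.445	0.2	1.462	1.657	1.6	1.614	1.23	1.57	1.712	1.651	1.478	1.478	1.866	1.778	1.558	1.781	1.781	1.781	1.781
H	1.694	1.638	1.676	1.243	1.748	1.638	0.2	1.657	1.882	1.816	1.833	1.39	1.782	1.946	1.876	1.676	1.676	2.124	2.022	1.769	2.025	2.025	2.025	2.025
I	1.635	1.582	1.618	1.202	1.687	1.582	0.2	1.6	1.816	1.753	1.769	1.343	1.72	1.877	1.81	1.618	1.618	2.048	1.951	1.707	1.954	1.954	1.954	1.954
L	1.65	1.596	1.632	1.213	1.702	1.596	0.2	1.614	1.833	1.769	1.785	1.355	1.736	1.895	1.827	1.632	1.632	2.068	1.969	1.723	1.972	1.972	1.972	1.972
K	1.256	1.217	1.243	0.938	1.294	1.217	0.2	1.23	1.39	1.343	1.355	1.041	1.319	2.235	1.385	1.243	1.243	2.36	2.288	1.309	2.291	2.291	2.291	2.291
M	1.605	1.553	1.588	1.181	1.656	1.553	0.2	1.57	1.782	1.72	1.736	1.319	1.688	1.842	1.776	1.588	1.588	2.009	1.914	1.675	1.917	1.917	1.917	1.917
F	1.75	2.492	1.731	1.283	1.806	1.692	0.2	1.712	1.946	1.877	1.895	2.235	1.842	2.612	1.939	1.731	1.731	2.796	2.691	1.828	2.694	2.694	2.694	2.694
P	1.688	1.633	1.67	1.239	1.742	1.633	0.2	1.651	1.876	1.81	1.827	1.385	1.776	1.939	1.869	1.67	1.67	2.116	2.015	1.762	2.018	2.018	2.018	2.018
S	1.51	1.461	1.494	1.115	1.557	1.461	0.2	1.478	1.676	1.618	1.632	1.243	1.588	1.731	1.67	1.494	1.494	1.887	1.798	1.576	1.801	1.801	1.801	1.801
T	1.51	1.461	1.494	1.115	1.557	1.461	0.2	1.478	1.676	1.618	1.632	1.243	1.588	1.731	1.67	1.494	1.494	1.887	1.798	1.576	1.801	1.801	1.801	1.801
W	1.908	2.645	1.887	1.393	1.97	1.845	0.2	1.866	2.124	2.048	2.068	2.36	2.009	2.796	2.116	1.887	1.887	3	2.884	1.994	2.887	2.887	2.887	2.887
Y	1.818	2.558	1.798	1.33	1.876	1.758	0.2	1.778	2.022	1.951	1.969	2.288	1.914	2.691	2.015	1.798	1.798	2.884	2.774	1.899	2.777	2.777	2.777	2.777
V	1.593	1.541	1.576	1.173	1.643	1.541	0.2	1.558	1.769	1.707	1.723	1.309	1.675	1.828	1.762	1.576	1.576	1.994	1.899	1.662	1.902	1.902	1.902	1.902
rA	1.821	2.56	1.801	1.332	1.879	1.76	0.2	1.781	2.025	1.954	1.972	2.291	1.917	2.694	2.018	1.801	1.801	2.887	2.777	1.902	2.78	2.78	2.78	2.78
rC	1.821	2.56	1.801	1.332	1.879	1.76	0.2	1.781	2.025	1.954	1.972	2.291	1.917	2.694	2.018	1.801	1.801	2.887	2.777	1.902	2.78	2.78	2.78	2.78
rG	1.821	2.56	1.801	1.332	1.879	1.76	0.2	1.781	2.025	1.954	1.972	2.291	1.917	2.694	2.018	1.801	1.801	2.887	2.777	1.902	2.78	2.78	2.78	2.78
rU	1.821	2.56	1.801	1.332	1.879	1.76	0.2	1.781	2.025	1.954	1.972	2.291	1.917	2.694	2.018	1.801	1.801	2.887	2.777	1.902	2.78	2.78	2.78	2.78
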
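snp	gene	coded_allele	population	caf	beta	se	p	generalized
rs1748195	ANGPTL3	C	EA	0.66	0.03	0.01	1.93E-07	N
rs1748195	ANGPTL3	C	AA	0.35	0.01	0.01	0.19	N
rs1748195	ANGPTL3	C	AI	0.61	0.16	0.07	2.44E-02	N
rs1748195	ANGPTL3	C	MAH	0.60	0.04	0.01	1.17E-02	N
rs1260326	GCKR	T	EA	0.42	0.05	0.01	6.44E-13	N
rs1260326	GCKR	T	AA	0.16	0.05	0.02	9.98E-04	N
rs1260326	GCKR	T	AI	0.28	0.15	0.09	8.52E-02	N
rs1260326	GCKR	T	MAH	0.33	0.06	0.02	1.97E-04	N
rs780094	GCKR	A	EA	0.40	0.06	0.01	1.69E-32	Y
rs780094	GCKR	A	AA	0.18	0.02	0.01	2.91E-02	Y
rs780094	GCKR	A	AI	0.25	0.04	0.01	3.23E-03	Y
rs780094	GCKR	A	MAH	0.33	0.06	0.02	1.13E-03	Y
rs17145738	MLXIPL	T	EA	0.12	-0.07	0.01	5.71E-24	Y
rs17145738	MLXIPL	T	AA	0.09	-0.03	0.01	2.53E-02	Y
rs17145738	MLXIPL	T	AI	0.08	-0.07	0.02	2.30E-04	Y
rs17145738	MLXIPL	T	MAH	0.07	-0.09	0.03	7.40E-04	Y
rs328	LPL	C	EA	0.90	0.09	0.01	4.16E-30	Y
rs328	LPL	C	AA	0.93	0.08	0.02	2.62E-08	Y
rs328	LPL	C	AI	0.97	0.09	0.03	4.83E-03	Y
rs328	LPL	C	MAH	0.93	0.09	0.03	6.31E-04	Y
rs2197089	LPL	T	EA	0.55	-0.03	0.01	4.97E-15	N
rs2197089	LPL	T	AA	0.78	-0.01	0.01	7.45E-02	N
rs2197089	LPL	T	AI	0.41	-0.05	0.01	2.57E-06	N
rs2197089	LPL	T	MAH	0.48	-0.05	0.01	4.01E-04	N
rs2954029	TRIB1	A	EA	0.54	0.05	0.01	1.13E-04	N
rs2954029	TRIB1	A	AA	0.68	-0.01	0.02	0.46	N
rs2954029	TRIB1	A	MAH	0.62	0.06	0.02	9.28E-04	N
rs174547	FADS1	T	EA	0.66	-0.03	0.01	3.82E-10	Y
rs174547	FADS1	T	AA	0.91	-0.05	0.01	3.73E-04	Y
rs174547	FADS1	T	AI	0.21	-0.06	0.02	1.10E-04	Y
rs174547	FADS1	T	MAH	0.39	-0.05	0.02	1.51E-03	Y
rs28927680	APOA1/C3/A4/A5	C	EA	0.93	-0.12	0.01	2.88E-38	N
rs28927680	APOA1/C3/A4/A5	C	AA	0.84	0.00	0.01	0.95	N
rs28927680	APOA1/C3/A4/A5	C	AI	0.83	-0.13	0.01	6.33E-19	N
rs28927680	APOA1/C3/A4/A5	C	MAH	0.86	-0.08	0.02	2.15E-05	N
rs964184	APOA1/C3/A4/A5	G	EA	0.86	-0.14	0.01	1.91E-59	Y
rs964184	APOA1/C3/A4/A5	G	AA	0.80	-0.02	0.01	4.87E-02	Y
rs964184	APOA1/C3/A4/A5	G	AI	0.78	-0.17	0.07	1.43E-02	Y
rs964184	APOA1/C3/A4/A5	G	MAH	0.72	-0.14	0.02	1.04E-19	Y
rs3135506	APOA1/C3/A4/A5	C	EA	0.06	0.13	0.01	2.59E-33	Y
rs3135506	APOA1/C3/A4/A5	C	AA	0.06	0.11	0.02	2.06E-10	Y
rs3135506	APOA1/C3/A4/A5	C	AI	0.17	0.13	0.01	4.28E-20	Y
rs3135506	APOA1/C3/A4/A5	C	MAH	0.14	0.13	0.02	3.08E-08	Y
rs4775041	LIPC	C	EA	0.29	0.01	0.01	3.15E-02	N
rs4775041	LIPC	C	AA	0.14	0.03	0.01	4.29E-03	N
rs4775041	LIPC	C	AI	0.21	0.02	0.01	5.15E-02	N
rs4775041	LIPC	C	MAH	0.18	0.01	0.02	0.58	N
rs16996148	CILP2/PBX4/NCAN	T	EA	0.08	-0.04	0.01	3.91E-05	N
rs16996148	CILP2/PBX4/NCAN	T	AA	0.15	0.00	0.01	0.77	N
rs16996148	CILP2/PBX4/NCAN	T	AI	0.04	-0.07	0.03	8.86E-03	N
rs16996148	CILP2/PBX4/NCAN	T	MAH	0.06	-0.06	0.03	2.69E-02	N
rs7679	PLTP	T	EA	0.82	-0.02	0.01	2.84E-02	N
rs7679	PLTP	T	AA	0.96	-0.01	0.02	0.61	N
rs7679	PLTP	T	AI	0.94	-2.0E-03	0.02	0.93	N
rs7679	PLTP	T	MAH	0.89	-0.03	0.03	0.31	N
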
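sample	two_c_pg	cv_percent	ploidy_label
KDA (Israel 3)	0.56	13.53	Diploid
KDA (Israel 2)	0.58	11.31	Diploid
KDA (Tunisia 2)	0.54	11.57	Diploid
KDA (Spain 1)	0.58	12.39	Diploid
KDE (Tunisia 1)	1.16	9.37	Tetraploid
KDE (Madagascar 2)	1.08	10.16	Tetraploid
KDE (Madagascar 1)	1.05	9.15	Tetraploid
KDE (Israel 1)	1.06	12.99	Tetraploid
KDE (Catalonia 1)	1.10	8.92	Tetraploid
KH (Greece)	1.05	7.71	Tetraploid
KH (France 2)	1.08	10.80	Tetraploid
KH (Italy 3)	1.04	18.00	Tetraploid
KH (Morocco)	1.08	10.96	Tetraploid
KH ('Palamos')	1.14	9.43	Tetraploid
KH (Italy 2)	1.06	8.81	Tetraploid
KH (Spain 2)	1.07	6.51	Tetraploid
KH (Italy 4)	1.14	10.67	Tetraploid
KH ('Jaws of Life')	1.12	5.89	Tetraploid
KH (Italy 7)	1.04	6.94	Tetraploid
KH (Portugal)	1.10	6.58	Tetraploid
KH (Italy 8)	1.13	4.69	Tetraploid
KH (Malta)	1.13	5.63	Tetraploid
KH (France 1)	1.13	9.20	Tetraploid
KH (Italy 5)	1.13	5.63	Tetraploid
KH (Spain 3)	1.17	8.43	Tetraploid
KH (Italy 6)	1.17	8.03	Tetraploid
KH (Catalonia 3)	1.15	8.49	Tetraploid
KH (France 3)	1.12	4.88	Tetraploid
KH (Spain 4)	1.18	8.32	Tetraploid
KH (Tunisia 2)	1.10	8.24	Tetraploid
KH ('Pink Butterflies')	0.85	8.15	Triploid
KH (Catalonia 2)	0.79	11.28	Triploid
KH (Italy 1)	0.83	11.94	Triploid
KH ('Hybrida')	0.84	7.42	Triploid
KH ('Linear leafed')	0.84	5.41	Triploid
KH (Madagascar 3)	0.59	12.31	Diploid
KH (Madagascar 4)	0.58	6.30	Diploid
KH ('Parsel Tongue')	0.53	9.60	Diploid
Kalanchoe ('RS574')	0.80	5.61	Triploid
Kalanchoe laetivirens	1.59	3.91	Hexaploid
Kalanchoe sanctula	0.57	6.67	Diploid
Kalanchoe x descoingsii	1.30	3.74	Pentaploid
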
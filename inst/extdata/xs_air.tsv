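# material: air
# density_g_cm3: 0.001205
# electrons_per_gram: 3.006192e+23
# provenance: standard-reference (NIST Hubbell & Seltzer style) photon mass
#   attenuation / mass energy-absorption grids, transcribed as package data;
#   dry air, sea level; no-coherent column = Klein-Nishina + photoelectric estimate.
# columns: energy_MeV mu_rho_total mu_rho_no_coherent muen_rho  (cm^2/g)
energy_MeV	mu_rho_total	mu_rho_no_coherent	muen_rho
0.001	3606	3606	3599
0.0015	1191	1191	1188
0.002	527.9	527.9	526.2
0.003	162.5	162.5	161.4
0.004	77.88	77.88	77
0.005	40.27	40.27	39.31
0.006	23.41	23.41	22.7
0.008	9.921	9.921	9.446
0.01	5.12	5.12	4.742
0.015	1.614	1.53308	1.334
0.02	0.7779	0.723379	0.5389
0.03	0.3538	0.325568	0.1537
0.04	0.2485	0.230365	0.06833
0.05	0.208	0.195365	0.04098
0.06	0.1875	0.178199	0.03041
0.08	0.1662	0.160798	0.02407
0.1	0.1541	0.150629	0.02325
0.15	0.1356	0.134003	0.02496
0.2	0.1233	0.122451	0.02672
0.3	0.1067	0.106322	0.02872
0.4	0.09549	0.0952273	0.02949
0.5	0.08712	0.0869426	0.02966
0.6	0.08055	0.0804229	0.02953
0.8	0.07074	0.0706368	0.02882
1	0.06358	0.0634949	0.02789
1.25	0.05687	0.0567637	0.02666
1.5	0.05175	0.0515797	0.02547
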
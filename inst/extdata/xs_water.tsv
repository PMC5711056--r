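# material: water
# density_g_cm3: 1
# electrons_per_gram: 3.342830e+23
# provenance: standard-reference (NIST Hubbell & Seltzer style) photon mass
#   attenuation / mass energy-absorption grids, transcribed as package data;
#   no-coherent column = analytic Klein-Nishina + photoelectric estimate.
# columns: energy_MeV mu_rho_total mu_rho_no_coherent muen_rho  (cm^2/g)
energy_MeV	mu_rho_total	mu_rho_no_coherent	muen_rho
0.001	4078	4076.22	4065
0.0015	1376	1374.22	1372
0.002	617.3	615.221	615.2
0.003	192.9	191.72	191.7
0.004	82.78	81.91	81.91
0.005	42.58	41.88	41.88
0.006	24.64	24.05	24.05
0.008	10.37	9.915	9.915
0.01	5.329	4.9541	4.944
0.015	1.673	1.49025	1.374
0.02	0.8096	0.718583	0.5503
0.03	0.3756	0.338732	0.1557
0.04	0.2683	0.247162	0.06947
0.05	0.2269	0.213002	0.04223
0.06	0.2059	0.195891	0.0319
0.08	0.1837	0.17796	0.02597
0.1	0.1707	0.167097	0.02546
0.15	0.1505	0.148906	0.02764
0.2	0.137	0.136122	0.02967
0.3	0.1186	0.118217	0.03192
0.4	0.1061	0.105887	0.03279
0.5	0.09687	0.0966764	0.03299
0.6	0.08956	0.0894275	0.03284
0.8	0.07865	0.0785463	0.03206
1	0.07072	0.0706049	0.03103
1.25	0.06323	0.06312	0.02965
1.5	0.05754	0.0573556	0.02833
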
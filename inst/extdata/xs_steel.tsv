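# material: steel
# density_g_cm3: 8
# electrons_per_gram: 2.804451e+23
# provenance: standard-reference (NIST Hubbell & Seltzer style) photon mass
#   attenuation / mass energy-absorption grids, transcribed as package data;
#   type-304 stainless approximated by elemental-iron coefficients at 8.0 g/cm3; no-coherent column kept equal to total (coherent lumped into absorption).
# columns: energy_MeV mu_rho_total mu_rho_no_coherent muen_rho  (cm^2/g)
energy_MeV	mu_rho_total	mu_rho_no_coherent	muen_rho
0.001	9085	9085	9052
0.0015	3399	3399	3388
0.002	1626	1626	1589
0.003	557.6	557.6	548.9
0.004	256.7	256.7	252.6
0.005	139.8	139.8	136.9
0.006	84.84	84.84	82.53
0.008	305.6	305.6	295.2
0.01	170.6	170.6	136.9
0.015	57.08	57.08	48.96
0.02	25.68	25.68	22.6
0.03	8.176	8.176	7.251
0.04	3.629	3.629	3.155
0.05	1.958	1.958	1.638
0.06	1.205	1.205	0.9555
0.08	0.5952	0.5952	0.4104
0.1	0.3717	0.3717	0.2177
0.15	0.1964	0.1964	0.07961
0.2	0.146	0.146	0.04825
0.3	0.1099	0.1099	0.03361
0.4	0.094	0.094	0.03039
0.5	0.08414	0.08414	0.02914
0.6	0.07704	0.07704	0.02836
0.8	0.06699	0.06699	0.02714
1	0.05995	0.05995	0.02603
1.25	0.0535	0.0535	0.02472
1.5	0.04883	0.04883	0.0236
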
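# material: iridium
# density_g_cm3: 22.42
# electrons_per_gram: 2.412403e+23
# provenance: approximate source-metal coefficients for source self-absorption:
#   analytic Klein-Nishina Compton plus a photoelectric term scaled from the
#   standard lead reference grid; coherent scattering lumped into absorption.
#   muen_rho is a placeholder (kerma is always scored in water).
# columns: energy_MeV mu_rho_total mu_rho_no_coherent muen_rho  (cm^2/g)
energy_MeV	mu_rho_total	mu_rho_no_coherent	muen_rho
0.001	4231.54	4231.54	3385.23
0.0015	1913.62	1913.62	1530.89
0.002	1043.79	1043.79	835.032
0.003	1596.06	1596.06	1276.85
0.004	1016.18	1016.18	812.94
0.005	593.362	593.362	474.69
0.006	379.6	379.6	303.68
0.008	185.898	185.898	148.718
0.01	106.223	106.223	84.9785
0.015	87.8655	87.8655	70.2924
0.02	68.3709	68.3709	54.6967
0.03	23.6157	23.6157	18.8925
0.04	11.0226	11.0226	8.81809
0.05	6.13735	6.13735	4.90988
0.06	3.81073	3.81073	3.04858
0.08	1.76536	1.76536	1.41229
0.1	4.37461	4.37461	3.49969
0.15	1.56891	1.56891	1.25513
0.2	0.784339	0.784339	0.627471
0.3	0.328916	0.328916	0.263133
0.4	0.198221	0.198221	0.158576
0.5	0.136356	0.136356	0.109085
0.6	0.1092	0.1092	0.0873601
0.8	0.0802345	0.0802345	0.0641876
1	0.0659769	0.0659769	0.0527815
1.25	0.0552968	0.0552968	0.0442375
1.5	0.0487006	0.0487006	0.0389605
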
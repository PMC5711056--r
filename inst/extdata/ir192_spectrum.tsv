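# Ir-192 photon emission spectrum (gamma lines plus K x-rays above 60 keV),
# transcribed from standard radioactive-decay tables; intensity in photons/decay.
# columns: energy_MeV intensity
energy_MeV	intensity
0.06149	0.012
0.063	0.0205
0.06512	0.0263
0.06683	0.0453
0.0711	0.0061
0.07341	0.0117
0.07553	0.008
0.13634	0.00199
0.20131	0.00473
0.20579	0.0334
0.28327	0.00266
0.29596	0.2871
0.30846	0.297
0.31651	0.8286
0.37449	0.00727
0.41647	0.0067
0.42052	0.00069
0.46807	0.4784
0.48458	0.03189
0.48906	0.00438
0.58858	0.04522
0.59349	0.00042
0.60441	0.08216
0.61246	0.0534
0.88454	0.00292
1.06148	0.00053
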
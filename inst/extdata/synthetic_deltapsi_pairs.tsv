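event	rmats_delta_psi	rtpcr_delta_psi
synth01	0.714	0.715
synth02	-0.279	-0.399
synth03	0.599	0.626
synth04	0.425	0.429
synth05	0.334	0.42
synth06	0.126	0.102
synth07	-0.324	-0.34
synth08	0.735	0.786
synth09	0.399	0.312
synth10	-0.173	-0.112
synth11	-0.736	-0.797
synth12	0.451	0.441
synth13	-0.254	-0.303
synth14	0.285	0.272
synth15	-0.277	-0.225
synth16	0.568	0.488
synth17	-0.153	-0.139
synth18	-0.592	-0.599
synth19	-0.82	-0.76
synth20	-0.273	-0.169
synth21	0.596	0.636
synth22	0.159	0.321
synth23	0.261	0.43
synth24	0.641	0.642
synth25	0.778	0.717
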
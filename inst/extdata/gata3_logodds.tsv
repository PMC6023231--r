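0.14	-4.16	1.03	-4.16	0.58	-0.36
0.17	-2.31	-4.16	-4.16	-2.31	-1.32
-1.06	1.64	-2.32	-0.85	-1.06	1.12
0.12	-4.16	-2.64	1.18	0.07	-0.77
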
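na0	k0	cl0	l0	B0	kv	na	k	l	cl	alpha	beta	gamma	pna	pk
140	5.8	121	5	48.2	1.032	37	158	0.0001	63	0	0.039	1.5	0.00349	0.0229
pl	pcl	inc	ikc	ilc	inkcc	ilkcc	kp	hp
0.00349	0.00426	0.00003	0.0	0.00018	0.0	0.0	0.0002	500
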
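collection	Na	Ho	Nei	PIC
full	3.7143	0.2382	0.4600	0.4085
core	3.5000	0.2351	0.5356	0.4753
random1	3.3929	0.2333	0.4436	0.3932
random2	3.3214	0.2374	0.4672	0.4154
random3	3.4286	0.2399	0.4524	0.4018
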
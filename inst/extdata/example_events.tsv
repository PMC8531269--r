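onset	duration	amplitude	condition
12.4	0.1	1	spike
55.1	0.1	1	spike
88.73	0.1	1.5	spike
130.2	0.1	1	spike
176.85	0.1	1	spike
221.4	0.1	0.8	spike
263.0	0.1	1	spike
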
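onset_sample	answer	vigilance	block
15541	MW	4	1
28873	MW	3	1
41495	MB	4	1
56479	ON	3	1
70964	MB	3	1
91495	MB	2	2
108231	MW	4	2
118953	MW	2	2
132325	ON	4	2
142859	ON	4	2
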
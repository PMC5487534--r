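name	c_start	c_end	n_tl_max
trpL	1	162	0
trpE	163	1725	4
trpD	1726	3321	4
trpC	3322	4680	5
trpB	4726	5919	10
trpA	5920	6726	10
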
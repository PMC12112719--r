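id	kd_uscale_nM	kd_labscale_nM
Exp-1	2.5	5.4
Exp-2	8.6	19.4
Exp-3	8.7	26.4
Exp-4	5.9	17.1
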
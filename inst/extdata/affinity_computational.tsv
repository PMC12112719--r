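id	kd_nM	status
Comp-1	NA	not_expressed
Comp-2	2061	measured
Comp-3	NA	not_expressed
Comp-4	NA	no_binding
Comp-5	NA	no_binding
Comp-6	10000	measured
Comp-7	462	measured
Comp-8	5381	measured
Comp-9	29.8	measured
Comp-10	1488	measured
Comp-11	63.2	measured
Comp-12	NA	no_binding
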
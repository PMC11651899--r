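fixture	asv_a	asv_b	rho
tri_iso	n1	n2	0.9
tri_iso	n1	n3	0.8
tri_iso	n2	n3	0.85
doubletons	n1	n2	0.9
doubletons	n3	n4	0.7
path5	n1	n2	0.9
path5	n2	n3	0.4
path5	n3	n4	0.9
path5	n4	n5	0.8
twotri	n1	n2	0.9
twotri	n1	n3	0.9
twotri	n2	n3	0.9
twotri	n4	n5	0.9
twotri	n4	n6	0.9
twotri	n5	n6	0.9
twotri	n3	n4	0.2
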
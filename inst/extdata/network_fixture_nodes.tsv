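fixture	node
tri_iso	n1
tri_iso	n2
tri_iso	n3
tri_iso	n4
doubletons	n1
doubletons	n2
doubletons	n3
doubletons	n4
path5	n1
path5	n2
path5	n3
path5	n4
path5	n5
twotri	n1
twotri	n2
twotri	n3
twotri	n4
twotri	n5
twotri	n6
edgeless	n1
edgeless	n2
edgeless	n3
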
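taxon_id	kingdom	phylum	genus
A1	Bacteria	Firmicutes	GenusA
A2	Bacteria	Firmicutes	GenusA
A3	Bacteria	Firmicutes	GenusA
A4	Bacteria	Firmicutes	GenusA
B1	Bacteria	Firmicutes	GenusB
B2	Bacteria	Firmicutes	GenusB
C1	Bacteria	Firmicutes	GenusC
C2	Bacteria	Firmicutes	GenusC
C3	Bacteria	Firmicutes	GenusC
C4	Bacteria	Firmicutes	GenusC
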
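#source: SYNTHETIC placeholder for the van der Waals contact propensities derived from 41 RNA-protein complexes; replace with the published table for production use.
A	0.22
C	0.18
G	0.29
U	0.20
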
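# TEIL octamer PFM -- SYNTHETIC reconstruction from the consensus AYGWAYCT
# (Y = C/T, W = A/T): 20 pseudo-aligned sites, degenerate columns split evenly.
# Rows in order A C G T; columns are motif positions 1..8.
20  0  0 10 20  0  0  0
 0 10  0  0  0 10 20  0
 0  0 20  0  0  0  0  0
 0 10  0 10  0 10  0 20
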
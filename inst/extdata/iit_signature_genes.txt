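# IIT (IFN/IL12-induced T cell) signature gene panel.
# The full signature comprises 22 genes; the six published members are
# pre-filled below. Replace/extend this list with the complete panel from
# the study's supplementary gene list before scoring real cohorts.
GZMA
GZMB
KLRG1
CD7
P2RX7
CCR5
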
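# Synthetic exclusion panel (illustrative azoospermia-associated genes) for the
# secondary-findings screen. Stand-in for curated clinical-validity gene lists.
TEX11
TEX14
SYCP3
MEIOB
STAG3
TERB1
M1AP
FANCM
DMRT1
NR5A1
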
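# Synthetic 24-gene piRNA-pathway screening panel: the 14 genes of the packaged
# cohort table plus ten canonical piRNA-biogenesis factors. Stand-in for a
# curated panel of human orthologues of murine piRNA-pathway genes.
DDX4
FKBP6
GPAT2
GTSF1
HENMT1
MAEL
MOV10L1
PIWIL1
PIWIL2
PLD6
PNLDC1
TDRD1
TDRD9
TDRD12
PIWIL3
PIWIL4
ASZ1
TDRKH
TDRD5
TDRD6
TDRD7
RNF17
EXD1
SPOCD1
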
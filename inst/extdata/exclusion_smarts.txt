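# Default exclusion patterns: reactive or otherwise undesired moieties.
# One SMARTS per line, optional name after whitespace. Edit freely or pass
# your own file to read_smarts_file().
[N+](=O)[O-]            nitro
C(=O)Cl                 acyl_chloride
C(=O)Br                 acyl_bromide
S(=O)(=O)Cl             sulfonyl_chloride
[C;!R](=[C;!R])C(=O)    acyclic_michael_acceptor
C(=O)OC(=O)             anhydride
[CX3](=O)[CX3](=O)      alpha_diketone
N=C=O                   isocyanate
N=C=S                   isothiocyanate
C1OC1                   epoxide
C1NC1                   aziridine
[N;!R]=[N;!R]           acyclic_azo
[SX2][SX2]              disulfide
[CH1]=O                 aldehyde
I                       iodine
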
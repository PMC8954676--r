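# Curated subset of well-known public pan-assay-interference (PAINS)
# substructure motifs. This is a representative, editable selection of the
# published families, not the complete catalog; point pains_matches() at a
# fuller file for production triage. One SMARTS per line, optional name.
c1cc(O)c(O)cc1            catechol
O=C1C=CC(=O)C=C1          para_quinone
O=C1C(=O)C=CC=C1          ortho_quinone
S1C(=O)NC(=O)C1           rhodanine_core
S1C(=S)NC(=O)C1           thioxo_rhodanine
c1ccccc1N=Nc1ccccc1       azo_aryl
[OH]c1ccccc1C=N           hydroxyphenyl_imine
[OH]c1ccccc1/C=N/N        hydroxyphenyl_hydrazone
C(=O)C=CC(=O)             ene_dione
c1ccccc1C(=O)C=Cc1ccccc1  chalcone
[#6]=[#6]([#6]#N)[#6]#N   alkylidene_malononitrile
c1cc(N)c(N)cc1            aromatic_12_diamine
[OH]c1cc([OH])cc([OH])c1  phloroglucinol
N=Nc1ccc(O)cc1            azo_phenol
C=C1C(=O)NC(=O)N1         alkylidene_hydantoin
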
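gene_id	early_lethal	source
GENE_LETHAL1	TRUE	synthetic null-mutant screen
GENE_LETHAL2	TRUE	synthetic null-mutant screen
GENE_BENIGN	FALSE	synthetic null-mutant screen
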
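quantity	value
total_ssrs	160318
ssrs_mapped_to_lg	116453
genes_total	27769
genes_with_ssr	9992
markers_screened	73
markers_polymorphic	19
cell_wall_genes_with_primers	113
cell_wall_ssrs	257
tf_ethylene_genes_with_primers	187
tf_ethylene_ssrs	528
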
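motif_class	exon	exon_intron	intron	intergenic
AT/TA	6	0	4554	38906
AC/CA/GT/TG	8	1	1049	7307
AG/GA/CT/TC	115	6	1546	8584
CG/GC	1	0	9	56
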
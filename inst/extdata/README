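Previously published genome-wide papaya microsatellite survey counts,
kept as plain inputs for the summary arithmetic:

  papaya_location_counts.tsv      repeats by genomic location x motif
                                  period class (di..hexa)
  papaya_dinucleotide_counts.tsv  dinucleotide canonical classes by
                                  genomic location
  papaya_survey_totals.tsv        headline totals (mapped repeats, gene
                                  counts, marker screen outcome,
                                  candidate-gene marker counts)
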
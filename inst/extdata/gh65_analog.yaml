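# Synthetic stand-in for the glycoside hydrolase family 65 dataset.
# 22 subfamilies x 50 sequences over 600 columns; the reference row is
# gap-free, so alignment columns and reference residue numbers coincide.
# Planted structure: a strongly coupled six-position set (hub 392), fifteen
# weakly coupled catalytic-domain positions sharing the same subgroup
# partition, and the N-terminal loop trio 56/62/63 on a partition of its
# own. Coupling strengths were calibrated once, on the generator's design,
# so that at substitution noise 0.02 the correlation bands fall on the
# conventional 0.8 / 0.9 thresholds.
n_subgroups: 22
seqs_per_subgroup: 50
n_columns: 600
epsilon: 0.02
gap_rate: 0.0
background: swissprot
reference_id: CsKP_synthetic
seed: 65
hub: 392
strong: [64, 392, 394, 402, 416, 585]
planted:
  - role: strong
    positions: [64, 392, 394, 402, 416, 585]
    partition: pairs
    coupling: 1.0
  - role: weak
    positions: [340, 351, 367, 389, 396, 399, 410, 423, 431, 447, 466, 478, 502, 533, 561]
    partition: pairs
    coupling: 0.93
  - role: loop
    positions: [56, 62, 63]
    partition: pairs_shifted
    coupling: 0.97
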
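# EXAMPLE ONLY - user-editable assumptions, not packaged defaults.
# Mechanism prediction (phosphorylase vs hydrolase) needs the alignment
# columns that line the phosphate-binding subsite and the residues that
# phosphorylases carry there. These are structure- and family-specific and
# must be curated by the user; the values below are illustrative
# placeholders in reference numbering and should be replaced with sites
# taken from a structure of the family under study.
phosphate_positions: [345, 587, 645]
phosphorylase_residues:
  - [R, K]
  - [Y]
  - [T, S]
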
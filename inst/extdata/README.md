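# Bundled reference tables

Both tables are SYNTHETIC stand-ins, constructed once to be consistent
with published summary statistics; they are not measured data.

- `bkm120_prolif_ic50_44lines_synthetic.csv`: per-line proliferation
  IC50s (uM) for a 44-cell-line panel of a dual PI3K/MDA drug.
  Constructed so that the panel median is 1.2 uM and 75% of lines have
  IC50 >= 0.9 uM, with a range compatible with a reported 0.1-12.1 uM
  histogram. Cell-line labels are generic placeholders.
- `pikin_kd_isoforms_synthetic.csv`: dissociation constants (nM) of two
  asymmetric PI3K-inhibitor pairs (parent vs regioisomer) for the four
  class-I PI3K isoforms. Constructed so that parent/regioisomer affinity
  folds lie in the reported 7-30x band (minimum 7.5x).
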
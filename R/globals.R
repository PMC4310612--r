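## data.table non-standard-evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "total_count", "ref_count", "chrom", "pos", "ratio",
  "individual", "cell_type", "library", "p0", "p0_lib", "p0_strat", "n",
  "pvalue", "is_ase", "sample", "gene_id", "primary", "secondary",
  "direction", "link_id", "five", "three", "N", "f", "p", "i", "ref",
  "alt", "uniqueN"))
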
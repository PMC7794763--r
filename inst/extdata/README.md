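# Bundled example data

- `plasma_triglycerides_summary.csv` — published per-group summary
  statistics (mean, SEM, n) for plasma triglycerides in a 2×2
  genotype × diet mouse design, in the `read_summary()` format; the
  standard input for `summary_stats_anova()`.
- `qpcr_synthetic.csv` — synthetic qPCR Ct table (two technical
  replicates per sample, GAPDH reference) for
  `qpcr_relative_expression()`.
- `luciferase_synthetic.csv` — synthetic dual-luciferase readings
  (firefly/Renilla channel pairs) for `net_luminescence()` and
  `fold_induction()`.
- `standards_synthetic.csv` — synthetic absorbance standard curve for
  `standard_curve_quantify()`.

The synthetic files are generated stand-ins shaped like the real assay
exports; ERG sweep data is always generated in code (see
`simulate_cohort()`).
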
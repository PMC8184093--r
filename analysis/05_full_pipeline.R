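#!/usr/bin/env Rscript
# One-stop end-to-end run: every report of the preceding steps produced by a
# single seeded configuration over the bio-entity corpus, with a manifest of
# checksummed outputs. Run analysis/01_simulate_corpora.R first.

library(bibliomine)

cfg <- run_config(
  input_medline = "results/data/bioentity.medline",
  input_pubtator = "results/data/bioentity.pubtator",
  outdir = "results/pipeline",
  granularity = "month",
  sigma = 0.1,
  min_df = 2,
  ngram_max = 1,
  seed = 1L
)
written <- run_pipeline(cfg)
message(length(written), " outputs under results/pipeline:")
for (f in names(written)) message("  ", f, " -> ", basename(written[[f]]))
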
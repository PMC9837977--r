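#!/usr/bin/env Rscript

# Step 2: the pairwise comparison analysis. The reporter-style query set is
# tested for overlap against every assay-style reference set and against
# each batch's consensus profile (>= 50% track support), with permutation
# significance and enrichment/depletion classification at a
# Bonferroni-adjusted alpha. Requires results/world/ from step 1.

library(enhancerConcord)

world <- read_world("results/world")
seed <- 20260925L

# consensus profile per batch, merged from that batch's tracks
batches <- vapply(world$assay_sets, function(s) s$metadata$batch_label,
                  character(1))
consensus <- list()
for (b in unique(batches)) {
  cons <- consensus_merge(world$assay_sets[batches == b], 0.5,
                          label = paste0(b, "_consensus"))
  cons$metadata$batch_label <- b
  consensus[[cons$label]] <- cons
  cat(sprintf("consensus for batch %s: %d regions from %d tracks\n",
              b, n_intervals(cons), sum(batches == b)))
}

report <- run_compare(analysis_config(
  genome = world$genome,
  queries = list(reporter = world$reporter_set),
  references = c(world$assay_sets, consensus),
  n_perm = 500, alpha = 0.01, seed = seed,
  out_dir = "results/compare"))

cat("\nPer-pair results (fraction found, z, classification):\n")
print(report[, c("reference_label", "n_overlapping", "n_query",
                 "fraction_pct", "z", "classification")], row.names = FALSE)
cat(sprintf("\n%d/%d comparisons enriched; median overlap %d%%\n",
            sum(report$classification == "enriched"), nrow(report),
            as.integer(stats::median(report$fraction_pct))))
cat("Report written to results/compare/\n")
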
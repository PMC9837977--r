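#!/usr/bin/env Rscript

# Step 1: generate the reference synthetic enhancer world and export it as
# a plain-text bundle (BED sets, chrom.sizes, truth table, manifest,
# config echo) under results/world/. Later steps load this bundle, so the
# whole workflow also exercises the on-disk round trip.

library(enhancerConcord)

seed <- 20260925L
out <- "results/world"

cfg <- synthetic_world_config(master_seed = seed)
world <- run_simulate(cfg, out, n_tissues = 4)

cat(sprintf("Simulated world (seed %d):\n", seed))
cat(sprintf("  true enhancers : %d (pairwise non-overlapping)\n",
            n_intervals(world$true_enhancers)))
cat(sprintf("  reporter set   : %d intervals (sensitivity %.2f, %d false positives, %d bp jitter)\n",
            n_intervals(world$reporter_set), cfg$reporter$sensitivity,
            cfg$reporter$n_false_positives, cfg$reporter$boundary_jitter_bp))
for (lab in names(world$assay_sets))
  cat(sprintf("  assay %-16s: %d intervals (batch %s)\n", lab,
              n_intervals(world$assay_sets[[lab]]),
              world$assay_sets[[lab]]$metadata$batch_label))
cat(sprintf("  tissue groups  : %s\n",
            paste(sprintf("%s=%d", names(world$tissue_groups),
                          lengths(world$tissue_groups)), collapse = ", ")))
cat(sprintf("Bundle written to %s\n", out))
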
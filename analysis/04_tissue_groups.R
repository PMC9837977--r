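#!/usr/bin/env Rscript

# Step 4: tissue-matched comparisons. The reporter query is restricted to
# short elements, de-overlapped keeping the smallest feature, and split
# into tissue groups via the annotation table; each tissue set is compared
# against one assay reference, and the best-matching candidate per
# reference is selected by overlap fraction. Requires results/world/.

library(enhancerConcord)

world <- read_world("results/world")
seed <- 20260925L

reporter <- select_smallest_nonoverlapping(
  filter_by_length(world$reporter_set, 1000))
cat(sprintf("reporter: %d -> %d intervals after <=1000 bp filter + de-overlap\n",
            n_intervals(world$reporter_set), n_intervals(reporter)))

tissue_map <- world$tissue_map
groups <- group_by_tissue(reporter, world$annotations, tissue_map)
cat(sprintf("tissue groups: %s\n",
            paste(sprintf("%s=%d", names(groups), vapply(groups, n_intervals, integer(1))),
                  collapse = ", ")))

report <- run_compare(analysis_config(
  genome = world$genome,
  queries = groups,
  references = list(seriesA_assay1 = world$assay_sets[["seriesA_assay1"]]),
  n_perm = 200, alpha = 0.01, seed = seed,
  out_dir = "results/tissue_compare"))

candidates <- lapply(split(report, report$query_label), function(row)
  structure(list(fraction_pct = row$fraction_pct), class = "overlap_result"))
best <- select_best_matching(candidates)
cat(sprintf("\nBest-matching tissue set for seriesA_assay1: %s (%d%% overlap)\n",
            best, report$fraction_pct[report$query_label == best]))
cat("Report written to results/tissue_compare/\n")
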
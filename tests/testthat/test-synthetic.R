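# Small worlds keep these tests fast; the genome and batch structure follow
# the generator's defaults unless a property needs otherwise.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    genome = genome_spec(c(chr1 = 2e5, chr2 = 2e5)),
    n_true = 100,
    length_range = c(100L, 400L),
    reporter = list(sensitivity = 0.7, n_false_positives = 20,
                    boundary_jitter_bp = 20),
    batches = list(
      list(batch_label = "A", latent_fraction = 0.4, n_assays = 2,
           assay_sensitivity = 0.9, assay_fp_count = 20),
      list(batch_label = "B", latent_fraction = 0.4, n_assays = 2,
           assay_sensitivity = 0.9, assay_fp_count = 20)),
    master_seed = 5L)
  defaults[names(args)] <- args   # replace whole entries, never merge
  do.call(synthetic_world_config, defaults)
}

test_that("degenerate parameters reproduce the truth exactly", {
  cfg <- small_config(reporter = list(sensitivity = 1, n_false_positives = 0,
                                      boundary_jitter_bp = 0))
  w <- make_world(cfg)
  expect_identical(w$reporter_set$intervals[, c("chrom", "start", "end", "name")],
                   w$true_enhancers$intervals[, c("chrom", "start", "end", "name")])
})

test_that("true enhancers are pairwise non-overlapping and on the genome", {
  w <- make_world(small_config())
  d <- w$true_enhancers$intervals
  for (i in seq_len(nrow(d)))
    expect_false(any(oracle_found(d[i, , drop = FALSE], d[-i, , drop = FALSE])))
  expect_true(all(d$end <= w$genome$chrom_lengths[d$chrom]))
})

test_that("reporter size follows the binomial sampling model across seeds", {
  # s_r = 0.6, n_true = 500, no false positives: mean count over 30 seeds
  # should sit in the 99% CI of the mean of Binomial(500, 0.6)
  counts <- vapply(1:30, function(seed) {
    cfg <- synthetic_world_config(
      n_true = 500,
      reporter = list(sensitivity = 0.6, n_false_positives = 0,
                      boundary_jitter_bp = 0),
      batches = list(list(batch_label = "A", latent_fraction = 0.5,
                          n_assays = 1, assay_sensitivity = 1,
                          assay_fp_count = 0)),
      master_seed = seed)
    n_intervals(make_world(cfg)$reporter_set)
  }, numeric(1))
  se_mean <- sqrt(500 * 0.6 * 0.4 / 30)
  expect_lt(abs(mean(counts) - 300), qnorm(0.995) * se_mean)
})

test_that("identical config and seed give bit-identical worlds", {
  w1 <- make_world(small_config())
  w2 <- make_world(small_config())
  expect_identical(w1$true_enhancers, w2$true_enhancers)
  expect_identical(w1$reporter_set, w2$reporter_set)
  expect_identical(w1$assay_sets, w2$assay_sets)
  expect_identical(w1$truth_table, w2$truth_table)
  w3 <- make_world(small_config(master_seed = 6L))
  expect_false(identical(w1$reporter_set$intervals, w3$reporter_set$intervals))
})

test_that("truth table is consistent with actual set membership", {
  w <- make_world(small_config())
  tt <- w$truth_table
  expect_setequal(tt$name[tt$reporter],
                  intersect(w$reporter_set$intervals$name, tt$name))
  for (lab in names(w$assay_sets))
    expect_setequal(tt$name[tt[[lab]]],
                    intersect(w$assay_sets[[lab]]$intervals$name, tt$name))
  # detected enhancers are always members of their batch's latent subset
  expect_true(all(!tt$A_assay1 | tt$latent_A))
  expect_true(all(!tt$B_assay2 | tt$latent_B))
  # disjoint batches: latent subsets do not intersect
  expect_false(any(tt$latent_A & tt$latent_B))
})

test_that("false positives never touch a true enhancer", {
  w <- make_world(small_config())
  truth <- w$true_enhancers$intervals
  fps <- w$reporter_set$intervals[grepl("^rep_fp_", w$reporter_set$intervals$name), ]
  expect_false(any(oracle_found(fps, truth)))
})

test_that("closed-form expected overlap matches its degenerate cases", {
  cfg1 <- small_config(
    reporter = list(sensitivity = 1, n_false_positives = 0,
                    boundary_jitter_bp = 0),
    batches = list(list(batch_label = "A", latent_fraction = 1, n_assays = 1,
                        assay_sensitivity = 1, assay_fp_count = 0)))
  expect_equal(expected_overlap_fraction(cfg1), 100)
  cfg2 <- small_config(
    reporter = list(sensitivity = 1, n_false_positives = 0,
                    boundary_jitter_bp = 0),
    batches = list(list(batch_label = "A", latent_fraction = 0.5, n_assays = 1,
                        assay_sensitivity = 0.8, assay_fp_count = 0)))
  expect_equal(expected_overlap_fraction(cfg2), 40)
})

test_that("full-mixture expectation tracks a Monte-Carlo estimate", {
  cfg <- function(seed) small_config(master_seed = seed)
  fracs <- vapply(1:25, function(seed) {
    w <- make_world(cfg(seed))
    count_overlapping(w$reporter_set, w$assay_sets[["A_assay1"]])$fraction_pct
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected_overlap_fraction(cfg(1))),
            3 * se + 2)  # small analytic bias allowed for jitter/adjacency
})

test_that("tissue worlds round-trip through the grouping operation", {
  w1 <- make_tissue_world(small_config(), n_tissues = 1)
  expect_equal(names(w1$tissue_groups), "tissue_01")
  expect_setequal(w1$tissue_groups[[1]], w1$true_enhancers$intervals$name)

  w3 <- make_tissue_world(small_config(), n_tissues = 3)
  expect_equal(sum(lengths(w3$tissue_groups)), w3$config$n_true)  # partition
  groups <- group_by_tissue(w3$true_enhancers, w3$annotations, w3$tissue_map)
  expect_setequal(names(groups), names(w3$tissue_groups))
  for (g in names(groups))
    expect_setequal(groups[[g]]$intervals$name, w3$tissue_groups[[g]])
})

test_that("config validation rejects impossible worlds", {
  expect_error(small_config(n_true = 1e5), "infeasible")
  expect_error(small_config(reporter = list(sensitivity = 1.4,
                                            n_false_positives = 0,
                                            boundary_jitter_bp = 0)),
               "sensitivity")
  expect_error(small_config(batches = list(
    list(batch_label = "A", latent_fraction = 0.8, n_assays = 1,
         assay_sensitivity = 1, assay_fp_count = 0),
    list(batch_label = "B", latent_fraction = 0.8, n_assays = 1,
         assay_sensitivity = 1, assay_fp_count = 0))),
    "disjoint")
})
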
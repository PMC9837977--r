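test_that("a query spanning several references is counted once", {
  q <- interval_set(data.frame(chrom = "chr1", start = 0L, end = 1000L,
                               name = "span"), "q")
  r <- interval_set(data.frame(chrom = "chr1", start = c(10L, 500L),
                               end = c(20L, 600L), name = c("r1", "r2")), "r")
  ov <- count_overlapping(q, r)
  expect_equal(ov$n_overlapping, 1L)
  expect_equal(ov$found_names, "span")
  expect_equal(ov$fraction_pct, 100)
})

test_that("disjoint chromosomes give zero overlap; empty query errors", {
  q <- interval_set(data.frame(chrom = "chr1", start = 0L, end = 100L,
                               name = "a"), "q")
  r <- interval_set(data.frame(chrom = "chr9", start = 0L, end = 100L,
                               name = "b"), "r")
  expect_equal(count_overlapping(q, r)$n_overlapping, 0L)
  expect_error(count_overlapping(interval_set(NULL, "e"), r), "empty query")
})

test_that("sweep counting equals the all-pairs oracle on random fixtures", {
  set.seed(41)
  for (k in 1:25) {
    q <- random_interval_set(sample(1:200, 1), "q")
    r <- random_interval_set(sample(1:300, 1), "r")
    ov <- count_overlapping(q, r)
    flags <- oracle_found(q$intervals, r$intervals)
    expect_equal(ov$n_overlapping, sum(flags))
    expect_setequal(ov$found_names, q$intervals$name[flags])
  }
})

test_that("enlarging the reference never decreases the overlap count", {
  set.seed(42)
  for (k in 1:10) {
    q <- random_interval_set(80, "q")
    r_small <- random_interval_df(40)
    r_extra <- random_interval_df(40)
    r_extra$name <- paste0("x_", r_extra$name)
    n1 <- count_overlapping(q, interval_set(r_small, "r1"))$n_overlapping
    n2 <- count_overlapping(q, interval_set(rbind(r_small, r_extra), "r2"))$n_overlapping
    expect_gte(n2, n1)
  }
})

test_that("percent rounds half away from zero and validates the denominator", {
  expect_identical(percent(0, 10), 0L)
  expect_identical(percent(1, 8), 13L)    # 12.5 -> 13, not banker's 12
  expect_identical(percent(3, 8), 38L)    # 37.5 -> 38
  expect_error(percent(1, 0), "positive")
})

test_that("shuffle preserves lengths and bounds, is seed-deterministic", {
  g <- tiny_genome()
  set.seed(43)
  s <- random_interval_set(50)
  for (seed in c(1L, 99L, 4242L)) {
    sh <- shuffle_set(s, g, seed)
    expect_setequal(interval_lengths(sh), interval_lengths(s))
    expect_equal(n_intervals(sh), n_intervals(s))
    expect_true(all(sh$intervals$start >= 0))
    expect_true(all(sh$intervals$end <=
                      g$chrom_lengths[sh$intervals$chrom]))
    expect_identical(shuffle_set(s, g, seed)$intervals, sh$intervals)
  }
})

test_that("shuffle placement is forced when the interval fills the chromosome", {
  g <- genome_spec(c(only = 500))
  s <- interval_set(data.frame(chrom = "only", start = 100L, end = 600L,
                               name = "full")[0, ], "s")
  s <- interval_set(data.frame(chrom = "only", start = 0L, end = 500L,
                               name = "full"), "s")
  for (seed in 1:5) {
    sh <- shuffle_set(s, g, seed)
    expect_equal(sh$intervals$start, 0L)
    expect_equal(sh$intervals$end, 500L)
  }
  too_big <- interval_set(data.frame(chrom = "only", start = 0L, end = 500L,
                                     name = "big"), "s")
  expect_error(shuffle_set(too_big, genome_spec(c(tiny = 100)), 1),
               "longer than every chromosome|beyond|absent")
})

test_that("shuffle does not disturb the caller's RNG stream", {
  g <- tiny_genome()
  s <- random_interval_set(10)
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(shuffle_set(s, g, 123)); after <- runif(3)
  expect_identical(before, after)
})

test_that("permutation test fields are internally consistent", {
  g <- tiny_genome()
  set.seed(44)
  q <- random_interval_set(60, "q")
  r <- random_interval_set(60, "r")
  pt <- permutation_test(q, r, g, n_perm = 50, rng_seed = 9)
  expect_equal(pt$z, (pt$observed - pt$perm_mean) / pt$perm_sd)
  expect_equal(pt$p_two_tailed, 2 * pnorm(-abs(pt$z)))
  expect_true(pt$p_two_tailed >= 0 && pt$p_two_tailed <= 1)
  expect_error(permutation_test(q, r, g, n_perm = 1), "n_perm")
  # reproducible under the same master seed
  pt2 <- permutation_test(q, r, g, n_perm = 50, rng_seed = 9)
  expect_identical(pt2[c("perm_mean", "perm_sd", "z")],
                   pt[c("perm_mean", "perm_sd", "z")])
})

test_that("a reference tiling the genome forces a degenerate result", {
  g <- genome_spec(c(chrA = 1000))
  q <- interval_set(data.frame(chrom = "chrA", start = c(10L, 200L),
                               end = c(60L, 260L), name = c("a", "b")), "q")
  tile <- interval_set(data.frame(chrom = "chrA", start = 0L, end = 1000L,
                                  name = "all"), "r")
  pt <- permutation_test(q, tile, g, n_perm = 20, rng_seed = 1)
  expect_equal(pt$classification, "degenerate")
  expect_true(is.na(pt$z) && is.na(pt$p_two_tailed))
  expect_equal(pt$perm_sd, 0)
})

test_that("bonferroni adjustment and classification arms", {
  expect_equal(bonferroni_alpha(0.01, 21), 0.01 / 21)
  expect_equal(bonferroni_alpha(0.01, 1), 0.01)
  expect_equal(bonferroni_alpha(0.01, 56), 0.01 / 56, tolerance = 1e-12)
  expect_error(bonferroni_alpha(0.01, 0), "positive")
  expect_error(bonferroni_alpha(1.2, 5), "alpha")
  base <- structure(list(observed = 0, perm_mean = 0, perm_sd = 1,
                         classification = "not_significant"),
                    class = "permutation_result")
  up <- base; up$z <- 5; up$p_two_tailed <- 2 * pnorm(-5)
  dn <- base; dn$z <- -5; dn$p_two_tailed <- 2 * pnorm(-5)
  mid <- base; mid$z <- 1; mid$p_two_tailed <- 2 * pnorm(-1)
  expect_equal(classify(up, 4.76e-4)$classification, "enriched")
  expect_equal(classify(dn, 4.76e-4)$classification, "depleted")
  expect_equal(classify(mid, 4.76e-4)$classification, "not_significant")
  dg <- base; dg$perm_sd <- 0; dg$classification <- "degenerate"
  dg$z <- NA_real_; dg$p_two_tailed <- NA_real_
  expect_equal(classify(dg, 0.01)$classification, "degenerate")
})

test_that("best-matching selection takes the argmax, ties lexicographic", {
  mk <- function(n_ov, n_q) structure(list(fraction_pct = 100 * n_ov / n_q),
                                      class = "overlap_result")
  expect_equal(select_best_matching(list(A = mk(1, 10), B = mk(26, 100))), "B")
  expect_equal(select_best_matching(list(B = mk(26, 100), A = mk(26, 100))), "A")
  expect_equal(select_best_matching(list(only = mk(3, 7))), "only")
  expect_error(select_best_matching(list()), "no candidates")
})
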
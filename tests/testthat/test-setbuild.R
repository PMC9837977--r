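test_that("length filtering is inclusive at the cutoff", {
  s <- interval_set(data.frame(chrom = "chr1",
                               start = c(0L, 5000L, 10000L),
                               end = c(2000L, 7001L, 10100L),
                               name = c("at_cutoff", "over", "short")), "s")
  kept <- filter_by_length(s, 2000)
  expect_setequal(kept$intervals$name, c("at_cutoff", "short"))
  expect_equal(n_intervals(filter_by_length(interval_set(NULL, "e"), 2000)), 0L)
})

test_that("smallest-feature de-overlap keeps the smaller of nested intervals", {
  s <- interval_set(data.frame(chrom = "chr1", start = c(0L, 100L),
                               end = c(300L, 200L), name = c("big", "small")), "s")
  expect_equal(select_smallest_nonoverlapping(s)$intervals$name, "small")
})

test_that("de-overlap greedy chain: rejected middle interval rescues the third", {
  # all length 100; middle overlaps first (rejected), third overlaps only the
  # rejected middle so it is accepted
  s <- interval_set(data.frame(chrom = "chr1", start = c(0L, 50L, 140L),
                               end = c(100L, 150L, 240L),
                               name = c("a", "b", "c")), "s")
  out <- select_smallest_nonoverlapping(s)
  expect_equal(out$intervals$name, c("a", "c"))
  expect_equal(out$intervals$start, c(0L, 140L))
})

test_that("de-overlap output is non-overlapping, a subset, and idempotent", {
  set.seed(21)
  for (k in 1:20) {
    s <- random_interval_set(60, chrom_len = 3000L, max_len = 400L)
    out <- select_smallest_nonoverlapping(s)
    d <- out$intervals
    # pairwise non-overlapping via oracle
    for (i in seq_len(nrow(d))) {
      others <- d[-i, , drop = FALSE]
      expect_false(any(oracle_found(d[i, , drop = FALSE], others)))
    }
    expect_true(all(d$name %in% s$intervals$name))
    expect_identical(select_smallest_nonoverlapping(out)$intervals, d)
    # already non-overlapping input returned unchanged
    expect_identical(select_smallest_nonoverlapping(out)$intervals,
                     out$intervals)
  }
})

test_that("the standard preparation order never increases the count", {
  set.seed(22)
  s <- random_interval_set(120, chrom_len = 5000L, max_len = 500L)
  filtered <- filter_by_length(s, 300)
  deov <- select_smallest_nonoverlapping(filtered)
  expect_lte(n_intervals(filtered), n_intervals(s))
  expect_lte(n_intervals(deov), n_intervals(filtered))
})

test_that("tissue grouping honors multi-membership and drops unmapped terms", {
  s <- interval_set(data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                               end = c(50L, 150L, 250L),
                               name = c("e1", "e2", "e3")), "s")
  ann <- data.frame(interval_name = c("e1", "e1", "e2", "e3"),
                    tissue_term = c("wing disc", "eye disc", "obscure", "gut"))
  map <- c("wing disc" = "wing", "eye disc" = "eye", "gut" = "gut")
  g <- group_by_tissue(s, ann, map)
  expect_setequal(names(g), c("wing", "eye", "gut"))
  expect_equal(g$wing$intervals$name, "e1")
  expect_equal(g$eye$intervals$name, "e1")   # same interval, two groups
  expect_equal(g$gut$intervals$name, "e3")   # e2's term unmapped -> no group
  expect_error(group_by_tissue(s, ann, character(0)), "non-empty")
  expect_warning(
    group_by_tissue(s, rbind(ann, data.frame(interval_name = "ghost",
                                             tissue_term = "gut")), map),
    "absent")
})

test_that("tissue annotation and map TSVs round-trip", {
  ann <- data.frame(interval_name = c("e1", "e2"),
                    tissue_term = c("wing disc", "gut"))
  f <- withr::local_tempfile()
  write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_tissue_annotations(f), ann)
  f2 <- withr::local_tempfile()
  writeLines(c("wing disc\twing", "gut\tgut"), f2)
  expect_equal(read_tissue_map(f2), c("wing disc" = "wing", "gut" = "gut"))
})

test_that("consensus threshold is ceil(support_fraction * n_tracks)", {
  mk <- function(start, end) interval_set(
    data.frame(chrom = "chrA", start = start, end = end,
               name = paste0("p", seq_along(start))), "t")
  # region [100,200) covered by 2 of 3 tracks: in (2 >= ceil(1.5) = 2);
  # region [500,600) covered by 1 of 3: out
  tr <- list(mk(100L, 200L), mk(100L, 200L), mk(500L, 600L))
  cons <- consensus_merge(tr)
  expect_equal(cons$intervals[, c("start", "end")],
               data.frame(start = 100L, end = 200L))
  expect_error(track_bundle(tr, 1.5), "support_fraction")
  expect_error(track_bundle(list()), "at least one")
})

test_that("consensus merge matches the per-base oracle and is order-invariant", {
  set.seed(31)
  lens <- c(chrA = 2000L, chrB = 1500L)
  for (k in 1:10) {
    dfs <- lapply(1:3, function(i)
      random_interval_df(12, chroms = names(lens), chrom_len = 1500L,
                         max_len = 200L))
    tracks <- lapply(seq_along(dfs), function(i)
      interval_set(dfs[[i]], paste0("t", i)))
    cons <- consensus_merge(tracks, 0.5)
    expected <- oracle_consensus(dfs, as.list(lens), ceiling(0.5 * 3))
    got <- cons$intervals[, c("chrom", "start", "end")]
    rownames(got) <- rownames(expected) <- NULL
    expect_equal(got, expected)
    # permuting track order changes nothing
    perm <- consensus_merge(tracks[c(3, 1, 2)], 0.5)
    expect_identical(perm$intervals, cons$intervals)
  }
})

test_that("single-track consensus is the track's union", {
  t1 <- interval_set(data.frame(chrom = "chrA",
                                start = c(0L, 50L, 300L),
                                end = c(100L, 150L, 400L),
                                name = c("a", "b", "c")), "t1")
  cons <- consensus_merge(list(t1), 0.5)
  expect_equal(cons$intervals[, c("start", "end")],
               data.frame(start = c(0L, 300L), end = c(150L, 400L)))
})
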
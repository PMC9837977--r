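# Overlap counting with unique query reporting, genome shuffling, and the
# permutation z-score significance test.
#
# The overlap contract mirrors `bedtools intersect -wa -u`: a query
# interval is scored as found iff it shares at least one basepair with at
# least one reference interval, and is counted at most once however many
# reference intervals it touches.

# Per-chromosome reference index: starts sorted ascending with the running
# maximum of ends, allowing an O(log m) "any overlap?" query per interval.
.make_ref_index <- function(df) {
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    o <- order(d$start)
    out[[ch]] <- list(starts = d$start[o], maxend = cummax(d$end[o]))
  }
  out
}

# Logical found-flag per query interval, given a prebuilt reference index.
# A reference interval overlaps [s, e) iff ref_start < e and ref_end > s;
# among references with start < e (the first k in start order) it suffices
# to check the running maximum of ends.
.found_flags <- function(chrom, start, end, ref_index) {
  found <- logical(length(chrom))
  for (ch in unique(chrom)) {
    ix <- ref_index[[ch]]
    if (is.null(ix)) next
    sel <- which(chrom == ch)
    k <- findInterval(end[sel] - 1L, ix$starts)  # refs with start <= end-1
    hit <- k > 0L
    hit[hit] <- ix$maxend[k[hit]] > start[sel][hit]
    found[sel] <- hit
  }
  found
}

#' Count query intervals overlapping a reference set
#'
#' Each query interval is counted at most once, and is counted iff it
#' overlaps at least one reference interval by at least one basepair
#' (half-open coordinates; adjacency does not count). Implemented as a
#' per-chromosome sort + sweep.
#'
#' @param query,reference `interval_set` objects; `query` must be non-empty.
#' @return A list of class `overlap_result` with fields `query_label`,
#'   `reference_label`, `n_query`, `n_overlapping`, `found_names`,
#'   `fraction_pct` (exact, unrounded percent).
#' @export
count_overlapping <- function(query, reference) {
  q <- query$intervals
  if (!nrow(q)) stop("empty query set: overlap fraction undefined")
  idx <- .make_ref_index(reference$intervals)
  found <- .found_flags(q$chrom, q$start, q$end, idx)
  structure(list(query_label = query$label,
                 reference_label = reference$label,
                 n_query = nrow(q),
                 n_overlapping = sum(found),
                 found_names = q$name[found],
                 fraction_pct = 100 * sum(found) / nrow(q)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap '%s' vs '%s': %d/%d found (%d%%)>\n",
              x$query_label, x$reference_label, x$n_overlapping, x$n_query,
              percent(x$n_overlapping, x$n_query)))
  invisible(x)
}

# ---- shuffling -------------------------------------------------------------

# Precompute, for a fixed vector of interval lengths, the number of valid
# (chrom, start) placements per chromosome. Reused across permutations.
.placement_table <- function(len, genome) {
  cl <- genome$chrom_lengths
  valid <- outer(len, cl, function(L, C) pmax(C - L + 1, 0))  # n x k
  tot <- rowSums(valid)
  if (any(tot == 0))
    stop("interval longer than every chromosome: no valid placement")
  cum <- valid
  if (ncol(cum) > 1L) for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
  list(len = len, chroms = names(cl), valid = valid, cum = cum, tot = tot)
}

# One uniform draw per interval over all valid genome-wide placements.
# Consumes length(len) uniforms from the current RNG stream.
.draw_placements <- function(tab) {
  n <- length(tab$len)
  u <- floor(stats::runif(n) * tab$tot)          # in [0, tot)
  ge <- tab$cum > u                              # first TRUE column = chrom
  j <- max.col(ge, ties.method = "first")
  pick <- cbind(seq_len(n), j)
  start <- u - (tab$cum[pick] - tab$valid[pick])
  list(chrom = tab$chroms[j], start = start, end = start + tab$len)
}

#' Randomly relocate every interval on the genome
#'
#' Each interval is independently moved to a placement drawn uniformly
#' over all valid (chrom, start) positions genome-wide (start + length
#' must fit on the chromosome). Lengths, names and count are preserved;
#' shuffled intervals may overlap one another. Deterministic given
#' `rng_seed`, without disturbing the caller's RNG state.
#'
#' @param set An `interval_set`.
#' @param genome A `genome_spec`.
#' @param rng_seed Integer seed.
#' @param per_chrom If `TRUE`, each interval stays on its original
#'   chromosome (uniform over starts there). Default `FALSE`.
#' @return A shuffled `interval_set`.
#' @export
shuffle_set <- function(set, genome, rng_seed, per_chrom = FALSE) {
  df <- set$intervals
  if (!nrow(df)) return(set)
  len <- df$end - df$start
  if (per_chrom) {
    room <- genome$chrom_lengths[df$chrom] - len
    if (any(is.na(room)) || any(room < 0))
      stop("interval does not fit on its own chromosome")
    pl <- with_seed(rng_seed, {
      start <- floor(stats::runif(nrow(df)) * (room + 1))
      list(chrom = df$chrom, start = start, end = start + len)
    })
  } else {
    tab <- .placement_table(len, genome)
    pl <- with_seed(rng_seed, .draw_placements(tab))
  }
  interval_set(data.frame(chrom = pl$chrom, start = pl$start, end = pl$end,
                          name = df$name, stringsAsFactors = FALSE),
               set$label, set$metadata)
}

# ---- permutation test ------------------------------------------------------

#' Permutation significance of an overlap count
#'
#' The observed count of query intervals overlapping the reference is
#' compared with the counts obtained after randomly relocating the query
#' set on the genome `n_perm` times. The permuted sample mean and sample
#' standard deviation (n-1 denominator) give a z-score for the observed
#' count, and a two-tailed p-value under the normal approximation,
#' `p = 2 * (1 - pnorm(|z|))`. With 500 permutations the empirical tail is
#' far too coarse for Bonferroni-scale thresholds, hence the z-test.
#'
#' Permutation i uses a seed derived deterministically from
#' `(rng_seed, i)`, so results are reproducible and independent of
#' evaluation order.
#'
#' @param query,reference Non-empty `interval_set` objects.
#' @param genome A `genome_spec` covering the query intervals.
#' @param n_perm Number of permutations (>= 2; default 500).
#' @param rng_seed Integer master seed.
#' @param alpha_adjusted Significance threshold already adjusted for
#'   multiplicity (see [bonferroni_alpha()]); default 0.01.
#' @param per_chrom Shuffle within chromosomes only (default `FALSE`).
#' @return A list of class `permutation_result`: `observed`, `n_perm`,
#'   `perm_mean`, `perm_sd`, `z`, `p_two_tailed`, `alpha_adjusted`,
#'   `classification` (enriched / depleted / not_significant / degenerate;
#'   degenerate when `perm_sd == 0`, in which case `z` and `p` are `NA`).
#' @export
permutation_test <- function(query, reference, genome, n_perm = 500,
                             rng_seed = 1L, alpha_adjusted = 0.01,
                             per_chrom = FALSE) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (!nrow(query$intervals) || !nrow(reference$intervals))
    stop("permutation_test requires non-empty query and reference sets")
  .check_on_genome(query, genome)
  observed <- count_overlapping(query, reference)$n_overlapping
  ref_index <- .make_ref_index(reference$intervals)
  q <- query$intervals
  len <- q$end - q$start
  tab <- if (!per_chrom) .placement_table(len, genome) else NULL
  room <- if (per_chrom) genome$chrom_lengths[q$chrom] - len else NULL
  counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    pl <- with_seed(derive_seed(rng_seed, i), {
      if (per_chrom) {
        start <- floor(stats::runif(nrow(q)) * (room + 1))
        list(chrom = q$chrom, start = start, end = start + len)
      } else .draw_placements(tab)
    })
    counts[i] <- sum(.found_flags(pl$chrom, pl$start, pl$end, ref_index))
  }
  m <- mean(counts)
  s <- stats::sd(counts)
  res <- list(query_label = query$label, reference_label = reference$label,
              observed = observed, n_perm = n_perm, perm_mean = m,
              perm_sd = s, z = NA_real_, p_two_tailed = NA_real_,
              alpha_adjusted = alpha_adjusted,
              classification = "degenerate")
  if (s > 0) {
    res$z <- (observed - m) / s
    res$p_two_tailed <- 2 * stats::pnorm(-abs(res$z))
    res <- classify(res, alpha_adjusted)
  }
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation test '%s' vs '%s': observed %d, null %.1f +/- %.2f, z = %s, %s>\n",
              x$query_label %||% "?", x$reference_label %||% "?",
              x$observed, x$perm_mean, x$perm_sd,
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)),
              x$classification))
  invisible(x)
}

#' Bonferroni-adjust a significance level
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons in the family (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("m must be a positive count")
  alpha / m
}

#' Classify a permutation result as enriched, depleted or not significant
#'
#' Two-tailed: significant overlap excess (`p < alpha_adjusted`, `z > 0`)
#' is `enriched`; significant deficit (`z < 0`) is `depleted` — the case
#' of significantly less overlap than expected by chance; otherwise
#' `not_significant`. Degenerate results (zero permutation spread) pass
#' through unchanged.
#'
#' @param result A `permutation_result`.
#' @param alpha_adjusted Adjusted significance threshold.
#' @return The result with `classification` (and `alpha_adjusted`) set.
#' @export
classify <- function(result, alpha_adjusted) {
  result$alpha_adjusted <- alpha_adjusted
  if (identical(result$classification, "degenerate") &&
      (is.na(result$perm_sd) || result$perm_sd == 0)) return(result)
  result$classification <-
    if (!is.na(result$p_two_tailed) && result$p_two_tailed < alpha_adjusted) {
      if (result$z > 0) "enriched" else "depleted"
    } else "not_significant"
  result
}

#' Pick the candidate reference with the highest overlap fraction
#'
#' When several candidate comparisons target the same reference, the one
#' with the highest degree of overlap is selected; ties break
#' lexicographically by label (C locale) for determinism.
#'
#' @param candidates Named list of `overlap_result`.
#' @return The winning label (character scalar).
#' @export
select_best_matching <- function(candidates) {
  if (!length(candidates)) stop("no candidates to select from")
  labs <- names(candidates)
  if (is.null(labs) || any(!nzchar(labs))) stop("candidates must be named")
  frac <- vapply(candidates, function(r) r$fraction_pct, numeric(1))
  best <- which(frac == max(frac))
  labs[best][radix_order(labs[best])[1]]
}
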
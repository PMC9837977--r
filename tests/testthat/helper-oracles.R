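# Independent oracles and fixture builders. These deliberately avoid the
# package's sweep/index code paths: overlap is checked all-pairs, consensus
# support is counted per base.

# O(n*m) all-pairs found flags for query vs reference data frames.
oracle_found <- function(q, r) {
  vapply(seq_len(nrow(q)), function(i)
    any(r$chrom == q$chrom[i] & r$start < q$end[i] & q$start[i] < r$end),
    logical(1))
}

# Random interval data frame on a small genome (uses the current RNG stream).
random_interval_df <- function(n, chroms = c("chrA", "chrB"),
                               chrom_len = 10000L, max_len = 300L) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(L) sample.int(chrom_len - L + 1L, 1L) - 1L,
                  integer(1))
  data.frame(chrom = chrom, start = start, end = start + len,
             name = sprintf("iv_%d", seq_len(n)), stringsAsFactors = FALSE)
}

random_interval_set <- function(n, label = "rand", ...) {
  interval_set(random_interval_df(n, ...), label)
}

# Per-base consensus oracle: counts, for every base of a small genome, how
# many tracks cover it, and returns runs meeting the threshold.
oracle_consensus <- function(track_dfs, chrom_lens, threshold) {
  out <- list()
  for (ch in names(chrom_lens)) {
    L <- chrom_lens[[ch]]
    support <- integer(L)
    for (df in track_dfs) {
      covered <- logical(L)
      d <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(d)))
        covered[(d$start[i] + 1L):d$end[i]] <- TRUE  # base b -> index b+1
      support <- support + covered
    }
    keep <- support >= threshold
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts[j] - 1L,
                                            end = ends[j],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Direct 2x2-contingency phi coefficient for two 0/1 vectors.
oracle_phi <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  den <- sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
  if (den == 0) return(NA_real_)
  (a * d - b * c_) / den
}

tiny_genome <- function() genome_spec(c(chrA = 10000, chrB = 10000))

make_bed <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
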
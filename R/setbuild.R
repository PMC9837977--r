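# Construction of analysis-ready enhancer sets: length filtering,
# smallest-feature de-overlapping, tissue grouping, and consensus merging
# of multiple tracks under a support threshold.

#' Keep intervals no longer than a cutoff
#'
#' Length filtering is inclusive: an interval of length exactly `max_len`
#' is retained ("max_len or shorter"). Applied before de-overlapping when
#' preparing reporter-gene sets, to avoid spuriously long entries spanning
#' several independent elements.
#'
#' @param set An `interval_set`.
#' @param max_len Maximum length in bp (>= 1).
#' @return Filtered `interval_set` (order preserved).
#' @export
filter_by_length <- function(set, max_len) {
  stopifnot(length(max_len) == 1L, is.finite(max_len), max_len >= 1)
  df <- set$intervals
  keep <- (df$end - df$start) <= max_len
  out <- set
  out$intervals <- df[keep, , drop = FALSE]
  rownames(out$intervals) <- NULL
  out
}

#' Reduce a set to non-overlapping intervals, preferring the smallest
#'
#' Greedy de-overlapping: intervals are visited in order of (length
#' ascending, chrom, start, name); each is accepted iff it overlaps no
#' already-accepted interval. The result is pairwise non-overlapping and a
#' subset of the input, and the operation is idempotent. Where a short
#' element is nested in a longer entry (e.g. a minimal enhancer inside a
#' large tested fragment), the short one survives.
#'
#' @param set An `interval_set`.
#' @return De-overlapped `interval_set`.
#' @export
select_smallest_nonoverlapping <- function(set) {
  df <- set$intervals
  if (nrow(df) <= 1L) return(set)
  len <- df$end - df$start
  o <- radix_order(len, df$chrom, df$start, df$name)
  df <- df[o, , drop = FALSE]
  acc_chrom <- character(0); acc_start <- integer(0); acc_end <- integer(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    same <- acc_chrom == df$chrom[i]
    hit <- any(same & acc_start < df$end[i] & df$start[i] < acc_end)
    if (!hit) {
      keep[i] <- TRUE
      acc_chrom <- c(acc_chrom, df$chrom[i])
      acc_start <- c(acc_start, df$start[i])
      acc_end <- c(acc_end, df$end[i])
    }
  }
  out <- set
  out$intervals <- df[keep, , drop = FALSE]
  o2 <- radix_order(out$intervals$chrom, out$intervals$start,
                    out$intervals$end, out$intervals$name)
  out$intervals <- out$intervals[o2, , drop = FALSE]
  rownames(out$intervals) <- NULL
  out
}

# ---- tissue grouping -------------------------------------------------------

#' Read tissue annotations (interval_name TAB tissue_term, one row per term)
#' @param path TSV path; an optional header line `interval_name\ttissue_term`
#'   is tolerated.
#' @return Data frame with columns `interval_name`, `tissue_term`.
#' @export
read_tissue_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("interval_name", "tissue_term"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) && df$interval_name[1] == "interval_name") df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a tissue-term to group mapping (tissue_term TAB group)
#' @param path TSV path.
#' @return Named character vector: `tissue_term -> group`.
#' @export
read_tissue_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tissue_term", "group"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) && df$tissue_term[1] == "tissue_term") df <- df[-1, , drop = FALSE]
  stats::setNames(df$group, df$tissue_term)
}

#' Partition a set into tissue-specific groups
#'
#' Each interval is placed in every group that any of its annotated tissue
#' terms maps to (multi-membership allowed). Terms absent from
#' `tissue_map` are ignored; annotation rows naming intervals not in `set`
#' produce a warning and are skipped; empty groups are omitted.
#'
#' @param set An `interval_set`.
#' @param annotations Data frame with `interval_name` and `tissue_term`
#'   columns (one row per interval/term pair).
#' @param tissue_map Named character vector mapping tissue terms to group
#'   names; must be non-empty.
#' @return Named list of `interval_set`, one per non-empty group.
#' @export
group_by_tissue <- function(set, annotations, tissue_map) {
  if (!length(tissue_map)) stop("tissue_map must be non-empty")
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  known <- ann$interval_name %in% set$intervals$name
  if (any(!known)) {
    warning(sprintf("%d annotation row(s) name intervals absent from set '%s'; skipped",
                    sum(!known), set$label))
    ann <- ann[known, , drop = FALSE]
  }
  ann$group <- unname(tissue_map[ann$tissue_term])
  ann <- ann[!is.na(ann$group), , drop = FALSE]
  groups <- sort(unique(ann$group))
  out <- list()
  for (g in groups) {
    nms <- unique(ann$interval_name[ann$group == g])
    sub <- set$intervals[set$intervals$name %in% nms, , drop = FALSE]
    if (!nrow(sub)) next
    out[[g]] <- interval_set(sub, label = g,
                             metadata = c(set$metadata, list(tissue_group = g)))
  }
  out
}

# ---- consensus merge -------------------------------------------------------

#' Bundle tracks for consensus merging
#' @param tracks List of `interval_set` (>= 1).
#' @param support_fraction Fraction of tracks that must cover a base for it
#'   to enter the consensus; in (0, 1], default 0.5 ("at least 50%").
#' @return An object of class `track_bundle`.
#' @export
track_bundle <- function(tracks, support_fraction = 0.5) {
  if (!length(tracks)) stop("track_bundle needs at least one track")
  if (!is.numeric(support_fraction) || length(support_fraction) != 1L ||
      support_fraction <= 0 || support_fraction > 1)
    stop("support_fraction must be in (0, 1]")
  structure(list(tracks = tracks, support_fraction = support_fraction),
            class = "track_bundle")
}

# Union-merge the intervals of one data frame (so each track contributes
# coverage at most once per base).
.reduce_df <- function(df) {
  if (nrow(df) <= 1L) return(df[, c("chrom", "start", "end"), drop = FALSE])
  o <- radix_order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  out_chrom <- character(0); out_start <- integer(0); out_end <- integer(0)
  cur_c <- df$chrom[1]; cur_s <- df$start[1]; cur_e <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$chrom[i] == cur_c && df$start[i] <= cur_e) {
      cur_e <- max(cur_e, df$end[i])
    } else {
      out_chrom <- c(out_chrom, cur_c); out_start <- c(out_start, cur_s)
      out_end <- c(out_end, cur_e)
      cur_c <- df$chrom[i]; cur_s <- df$start[i]; cur_e <- df$end[i]
    }
  }
  data.frame(chrom = c(out_chrom, cur_c), start = c(out_start, cur_s),
             end = c(out_end, cur_e), stringsAsFactors = FALSE)
}

#' Merge tracks into a consensus profile under a support threshold
#'
#' Per-base support is the number of tracks covering that base (each track
#' counts once, regardless of internal overlaps). The consensus consists
#' of maximal runs of bases with support >= `ceiling(support_fraction *
#' n_tracks)`, so "at least 50%" of 3 tracks means 2. Output intervals are
#' named `consensus_<k>` in deterministic order; the result is invariant
#' to track order.
#'
#' @param bundle A `track_bundle`, or a plain list of `interval_set` (then
#'   `support_fraction` applies).
#' @param support_fraction Used only when `bundle` is a plain list.
#' @param label Label for the output set.
#' @return An `interval_set` of consensus regions.
#' @export
consensus_merge <- function(bundle, support_fraction = 0.5, label = "consensus") {
  if (!inherits(bundle, "track_bundle"))
    bundle <- track_bundle(bundle, support_fraction)
  n_tracks <- length(bundle$tracks)
  threshold <- ceiling(bundle$support_fraction * n_tracks)
  reduced <- lapply(bundle$tracks, function(s) .reduce_df(s$intervals))
  all_df <- do.call(rbind, reduced)
  if (is.null(all_df) || !nrow(all_df)) return(interval_set(NULL, label))
  pieces <- list()
  for (ch in sort(unique(all_df$chrom))) {
    d <- all_df[all_df$chrom == ch, , drop = FALSE]
    pos <- c(d$start, d$end)
    delta <- c(rep(1L, nrow(d)), rep(-1L, nrow(d)))
    up <- sort(unique(pos))
    dsum <- vapply(split(delta, factor(match(pos, up), levels = seq_along(up))),
                   sum, integer(1))
    supp <- cumsum(dsum)            # support on [up[i], up[i+1])
    if (length(up) < 2L) next
    seg_keep <- supp[-length(supp)] >= threshold
    r <- rle(seg_keep)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (j in which(r$values)) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = ch, start = up[starts_idx[j]],
                   end = up[ends_idx[j] + 1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces)) return(interval_set(NULL, label))
  df <- do.call(rbind, pieces)
  o <- radix_order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  df$name <- paste0("consensus_", seq_len(nrow(df)))
  interval_set(df, label,
               metadata = list(n_tracks = n_tracks,
                               support_fraction = bundle$support_fraction))
}
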
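# Found-vector construction, pairwise phi correlation matrices, and
# within-/between-batch summaries used to expose batch effects: when
# reference sets from the same experiment series recover the same query
# enhancers, their found-vectors correlate strongly even across assay
# types, while sets from different series may recover disjoint enhancers.

#' Score each query enhancer as found (1) or not found (0) in a reference
#'
#' Entry i is 1 iff query interval i overlaps at least one reference
#' interval by at least one basepair — the same contract as
#' [count_overlapping()], so the vector sum equals `n_overlapping`.
#' Order follows the query set's deterministic interval order.
#'
#' @param query Non-empty `interval_set` (common to all vectors compared).
#' @param reference An `interval_set`.
#' @param batch_label Experiment-series label carried alongside (e.g. a
#'   GEO series identifier in real data).
#' @return A list of class `found_vector` with `reference_label`,
#'   `batch_label`, `values` (named 0/1 integer vector).
#' @export
found_vector <- function(query, reference, batch_label = NA_character_) {
  q <- query$intervals
  if (!nrow(q)) stop("empty query set")
  idx <- .make_ref_index(reference$intervals)
  found <- .found_flags(q$chrom, q$start, q$end, idx)
  structure(list(reference_label = reference$label,
                 batch_label = as.character(batch_label),
                 values = stats::setNames(as.integer(found), q$name)),
            class = "found_vector")
}

#' Pairwise correlation matrix of found-vectors
#'
#' Pearson correlation of the 0/1 vectors, which on binary data is the phi
#' coefficient of the corresponding 2x2 contingency table. Pairs involving
#' a constant vector (all found or none found) have undefined correlation
#' and are marked `NA`, never coerced to 0; the diagonal is 1 for every
#' non-constant vector.
#'
#' @param vectors List of >= 2 `found_vector` objects of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `concordance_matrix` with `labels`, `batches`,
#'   and the symmetric correlation matrix `r`.
#' @export
correlation_matrix <- function(vectors, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(vectors) < 2L) stop("need at least two found-vectors")
  lens <- vapply(vectors, function(v) length(v$values), integer(1))
  if (length(unique(lens)) != 1L) stop("found-vectors differ in length")
  labels <- vapply(vectors, function(v) v$reference_label, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "_")
  batches <- vapply(vectors, function(v) v$batch_label, character(1))
  V <- vapply(vectors, function(v) as.numeric(v$values), numeric(lens[1]))
  colnames(V) <- labels
  constant <- apply(V, 2, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(V, method = method))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!constant] <- 1
  structure(list(labels = labels, batches = stats::setNames(batches, labels),
                 r = r, method = method),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("<concordance_matrix: %d reference sets, %d batch(es)>\n",
              length(x$labels), length(unique(x$batches))))
  invisible(x)
}

#' Summarize correlations within or between batches
#'
#' Within-batch summaries (`group_a == group_b`) use off-diagonal pairs
#' only; between-batch summaries use every cross pair. Undefined (`NA`)
#' entries are excluded. The spread is the sample standard deviation over
#' eligible pairs (0 when there is a single pair), matching the
#' "mean r +/- sd" presentation.
#'
#' @param matrix A `concordance_matrix`.
#' @param group_a,group_b Batch labels (`group_b` defaults to `group_a`).
#' @return List with `mean_r`, `sd_r`, `n_pairs`.
#' @export
group_summary <- function(matrix, group_a, group_b = group_a) {
  b <- matrix$batches
  ia <- which(b == group_a); ib <- which(b == group_b)
  if (!length(ia)) stop("unknown batch label: ", group_a)
  if (!length(ib)) stop("unknown batch label: ", group_b)
  if (group_a == group_b) {
    if (length(ia) < 2L) stop("within-batch summary needs >= 2 members (no off-diagonal pairs)")
    pairs <- utils::combn(ia, 2)
    vals <- matrix$r[t(pairs)]
  } else {
    vals <- as.vector(matrix$r[ia, ib, drop = FALSE])
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("zero eligible (defined) correlation pairs")
  list(mean_r = mean(vals),
       sd_r = if (length(vals) == 1L) 0 else stats::sd(vals),
       n_pairs = length(vals))
}

#' Export a concordance matrix as TSV (plus batch-label sidecar)
#'
#' Writes a square TSV with header labels and row names, `NA` for
#' undefined entries, and a two-column sidecar TSV (`label`, `batch`) at
#' `batch_path`. Optionally renders a heatmap (rows/columns ordered by
#' batch then label) if the pheatmap package is available; the image is
#' cosmetic only.
#'
#' @param matrix A `concordance_matrix`.
#' @param path Output TSV path.
#' @param batch_path Sidecar path (default: `<path minus extension>_batches.tsv`).
#' @param heatmap_path Optional PNG path; `NULL` (default) skips plotting.
#' @return Invisibly, `path`.
#' @export
export_matrix <- function(matrix, path, batch_path = NULL, heatmap_path = NULL) {
  if (is.null(batch_path))
    batch_path <- paste0(tools::file_path_sans_ext(path), "_batches.tsv")
  m <- matrix$r
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  utils::write.table(data.frame(label = matrix$labels,
                                batch = unname(matrix$batches[matrix$labels])),
                     batch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(heatmap_path) && requireNamespace("pheatmap", quietly = TRUE)) {
    o <- radix_order(unname(matrix$batches[matrix$labels]), matrix$labels)
    grDevices::png(heatmap_path, width = 900, height = 800)
    pheatmap::pheatmap(m[o, o], cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  invisible(path)
}

#' Read back a concordance matrix TSV written by [export_matrix()]
#' @param path Matrix TSV path.
#' @param batch_path Sidecar path (same default as [export_matrix()]).
#' @return A `concordance_matrix`.
#' @export
read_matrix <- function(path, batch_path = NULL) {
  if (is.null(batch_path))
    batch_path <- paste0(tools::file_path_sans_ext(path), "_batches.tsv")
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  b <- utils::read.table(batch_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  structure(list(labels = rownames(m),
                 batches = stats::setNames(b$batch, b$label)[rownames(m)],
                 r = m, method = "pearson"),
            class = "concordance_matrix")
}
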
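# Interval data model and BED / chrom.sizes I/O.
#
# Coordinates are BED-standard 0-based half-open throughout: an interval
# [start, end) covers bases start .. end-1, and length == end - start.
# Strand is ignored everywhere.

#' Construct a single genomic interval
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp), non-negative.
#' @param end 0-based exclusive end (bp); must exceed `start`.
#' @param name Identifier; `NA` allowed.
#' @return A list of class `interval`.
#' @export
interval <- function(chrom, start, end, name = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("interval coordinates must be integers")
  if (start < 0) stop("interval start must be non-negative")
  if (start >= end) stop("interval must have start < end (zero-length rejected)")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 name = as.character(name)),
            class = "interval")
}

#' Do two intervals share at least one basepair?
#'
#' Half-open overlap test: adjacency (`a$end == b$start`) is not overlap,
#' but a single shared basepair is. This is the scoring rule used for all
#' set comparisons in the package.
#'
#' @param a,b `interval` objects (or lists with chrom/start/end fields).
#' @return Logical scalar.
#' @export
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# ---- interval sets ---------------------------------------------------------

.validate_interval_df <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(df)))
  if (nrow(df)) {
    if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
      stop("non-finite interval coordinates")
    if (any(df$start < 0)) stop("negative interval start")
    if (any(df$start >= df$end)) stop("zero- or negative-length interval")
  }
  df
}

#' Construct an interval set
#'
#' An `interval_set` is a labelled, deterministically ordered collection of
#' named intervals: rows are sorted by (chrom, start, end, name) using
#' C-locale radix order, and duplicate names are disambiguated with a
#' numeric suffix so that names are unique within the set.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (missing names are generated as `<label>_<row>`).
#' @param label Set identifier.
#' @param metadata Free-form key/value list (e.g. assay type, series id).
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(intervals, label, metadata = list()) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), name = character(),
                            stringsAsFactors = FALSE)
  } else {
    intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
    if (!"name" %in% names(intervals) || all(is.na(intervals$name)))
      intervals$name <- paste0(label, "_", seq_len(nrow(intervals)))
    miss <- is.na(intervals$name) | intervals$name == ""
    intervals$name[miss] <- paste0(label, "_", which(miss))
    intervals <- intervals[, c("chrom", "start", "end", "name")]
    intervals$chrom <- as.character(intervals$chrom)
    intervals$start <- as.integer(intervals$start)
    intervals$end <- as.integer(intervals$end)
    intervals$name <- as.character(intervals$name)
  }
  .validate_interval_df(intervals)
  o <- radix_order(intervals$chrom, intervals$start, intervals$end, intervals$name)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  intervals$name <- make.unique(intervals$name, sep = "_")
  structure(list(label = as.character(label), intervals = intervals,
                 metadata = metadata),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set '%s': %d intervals on %d chromosome(s)>\n",
              x$label, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' @export
length.interval_set <- function(x) nrow(x$intervals)

#' Number of intervals in a set
#' @param set An `interval_set`.
#' @return Integer count.
#' @export
n_intervals <- function(set) nrow(set$intervals)

#' Interval lengths (bp) of a set
#' @param set An `interval_set`.
#' @return Integer vector of `end - start`.
#' @export
interval_lengths <- function(set) set$intervals$end - set$intervals$start

# ---- BED I/O ---------------------------------------------------------------

#' Read a BED file into an interval set
#'
#' Accepts 3+ tab-separated columns (chrom, start, end, name, ...); columns
#' beyond the fourth are ignored. `browser`, `track` and `#` comment lines
#' and blank lines are skipped. Missing names are generated as
#' `<label>_<line#>`. Malformed coordinates raise an error naming the
#' offending line.
#'
#' @param path Path to a BED file.
#' @param label Label for the resulting set (default: file basename).
#' @return An `interval_set`.
#' @export
read_bed <- function(path, label = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$|^browser\\b|^track\\b|^#", lines)
  idx <- which(keep)
  if (!length(idx)) return(interval_set(NULL, label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  chrom <- character(length(idx)); start <- integer(length(idx))
  end <- integer(length(idx)); name <- character(length(idx))
  for (k in seq_along(idx)) {
    f <- fields[[k]]
    ln <- idx[k]
    if (length(f) < 3L) stop_line(ln, "fewer than 3 tab-separated fields")
    if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3]))
      stop_line(ln, sprintf("non-integer coordinates '%s'/'%s'", f[2], f[3]))
    s <- as.integer(f[2]); e <- as.integer(f[3])
    if (s >= e) stop_line(ln, sprintf("start %d >= end %d (zero-length or inverted)", s, e))
    chrom[k] <- f[1]; start[k] <- s; end[k] <- e
    name[k] <- if (length(f) >= 4L && nzchar(f[4])) f[4] else paste0(label, "_", ln)
  }
  interval_set(data.frame(chrom = chrom, start = start, end = end, name = name,
                          stringsAsFactors = FALSE), label)
}

#' Write an interval set as 4-column BED
#'
#' Emits tab-separated chrom/start/end/name rows in the set's deterministic
#' order, so that `read_bed(write_bed(S))` reproduces `S` exactly.
#'
#' @param set An `interval_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(set, path) {
  df <- set$intervals
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$name)
  writeLines(lines, path)
  invisible(path)
}

# ---- genome spec -----------------------------------------------------------

#' Construct a genome specification
#'
#' A genome is just a chromosome-name to length map; it defines the space
#' over which intervals are shuffled when building the permutation null.
#'
#' @param chrom_lengths Named numeric vector of positive chromosome lengths (bp).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths) {
  if (!length(chrom_lengths) || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a non-empty named vector")
  if (anyDuplicated(names(chrom_lengths))) stop("duplicate chromosome name")
  lens <- as.numeric(chrom_lengths)
  if (any(!is.finite(lens)) || any(lens <= 0) || any(lens != floor(lens)))
    stop("chromosome lengths must be positive integers")
  structure(list(chrom_lengths = stats::setNames(lens, names(chrom_lengths))),
            class = "genome_spec")
}

#' Total genome length (bp)
#' @param genome A `genome_spec`.
#' @return Numeric scalar.
#' @export
genome_total_length <- function(genome) sum(genome$chrom_lengths)

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec: %d chromosome(s), %.0f bp total>\n",
              length(x$chrom_lengths), genome_total_length(x)))
  invisible(x)
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length. Duplicate names
#' or non-positive lengths are errors.
#'
#' @param path Path to a chrom.sizes file.
#' @return A `genome_spec`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, function(f) {
    if (length(f) < 2L) stop("chrom.sizes line needs two tab-separated columns")
    f[1]
  }, character(1))
  ln <- vapply(fields, function(f) {
    if (!grepl("^[0-9]+$", f[2])) stop("non-integer chromosome length: ", f[2])
    as.numeric(f[2])
  }, numeric(1))
  genome_spec(stats::setNames(ln, nm))
}

#' Write a genome specification as chrom.sizes
#' @param genome A `genome_spec`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  writeLines(sprintf("%s\t%.0f", names(genome$chrom_lengths),
                     genome$chrom_lengths), path)
  invisible(path)
}

# Check every interval fits on the genome; used by shuffle and the
# synthetic generator.
.check_on_genome <- function(set, genome) {
  df <- set$intervals
  if (!nrow(df)) return(invisible(TRUE))
  unknown <- setdiff(unique(df$chrom), names(genome$chrom_lengths))
  if (length(unknown))
    stop("intervals on chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  if (any(df$end > genome$chrom_lengths[df$chrom]))
    stop("interval extends beyond chromosome end")
  invisible(TRUE)
}
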
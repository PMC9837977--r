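# Synthetic enhancer universe with known ground truth.
#
# The generator emulates the study design the package analyses: a genome
# carrying a fixed set of true enhancers; a reporter-gene-style query set
# that recovers each true enhancer with some sensitivity, with jittered
# boundaries and a complement of false positives; and chromatin-assay-style
# reference sets organized into experiment-series batches, where each batch
# has a latent detectable subset of the truth (the batch effect) and each
# assay within a batch samples that subset with its own sensitivity plus
# false positives. Every downstream stage therefore has a recoverable truth.

#' Configuration for a synthetic enhancer world
#'
#' Defaults describe the package's reference study conditions: a
#' 2-chromosome, 2-Mb genome; 500 non-overlapping true enhancers of
#' 200-1000 bp (typical enhancers are hundreds of bp); a reporter set with
#' sensitivity 0.7, 100 false positives and 50 bp boundary jitter; and two
#' disjoint experiment-series batches, each a latent detectable subset of
#' 40% of the truth assayed by 5 replicate tracks at sensitivity 0.9 with
#' 100 false positives each.
#'
#' @param genome A `genome_spec`.
#' @param n_true Number of true enhancers.
#' @param length_range Integer pair: min/max enhancer length (bp).
#' @param reporter List: `sensitivity` in \[0,1\], `n_false_positives`,
#'   `boundary_jitter_bp`.
#' @param batches List of batches, each a list with `batch_label`,
#'   `latent_fraction` in (0,1\], `n_assays`, `assay_sensitivity` in \[0,1\],
#'   `assay_fp_count`.
#' @param batch_overlap `"disjoint"` (latent subsets sampled without
#'   replacement across batches; their sizes must fit in `n_true`) or
#'   `"independent"` (each batch samples its subset independently).
#' @param master_seed Integer; all randomness derives from it.
#' @return A validated list of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(
    genome = genome_spec(c(chr1 = 1e6, chr2 = 1e6)),
    n_true = 500,
    length_range = c(200L, 1000L),
    reporter = list(sensitivity = 0.7, n_false_positives = 100,
                    boundary_jitter_bp = 50),
    batches = list(
      list(batch_label = "seriesA", latent_fraction = 0.4, n_assays = 5,
           assay_sensitivity = 0.9, assay_fp_count = 100),
      list(batch_label = "seriesB", latent_fraction = 0.4, n_assays = 5,
           assay_sensitivity = 0.9, assay_fp_count = 100)),
    batch_overlap = c("disjoint", "independent"),
    master_seed = 1L) {
  batch_overlap <- match.arg(batch_overlap)
  stopifnot(inherits(genome, "genome_spec"), n_true >= 1,
            length(length_range) == 2L, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  pr <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!pr(reporter$sensitivity)) stop("reporter$sensitivity must be in [0, 1]")
  if (reporter$n_false_positives < 0 || reporter$boundary_jitter_bp < 0)
    stop("reporter counts/jitter must be non-negative")
  for (b in batches) {
    if (!pr(b$assay_sensitivity)) stop("assay_sensitivity must be in [0, 1]")
    if (!is.numeric(b$latent_fraction) || b$latent_fraction <= 0 ||
        b$latent_fraction > 1)
      stop("latent_fraction must be in (0, 1]")
    if (b$n_assays < 1 || b$assay_fp_count < 0) stop("invalid batch assay counts")
  }
  if (anyDuplicated(vapply(batches, `[[`, character(1), "batch_label")))
    stop("duplicate batch_label")
  if (n_true * length_range[2] > 0.5 * genome_total_length(genome))
    stop("placement infeasible: true enhancers would cover over half the genome")
  if (batch_overlap == "disjoint" &&
      sum(vapply(batches, function(b) round(b$latent_fraction * n_true),
                 numeric(1))) > n_true)
    stop("disjoint latent subsets exceed n_true")
  reporter <- list(sensitivity = as.numeric(reporter$sensitivity),
                   n_false_positives = as.integer(reporter$n_false_positives),
                   boundary_jitter_bp = as.integer(reporter$boundary_jitter_bp))
  batches <- lapply(batches, function(b)
    list(batch_label = as.character(b$batch_label),
         latent_fraction = as.numeric(b$latent_fraction),
         n_assays = as.integer(b$n_assays),
         assay_sensitivity = as.numeric(b$assay_sensitivity),
         assay_fp_count = as.integer(b$assay_fp_count)))
  structure(list(genome = genome, n_true = as.integer(n_true),
                 length_range = as.integer(length_range), reporter = reporter,
                 batches = batches, batch_overlap = batch_overlap,
                 master_seed = as.integer(master_seed)),
            class = "synthetic_world_config")
}

# Place n intervals with lengths uniform in length_range. Placements are
# uniform over all valid (chrom, start); candidates overlapping `avoid_index`
# are rejected, and with self_nonoverlap the accepted set stays pairwise
# non-overlapping. Rejection sampling with a hard attempt bound.
.place_intervals <- function(n, length_range, genome, avoid_index = NULL,
                             self_nonoverlap = FALSE, max_attempts = NULL) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  if (is.null(max_attempts)) max_attempts <- 1000 * n
  acc_chrom <- character(0); acc_start <- numeric(0); acc_end <- numeric(0)
  attempts <- 0
  while (length(acc_chrom) < n) {
    batch_n <- max(2L * (n - length(acc_chrom)), 16L)
    attempts <- attempts + batch_n
    if (attempts > max_attempts)
      stop("infeasible placement: attempt bound exceeded")
    len <- sample.int(length_range[2] - length_range[1] + 1L, batch_n,
                      replace = TRUE) + length_range[1] - 1L
    pl <- .draw_placements(.placement_table(len, genome))
    ok <- rep(TRUE, batch_n)
    if (!is.null(avoid_index))
      ok <- !.found_flags(pl$chrom, pl$start, pl$end, avoid_index)
    for (i in which(ok)) {
      if (length(acc_chrom) >= n) break
      if (self_nonoverlap && length(acc_chrom)) {
        same <- acc_chrom == pl$chrom[i]
        if (any(same & acc_start < pl$end[i] & pl$start[i] < acc_end)) next
      }
      acc_chrom <- c(acc_chrom, pl$chrom[i])
      acc_start <- c(acc_start, pl$start[i])
      acc_end <- c(acc_end, pl$end[i])
    }
  }
  data.frame(chrom = acc_chrom, start = as.integer(acc_start),
             end = as.integer(acc_end), stringsAsFactors = FALSE)
}

# Jitter interval endpoints by uniform integers in [-j, j], clamping to the
# chromosome and enforcing length >= 1.
.jitter_df <- function(df, jitter, genome) {
  if (!nrow(df) || jitter == 0) return(df)
  n <- nrow(df)
  ds <- floor(stats::runif(n) * (2 * jitter + 1)) - jitter
  de <- floor(stats::runif(n) * (2 * jitter + 1)) - jitter
  cl <- genome$chrom_lengths[df$chrom]
  s <- pmax(0, pmin(df$start + ds, cl - 1))
  e <- pmax(1, pmin(df$end + de, cl))
  bad <- e <= s
  e[bad] <- pmin(s[bad] + 1, cl[bad])
  s[bad] <- e[bad] - 1
  df$start <- as.integer(s); df$end <- as.integer(e)
  df
}

#' Generate a synthetic enhancer world
#'
#' Deterministic given the config's `master_seed`: identical configs give
#' bit-identical worlds. See [synthetic_world_config()] for the generative
#' model. Reporter true positives keep the name of the true enhancer they
#' derive from; false positives are placed avoiding all true enhancers so
#' the sensitivity/false-positive decomposition stays clean.
#'
#' @param config A `synthetic_world_config`.
#' @return A list of class `synthetic_world`: `genome`, `config`,
#'   `true_enhancers`, `reporter_set`, `assay_sets` (each with
#'   `batch_label` metadata), and `truth_table` (one row per true
#'   enhancer; logical membership column per generated set plus
#'   `latent_<batch>` columns for the latent detectable subsets).
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  genome <- config$genome
  with_seed(config$master_seed, {
    truth_df <- .place_intervals(config$n_true, config$length_range, genome,
                                 self_nonoverlap = TRUE)
    truth_df$name <- sprintf("enh_%05d", seq_len(config$n_true))
    true_enhancers <- interval_set(truth_df, "true_enhancers")
    truth_index <- .make_ref_index(truth_df)
    truth_names <- true_enhancers$intervals$name   # deterministic order

    truth_table <- data.frame(name = truth_names, stringsAsFactors = FALSE)

    # reporter: sensitivity, boundary jitter, false positives
    td <- true_enhancers$intervals
    keep <- stats::runif(config$n_true) < config$reporter$sensitivity
    rep_tp <- .jitter_df(td[keep, c("chrom", "start", "end", "name")],
                         config$reporter$boundary_jitter_bp, genome)
    rep_fp <- .place_intervals(config$reporter$n_false_positives,
                               config$length_range, genome,
                               avoid_index = truth_index)
    if (nrow(rep_fp)) rep_fp$name <- sprintf("rep_fp_%04d", seq_len(nrow(rep_fp)))
    reporter_set <- interval_set(rbind(rep_tp, rep_fp), "reporter")
    truth_table$reporter <- keep

    # batches: latent detectable subsets, then per-assay detection + FPs
    assay_sets <- list()
    pool <- seq_len(config$n_true)
    for (b in config$batches) {
      size <- round(b$latent_fraction * config$n_true)
      if (config$batch_overlap == "disjoint") {
        latent <- sort(sample(pool, size))
        pool <- setdiff(pool, latent)
      } else {
        latent <- sort(sample.int(config$n_true, size))
      }
      truth_table[[paste0("latent_", b$batch_label)]] <-
        seq_len(config$n_true) %in% latent
      for (a in seq_len(b$n_assays)) {
        det <- latent[stats::runif(length(latent)) < b$assay_sensitivity]
        ad <- td[det, c("chrom", "start", "end", "name"), drop = FALSE]
        afp <- .place_intervals(b$assay_fp_count, config$length_range, genome,
                                avoid_index = truth_index)
        if (nrow(afp))
          afp$name <- sprintf("%s_a%d_fp_%04d", b$batch_label, a,
                              seq_len(nrow(afp)))
        lab <- sprintf("%s_assay%d", b$batch_label, a)
        assay_sets[[lab]] <- interval_set(
          rbind(ad, afp), lab, metadata = list(batch_label = b$batch_label))
        truth_table[[lab]] <- seq_len(config$n_true) %in% det
      }
    }
    structure(list(genome = genome, config = config,
                   true_enhancers = true_enhancers,
                   reporter_set = reporter_set,
                   assay_sets = assay_sets,
                   truth_table = truth_table),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d true enhancers, reporter %d, %d assay set(s)>\n",
              n_intervals(x$true_enhancers), n_intervals(x$reporter_set),
              length(x$assay_sets)))
  invisible(x)
}

#' Closed-form expectation of the reporter-vs-assay overlap fraction
#'
#' For a reporter true positive, being found in one assay of batch `batch`
#' requires membership in the batch's latent subset (probability
#' `round(q * n_true) / n_true`) and detection by the assay (probability
#' `s_a`). A reporter false positive overlaps the assay approximately with
#' the assay's genomic cover fraction. The returned value is the mixture
#' expectation, in percent; the approximation assumes boundary jitter
#' small relative to enhancer length.
#'
#' @param config A `synthetic_world_config`.
#' @param batch Batch index (default 1).
#' @return Expected overlap percent (numeric, not rounded).
#' @export
expected_overlap_fraction <- function(config, batch = 1L) {
  b <- config$batches[[batch]]
  q_eff <- round(b$latent_fraction * config$n_true) / config$n_true
  p_tp <- q_eff * b$assay_sensitivity
  mean_len <- mean(config$length_range)
  cover <- (round(b$latent_fraction * config$n_true) * b$assay_sensitivity +
              b$assay_fp_count) * mean_len / genome_total_length(config$genome)
  e_tp <- config$reporter$sensitivity * config$n_true
  n_fp <- config$reporter$n_false_positives
  if (e_tp + n_fp == 0) stop("reporter set empty in expectation")
  100 * (e_tp * p_tp + n_fp * min(cover, 1)) / (e_tp + n_fp)
}

#' Generate a world with tissue-annotated true enhancers
#'
#' Extends [make_world()] with a tissue structure: each true enhancer is
#' assigned one tissue group uniformly (plus, with probability
#' `multi_prob`, a second distinct group, since real enhancers may be
#' active in several tissues). Annotation rows (`interval_name`,
#' `tissue_term`) and a term-to-group map are emitted in the shape
#' consumed by [group_by_tissue()], so the grouping step can be validated
#' against the generator's own partition.
#'
#' @param config A `synthetic_world_config`.
#' @param n_tissues Number of tissue groups (>= 1).
#' @param multi_prob Probability of a second tissue membership (default 0:
#'   disjoint partition).
#' @return A `synthetic_world` with extra fields `annotations`,
#'   `tissue_map`, `tissue_groups` (named list of true-enhancer names).
#' @export
make_tissue_world <- function(config, n_tissues, multi_prob = 0) {
  stopifnot(n_tissues >= 1, multi_prob >= 0, multi_prob <= 1)
  world <- make_world(config)
  nms <- world$true_enhancers$intervals$name
  with_seed(derive_seed(config$master_seed, 424243L), {
    g1 <- sample.int(n_tissues, length(nms), replace = TRUE)
    rows <- data.frame(interval_name = nms,
                       tissue_term = sprintf("term_%02d", g1),
                       stringsAsFactors = FALSE)
    if (n_tissues > 1 && multi_prob > 0) {
      extra <- which(stats::runif(length(nms)) < multi_prob)
      if (length(extra)) {
        g2 <- vapply(g1[extra], function(g)
          sample(setdiff(seq_len(n_tissues), g), 1L), integer(1))
        rows <- rbind(rows, data.frame(interval_name = nms[extra],
                                       tissue_term = sprintf("term_%02d", g2),
                                       stringsAsFactors = FALSE))
      }
    }
    rows <- rows[radix_order(rows$interval_name, rows$tissue_term), , drop = FALSE]
    rownames(rows) <- NULL
    tissue_map <- stats::setNames(sprintf("tissue_%02d", seq_len(n_tissues)),
                                  sprintf("term_%02d", seq_len(n_tissues)))
    groups <- lapply(stats::setNames(seq_len(n_tissues),
                                     sprintf("tissue_%02d", seq_len(n_tissues))),
                     function(g) sort(unique(rows$interval_name[
                       rows$tissue_term == sprintf("term_%02d", g)])))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    world$annotations <- rows
    world$tissue_map <- tissue_map
    world$tissue_groups <- groups
  })
  world
}

#' Export a synthetic world as a plain-text bundle
#'
#' Writes one BED per set, a chrom.sizes file, the truth table as TSV, a
#' `sets.tsv` manifest (role, label, batch, file), tissue annotations and
#' map when present, and the config echoed as JSON. Byte-deterministic.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
export_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(world$genome, file.path(dir, "genome.chrom.sizes"))
  write_bed(world$true_enhancers, file.path(dir, "true_enhancers.bed"))
  write_bed(world$reporter_set, file.path(dir, "reporter.bed"))
  manifest <- data.frame(
    role = c("truth", "reporter"), label = c("true_enhancers", "reporter"),
    batch = c(NA_character_, NA_character_),
    file = c("true_enhancers.bed", "reporter.bed"), stringsAsFactors = FALSE)
  for (lab in names(world$assay_sets)) {
    f <- paste0(lab, ".bed")
    write_bed(world$assay_sets[[lab]], file.path(dir, f))
    manifest <- rbind(manifest, data.frame(
      role = "assay", label = lab,
      batch = world$assay_sets[[lab]]$metadata$batch_label,
      file = f, stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(dir, "sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$truth_table, file.path(dir, "truth_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(world$annotations)) {
    utils::write.table(world$annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(tissue_term = names(world$tissue_map),
                                  group = unname(world$tissue_map)),
                       file.path(dir, "tissue_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- world$config
  echo <- list(genome = as.list(cfg$genome$chrom_lengths),
               n_true = cfg$n_true, length_range = cfg$length_range,
               reporter = cfg$reporter, batches = cfg$batches,
               batch_overlap = cfg$batch_overlap,
               master_seed = cfg$master_seed)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Reload a world bundle written by [export_world()]
#'
#' Reconstructs the genome, sets (with batch metadata from the manifest)
#' and truth table; the returned object is interchangeable with a fresh
#' [make_world()] result for downstream analysis.
#'
#' @param dir Bundle directory.
#' @return A `synthetic_world` (config restored from the JSON echo).
#' @export
read_world <- function(dir) {
  genome <- read_genome(file.path(dir, "genome.chrom.sizes"))
  manifest <- utils::read.table(file.path(dir, "sets.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  config <- synthetic_world_config(
    genome = genome_spec(unlist(cfg_raw$genome)),
    n_true = cfg_raw$n_true, length_range = cfg_raw$length_range,
    reporter = as.list(cfg_raw$reporter),
    batches = if (is.data.frame(cfg_raw$batches))
      lapply(seq_len(nrow(cfg_raw$batches)), function(i) as.list(cfg_raw$batches[i, ]))
    else cfg_raw$batches,
    batch_overlap = cfg_raw$batch_overlap, master_seed = cfg_raw$master_seed)
  assay_rows <- manifest[manifest$role == "assay", , drop = FALSE]
  assay_sets <- list()
  for (i in seq_len(nrow(assay_rows))) {
    s <- read_bed(file.path(dir, assay_rows$file[i]), assay_rows$label[i])
    s$metadata$batch_label <- assay_rows$batch[i]
    assay_sets[[assay_rows$label[i]]] <- s
  }
  world <- list(genome = genome, config = config,
                true_enhancers = read_bed(file.path(dir, "true_enhancers.bed"),
                                          "true_enhancers"),
                reporter_set = read_bed(file.path(dir, "reporter.bed"),
                                        "reporter"),
                assay_sets = assay_sets,
                truth_table = utils::read.table(file.path(dir, "truth_table.tsv"),
                                                sep = "\t", header = TRUE,
                                                stringsAsFactors = FALSE))
  ann_path <- file.path(dir, "annotations.tsv")
  if (file.exists(ann_path)) {
    world$annotations <- utils::read.table(ann_path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE)
    tm <- utils::read.table(file.path(dir, "tissue_map.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    world$tissue_map <- stats::setNames(tm$group, tm$tissue_term)
  }
  structure(world, class = "synthetic_world")
}
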
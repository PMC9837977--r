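# Orchestration of the three analyses: pairwise overlap comparison with
# permutation significance, found-vector concordance across batches, and
# synthetic-world generation. All outputs are plain text (TSV + JSON) and
# byte-deterministic for a fixed seed; the diagnostic log is the only
# artifact carrying wall-clock timestamps.

.as_genome <- function(x) {
  if (inherits(x, "genome_spec")) x else read_genome(x)
}

.as_set <- function(x, label) {
  if (inherits(x, "interval_set")) x else read_bed(x, label)
}

.logger <- function(path, timestamps = TRUE) {
  con <- file(path, open = "wt")
  list(log = function(...) {
    msg <- paste0(...)
    if (timestamps)
      msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", msg)
    writeLines(msg, con)
  }, close = function() close(con))
}

#' Validate an analysis configuration
#'
#' @param genome `genome_spec` or chrom.sizes path.
#' @param queries Named list of `interval_set` objects or BED paths.
#' @param references Named list of `interval_set` objects or BED paths.
#' @param batches Optional named character vector mapping reference labels
#'   to batch (experiment-series) labels; required by [run_correlate()].
#' @param max_len Optional length cutoff (bp) applied to each query set.
#' @param deoverlap Apply [select_smallest_nonoverlapping()] to each query
#'   after length filtering (the standard preparation order).
#' @param n_perm Permutations per test (>= 2; default 500).
#' @param alpha Family-wise significance level (default 0.01).
#' @param bonferroni_m Family size for the Bonferroni correction; default
#'   `NULL` means the number of comparisons in the run.
#' @param seed Master seed; every source of randomness derives from it.
#' @param out_dir Output directory.
#' @param per_chrom Restrict shuffling to each interval's own chromosome.
#' @param log_timestamps Write ISO timestamps in the log (default `TRUE`).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(genome, queries, references, batches = NULL,
                            max_len = NULL, deoverlap = FALSE, n_perm = 500,
                            alpha = 0.01, bonferroni_m = NULL, seed = 1L,
                            out_dir = ".", per_chrom = FALSE,
                            log_timestamps = TRUE) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(max_len) && max_len < 1) stop("max_len must be >= 1")
  if (!is.null(bonferroni_m) && bonferroni_m < 1) stop("bonferroni_m must be >= 1")
  if (is.null(names(queries)) || is.null(names(references)))
    stop("queries and references must be named")
  structure(list(genome = genome, queries = queries, references = references,
                 batches = batches, max_len = max_len, deoverlap = deoverlap,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 bonferroni_m = bonferroni_m, seed = as.integer(seed),
                 out_dir = out_dir, per_chrom = per_chrom,
                 log_timestamps = log_timestamps),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON or YAML
#'
#' File values are passed to [analysis_config()] unchanged, so set entries
#' are interpreted as BED paths (relative to the config file's directory).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  fix <- function(x) {
    stats::setNames(lapply(x, function(p)
      if (is.character(p) && !file.exists(p)) file.path(base, p) else p),
      names(x))
  }
  raw$queries <- fix(as.list(raw$queries))
  raw$references <- fix(as.list(raw$references))
  if (!is.null(raw$batches)) raw$batches <- unlist(raw$batches)
  if (is.character(raw$genome) && !file.exists(raw$genome))
    raw$genome <- file.path(base, raw$genome)
  do.call(analysis_config, raw)
}

.load_queries <- function(config, log) {
  out <- list()
  for (ql in names(config$queries)) {
    qs <- .as_set(config$queries[[ql]], ql)
    log(sprintf("query '%s': %d intervals pre-filter", ql, n_intervals(qs)))
    if (!is.null(config$max_len)) {
      qs <- filter_by_length(qs, config$max_len)
      log(sprintf("query '%s': %d intervals after length filter (<= %d bp)",
                  ql, n_intervals(qs), as.integer(config$max_len)))
    }
    if (isTRUE(config$deoverlap)) {
      qs <- select_smallest_nonoverlapping(qs)
      log(sprintf("query '%s': %d intervals after de-overlap", ql, n_intervals(qs)))
    }
    out[[ql]] <- qs
  }
  out
}

#' Run all pairwise overlap comparisons with permutation significance
#'
#' For every (query, reference) pair: length filter and de-overlap the
#' query as configured, count overlapping query intervals, run the
#' permutation test, and classify against the Bonferroni-adjusted alpha
#' (family size = number of pairs unless `bonferroni_m` overrides it).
#' A failing pair is logged and skipped; the run continues. Writes
#' `compare_report.tsv`, `compare_report.json` and `compare.log` in
#' `out_dir`.
#'
#' @param config An `analysis_config` (or list of its arguments).
#' @return Invisibly, the report data frame.
#' @export
run_compare <- function(config) {
  if (!inherits(config, "analysis_config")) config <- do.call(analysis_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lg <- .logger(file.path(config$out_dir, "compare.log"), config$log_timestamps)
  on.exit(lg$close())
  lg$log(sprintf("run_compare: seed %d, n_perm %d, alpha %g",
                 config$seed, config$n_perm, config$alpha))
  genome <- .as_genome(config$genome)
  queries <- .load_queries(config, lg$log)
  refs <- stats::setNames(lapply(names(config$references), function(rl)
    .as_set(config$references[[rl]], rl)), names(config$references))
  n_pairs <- length(queries) * length(refs)
  m <- config$bonferroni_m %||% n_pairs
  alpha_adj <- bonferroni_alpha(config$alpha, m)
  lg$log(sprintf("%d comparison(s); Bonferroni m = %d, adjusted alpha = %g",
                 n_pairs, m, alpha_adj))
  rows <- list()
  k <- 0L
  for (ql in names(queries)) for (rl in names(refs)) {
    k <- k + 1L
    row <- tryCatch({
      ov <- count_overlapping(queries[[ql]], refs[[rl]])
      pt <- permutation_test(queries[[ql]], refs[[rl]], genome,
                             n_perm = config$n_perm,
                             rng_seed = derive_seed(config$seed, 10000L + k),
                             alpha_adjusted = alpha_adj,
                             per_chrom = config$per_chrom)
      data.frame(query_label = ql, reference_label = rl,
                 n_query = ov$n_query, n_overlapping = ov$n_overlapping,
                 fraction_pct = percent(ov$n_overlapping, ov$n_query),
                 perm_mean = pt$perm_mean, perm_sd = pt$perm_sd,
                 z = pt$z, p_two_tailed = pt$p_two_tailed,
                 alpha_adjusted = alpha_adj,
                 classification = pt$classification,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      lg$log(sprintf("pair '%s' vs '%s' FAILED: %s", ql, rl, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) {
      lg$log(sprintf("pair '%s' vs '%s': %d/%d found, z = %s, %s",
                     ql, rl, row$n_overlapping, row$n_query,
                     ifelse(is.na(row$z), "NA", sprintf("%.3f", row$z)),
                     row$classification))
      rows[[k]] <- row
    }
  }
  report <- do.call(rbind, rows)
  utils::write.table(report, file.path(config$out_dir, "compare_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "compare_report.json"),
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the found-vector concordance analysis
#'
#' Builds one found-vector per reference set over a common query set,
#' computes the pairwise phi correlation matrix, and summarizes every
#' within- and between-batch cell (mean r, sample sd, n pairs). Batches
#' with a single member get an `NA` within-batch row with a warning.
#' Writes `concordance_matrix.tsv` (+ `_batches.tsv` sidecar),
#' `group_summary.tsv`, `group_summary.json` and `correlate.log`.
#'
#' @param config An `analysis_config` with >= 2 references and a `batches`
#'   mapping.
#' @return Invisibly, a list with the `concordance_matrix` and the summary
#'   data frame.
#' @export
run_correlate <- function(config) {
  if (!inherits(config, "analysis_config")) config <- do.call(analysis_config, config)
  if (length(config$references) < 2L) stop("run_correlate needs >= 2 reference sets")
  if (is.null(config$batches)) stop("run_correlate needs a reference -> batch mapping")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lg <- .logger(file.path(config$out_dir, "correlate.log"), config$log_timestamps)
  on.exit(lg$close())
  queries <- .load_queries(config, lg$log)
  query <- queries[[1L]]
  vectors <- lapply(names(config$references), function(rl) {
    ref <- .as_set(config$references[[rl]], rl)
    fv <- found_vector(query, ref, batch_label = config$batches[[rl]])
    lg$log(sprintf("reference '%s' (batch %s): %d/%d query enhancers found",
                   rl, fv$batch_label, sum(fv$values), length(fv$values)))
    fv
  })
  n_nonconst <- sum(vapply(vectors, function(v) stats::sd(v$values) > 0, logical(1)))
  if (n_nonconst < 2L) stop("fewer than 2 non-constant found-vectors: correlation undefined")
  cm <- correlation_matrix(vectors)
  export_matrix(cm, file.path(config$out_dir, "concordance_matrix.tsv"))
  batches <- sort(unique(unname(cm$batches)))
  rows <- list()
  for (i in seq_along(batches)) for (j in i:length(batches)) {
    a <- batches[i]; b <- batches[j]
    s <- tryCatch(group_summary(cm, a, b), error = function(e) {
      warning(sprintf("group summary %s/%s unavailable: %s", a, b,
                      conditionMessage(e)))
      list(mean_r = NA_real_, sd_r = NA_real_, n_pairs = 0L)
    })
    rows[[length(rows) + 1L]] <- data.frame(
      batch_a = a, batch_b = b, within = a == b, mean_r = s$mean_r,
      sd_r = s$sd_r, n_pairs = s$n_pairs, stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, rows)
  utils::write.table(summary_df, file.path(config$out_dir, "group_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary_df, file.path(config$out_dir, "group_summary.json"),
                       digits = NA, pretty = TRUE)
  for (r in rows)
    lg$log(sprintf("batches %s vs %s: mean r = %s (sd %s, n = %d)",
                   r$batch_a, r$batch_b,
                   ifelse(is.na(r$mean_r), "NA", sprintf("%.3f", r$mean_r)),
                   ifelse(is.na(r$sd_r), "NA", sprintf("%.3f", r$sd_r)),
                   r$n_pairs))
  invisible(list(matrix = cm, summary = summary_df))
}

#' Generate and export a synthetic world bundle
#'
#' Thin wrapper over [make_world()] / [make_tissue_world()] +
#' [export_world()]. Writes the bundle plus `simulate.log`.
#'
#' @param config A `synthetic_world_config` (or list of its arguments).
#' @param out_dir Output directory for the bundle.
#' @param n_tissues Optional: generate tissue annotations for this many
#'   groups.
#' @param multi_prob Passed to [make_tissue_world()].
#' @param log_timestamps Write ISO timestamps in the log.
#' @return Invisibly, the `synthetic_world`.
#' @export
run_simulate <- function(config, out_dir, n_tissues = NULL, multi_prob = 0,
                         log_timestamps = TRUE) {
  if (!inherits(config, "synthetic_world_config"))
    config <- do.call(synthetic_world_config, config)
  world <- if (is.null(n_tissues)) make_world(config)
           else make_tissue_world(config, n_tissues, multi_prob)
  export_world(world, out_dir)
  lg <- .logger(file.path(out_dir, "simulate.log"), log_timestamps)
  lg$log(sprintf("simulated world: seed %d, %d true enhancers, reporter %d, %d assay set(s)",
                 config$master_seed, n_intervals(world$true_enhancers),
                 n_intervals(world$reporter_set), length(world$assay_sets)))
  lg$close()
  invisible(world)
}
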
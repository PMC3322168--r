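#' Default run configuration
#'
#' The resolved configuration of a pipeline run: markup markers, element
#' separator, optional lexeme-map CSV path, the edge deviation convention,
#' cross-validation scheme and seed, and per-comparison feature subsets.
#' Serializes losslessly to/from JSON; every pipeline command writes the
#' resolved config (with package version) next to its outputs so runs are
#' reproducible bit for bit.
#'
#' @param ... Overrides of the default fields.
#' @return A named list of configuration values.
#' @export
sg_config <- function(...) {
  cfg <- list(open = "[", close = "]", sep = "/",
              lexeme_map = NULL,
              deviation_edges = "either",
              cv_scheme = "loo", cv_k = 5L, seed = 1L,
              features = DEFAULT_FEATURES,
              alpha = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read / write a JSON run configuration
#'
#' @param path JSON file path.
#' @param cfg Configuration list from [sg_config()].
#' @return `read_config` returns the configuration list (defaults filled
#'   in); `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(sg_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

write_run_info <- function(outdir, cfg) {
  info <- c(list(package = "speechgraph",
                 version = as.character(utils::packageVersion("speechgraph"))),
            cfg)
  jsonlite::write_json(info, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Pipeline step: compute the measure table for a corpus
#'
#' Loads the corpus (or takes a `speech_corpus` directly), applies the
#' lexeme map if configured, computes the full measure vector per subject
#' and writes `measures.csv` plus the resolved configuration to `outdir`.
#'
#' @param corpus A `speech_corpus`, or a directory containing transcripts
#'   and a `metadata.csv`.
#' @param outdir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param config Configuration from [sg_config()].
#' @return The measure table, invisibly when writing.
#' @export
run_measure <- function(corpus, outdir = NULL, config = sg_config()) {
  if (is.character(corpus))
    corpus <- load_corpus(corpus, file.path(corpus, "metadata.csv"),
                          open = config$open, close = config$close,
                          sep = config$sep)
  if (!is.null(config$lexeme_map)) {
    lm <- utils::read.csv(config$lexeme_map, stringsAsFactors = FALSE)
    map <- stats::setNames(lm[[2]], lm[[1]])
    corpus$transcripts <- lapply(corpus$transcripts, apply_lexeme_map, map = map)
  }
  tab <- measure_table(corpus, deviation_edges = config$deviation_edges)
  n_undef <- sum(is.na(tab[MEASURE_NAMES]))
  message(sprintf("measured %d subjects (%d undefined values)", nrow(tab), n_undef))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(outdir, "measures.csv"), row.names = FALSE)
    write_run_info(outdir, config)
    return(invisible(tab))
  }
  tab
}

#' Pipeline step: group statistics over a measure table
#'
#' Kruskal-Wallis + pairwise rank-sum battery on the raw and the
#' word-normalized measure columns, plus Spearman correlations against
#' psychometric scales when scale columns are present.  Writes
#' `stats_kw.csv`, `stats_pairwise.csv` and (when available)
#' `stats_correlations.csv`.
#'
#' @param table Measure table (data.frame or path to `measures.csv`).
#' @param outdir Output directory; `NULL` to skip writing.
#' @param config Configuration from [sg_config()].
#' @return List with `raw` and `normalized` `group_comparison`s and
#'   `correlations` (possibly `NULL`).
#' @export
run_compare <- function(table, outdir = NULL, config = sg_config()) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  labeled <- setdiff(unique(table$group), "unlabeled")
  if (length(labeled) < 2L)
    sg_error("InsufficientData", "need >= 2 labeled groups")
  raw <- compare_groups(table, MEASURE_NAMES, groups = labeled, alpha = config$alpha)
  norm <- compare_groups(table, paste0(MEASURE_NAMES, "_per_word"),
                         groups = labeled, alpha = config$alpha)
  corr <- if (any(c("bprs", "panss") %in% names(table)))
    correlate_scales(table) else {
      warning("no scale columns present; correlation table omitted")
      NULL
    }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rbind(raw$kw, norm$kw),
                     file.path(outdir, "stats_kw.csv"), row.names = FALSE)
    utils::write.csv(rbind(raw$pairwise, norm$pairwise),
                     file.path(outdir, "stats_pairwise.csv"), row.names = FALSE)
    if (!is.null(corr))
      utils::write.csv(corr, file.path(outdir, "stats_correlations.csv"),
                       row.names = FALSE)
    write_run_info(outdir, config)
  }
  list(raw = raw, normalized = norm, correlations = corr)
}

#' Pipeline step: classify one binary group comparison
#'
#' Wraps [run_comparison()] and writes the full report (scores, ROC
#' points, AUC, sensitivity/specificity, kappa, seed) as JSON.
#'
#' @param table Measure table (data.frame or path to `measures.csv`).
#' @param comparison `"SxM"`, `"SxC"` or `"MxC"`.
#' @param outdir Output directory; `NULL` to skip writing.
#' @param config Configuration from [sg_config()].
#' @return The `classifier_report`.
#' @export
run_classify <- function(table, comparison = "SxM", outdir = NULL,
                         config = sg_config()) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  rep <- run_comparison(table, comparison,
                        features = config$features[[comparison]],
                        scheme = config$cv_scheme, k = config$cv_k,
                        seed = config$seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(rep),
                         file.path(outdir, paste0("report_", comparison, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_run_info(outdir, config)
  }
  rep
}

#' Pipeline step: simulate a synthetic corpus to disk
#'
#' Generates a seeded cohort with [generate_cohort()] and writes the
#' transcript files, `metadata.csv` and `manifest.json` via
#' [write_corpus()].
#'
#' @param outdir Output directory.
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @param profiles Named list of `speech_profile`s.
#' @return The generated `speech_corpus`, invisibly.
#' @export
run_simulate <- function(outdir, n_per_group = 8L, seed = 1L,
                         profiles = default_profiles()) {
  corpus <- generate_cohort(profiles, n_per_group = n_per_group, seed = seed)
  write_corpus(corpus, outdir)
  message(sprintf("wrote %d transcripts to %s (seed %d)",
                  length(corpus$transcripts), outdir, seed))
  invisible(corpus)
}
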
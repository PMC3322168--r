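#' Define a synthetic speech profile
#'
#' A profile parameterizes the transcript generator: report length is
#' negative-binomial (`mean_words`, `dispersion` = NB size, smaller =
#' more variable); the element sequence is a random walk over a growing
#' lexicon where each step introduces a fresh lexeme with probability
#' `p_new`, re-traverses a previously used outgoing transition from the
#' current lexeme with probability `p_retrace` (creating parallel edges
#' and loops, i.e. recurrence), and otherwise jumps to a uniformly chosen
#' known lexeme; deviation spans (departures from the anchor topic) open
#' per element with probability `p_deviate` and have geometric length with
#' mean `deviation_run`.  `subject_sd` spreads the parameters across
#' subjects of a cohort (log / logit scale), modelling between-subject
#' heterogeneity.
#'
#' @param name Profile name.
#' @param mean_words Mean report length in elements (>= 2).
#' @param dispersion Negative-binomial size parameter.
#' @param p_new,p_retrace,p_deviate Probabilities in \[0, 1\] with
#'   `p_new + p_retrace <= 1`.
#' @param deviation_run Mean deviation-span length (>= 1).
#' @param subject_sd Between-subject sd of the parameters on the
#'   log/logit scale (0 = identical subjects).
#' @return A `speech_profile` list.
#' @export
speech_profile <- function(name, mean_words, dispersion = 10,
                           p_new = 0.4, p_retrace = 0.1, p_deviate = 0.02,
                           deviation_run = 3, subject_sd = 0) {
  stopifnot(mean_words >= 2, dispersion > 0, deviation_run >= 1,
            p_new >= 0, p_new <= 1, p_retrace >= 0, p_retrace <= 1,
            p_deviate >= 0, p_deviate <= 1, p_new + p_retrace <= 1,
            subject_sd >= 0)
  structure(list(name = name, mean_words = mean_words, dispersion = dispersion,
                 p_new = p_new, p_retrace = p_retrace, p_deviate = p_deviate,
                 deviation_run = deviation_run, subject_sd = subject_sd),
            class = "speech_profile")
}

#' Default group profiles
#'
#' Three profiles encode the qualitative group signatures: the
#' schizophrenic-like profile produces short reports that address topics
#' only once (high lexeme novelty, near-zero recurrence and topic
#' deviation — "poor speech"); the manic-like profile produces long
#' reports that branch and return to the same transitions (low novelty,
#' high recurrence) and frequently leave the anchor topic ("logorrhea"
#' and "flight of thoughts"); the control-like profile sits between the
#' two with strongly inflated between-subject dispersion, reflecting the
#' wide inter-individual variability of non-pathological speech.  The
#' grand mean report length across the three profiles is about 87 words,
#' close to the ~84 words per report typical of anchor-topic dream
#' reports.
#'
#' @return Named list of three `speech_profile`s: `schizophrenic`,
#'   `manic`, `control`.
#' @export
default_profiles <- function() {
  list(
    schizophrenic = speech_profile("schizophrenic", mean_words = 45,
                                   dispersion = 12, p_new = 0.55,
                                   p_retrace = 0.04, p_deviate = 0.01,
                                   deviation_run = 2, subject_sd = 0.15),
    manic = speech_profile("manic", mean_words = 130, dispersion = 12,
                           p_new = 0.22, p_retrace = 0.38, p_deviate = 0.06,
                           deviation_run = 4, subject_sd = 0.15),
    control = speech_profile("control", mean_words = 85, dispersion = 5,
                             p_new = 0.38, p_retrace = 0.18, p_deviate = 0.03,
                             deviation_run = 3, subject_sd = 0.5)
  )
}

# jitter one subject's parameters around the profile (log/logit normal)
jitter_profile <- function(p) {
  if (p$subject_sd == 0) return(p)
  logit <- function(q) log(q / (1 - q))
  inv <- function(z) 1 / (1 + exp(-z))
  jp <- function(q) if (q <= 0 || q >= 1) q else
    inv(logit(q) + stats::rnorm(1, 0, p$subject_sd))
  mw <- max(2, p$mean_words * exp(stats::rnorm(1, 0, p$subject_sd)))
  new_p <- jp(p$p_new)
  ret <- jp(p$p_retrace)
  # keep the walk well-defined after jitter
  if (new_p + ret > 1) ret <- 1 - new_p
  speech_profile(p$name, mean_words = mw, dispersion = p$dispersion,
                 p_new = new_p, p_retrace = ret, p_deviate = jp(p$p_deviate),
                 deviation_run = p$deviation_run, subject_sd = 0)
}

#' Generate one synthetic transcript
#'
#' Draws the element count from the profile's length distribution, then
#' walks a growing lexicon as described in [speech_profile()].  When a
#' retrace is drawn but the current lexeme has no traversed outgoing
#' transition yet, the step falls back to a fresh lexeme.  In synthetic
#' mode each element is one word, so `word_count` equals the element
#' count.  Uses the current RNG state: seed before calling (or use
#' [generate_cohort()], which seeds once per cohort) for reproducibility.
#'
#' @param profile A `speech_profile`.
#' @param subject_id,group Metadata for the transcript.
#' @return A `speech_transcript`.
#' @export
generate_transcript <- function(profile, subject_id = "synthetic",
                                group = "unlabeled") {
  n <- max(2L, stats::rnbinom(1, mu = profile$mean_words, size = profile$dispersion))
  lexeme <- integer(n)       # lexicon indices; rendered as wNNN at the end
  segment <- character(n)
  edges_from <- integer(0)   # traversed transitions, for retracing
  edges_to <- integer(0)
  lexicon_size <- 1L
  lexeme[1L] <- 1L
  in_dev <- FALSE
  run_left <- 0L

  for (i in seq_len(n)) {
    if (i > 1L) {
      cur <- lexeme[i - 1L]
      u <- stats::runif(1)
      out <- which(edges_from == cur)
      if (u < profile$p_new || (u < profile$p_new + profile$p_retrace && !length(out))) {
        lexicon_size <- lexicon_size + 1L
        nxt <- lexicon_size
      } else if (u < profile$p_new + profile$p_retrace) {
        nxt <- edges_to[out[sample.int(length(out), 1L)]]
      } else {
        nxt <- sample.int(lexicon_size, 1L)
      }
      lexeme[i] <- nxt
      edges_from <- c(edges_from, cur)
      edges_to <- c(edges_to, nxt)
    }
    if (!in_dev && stats::runif(1) < profile$p_deviate) {
      in_dev <- TRUE
      run_left <- stats::rgeom(1, 1 / profile$deviation_run) + 1L
    }
    segment[i] <- if (in_dev) "deviation" else "anchor"
    if (in_dev) {
      run_left <- run_left - 1L
      if (run_left <= 0L) in_dev <- FALSE
    }
  }
  new_transcript(subject_id, group,
                 data.frame(lexeme = sprintf("w%03d", lexeme),
                            segment = segment, position = seq_len(n) - 1L,
                            stringsAsFactors = FALSE),
                 word_count = n)
}

#' Generate a group-conditioned synthetic cohort
#'
#' One profile per group, `n_per_group` subjects each, mirroring the
#' three-group study design (8 schizophrenic, 8 manic, 8 control subjects
#' in the original cohort).  Per subject, the profile parameters are
#' jittered by `subject_sd` and a transcript is generated.  Deterministic
#' given `seed`.
#'
#' @param profiles Named list of `speech_profile`s (names become group
#'   labels; must be valid group labels).
#' @param n_per_group Subjects per group (>= 1).
#' @param seed Integer seed.
#' @return A `speech_corpus` with metadata columns `subject_id`, `group`,
#'   `word_count`.
#' @examples
#' corpus <- generate_cohort(n_per_group = 8, seed = 42)
#' corpus
#' @export
generate_cohort <- function(profiles = default_profiles(), n_per_group = 8L,
                            seed = 1L) {
  stopifnot(n_per_group >= 1)
  bad <- setdiff(names(profiles), GROUP_LEVELS)
  if (length(bad))
    sg_error("InvalidGroup", paste("unknown group label(s):", paste(bad, collapse = ", ")))
  set.seed(seed)
  transcripts <- list()
  md <- list()
  for (grp in names(profiles)) {
    for (j in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", substr(grp, 1, 1), j)
      tr <- generate_transcript(jitter_profile(profiles[[grp]]),
                                subject_id = sid, group = grp)
      transcripts[[sid]] <- tr
      md[[sid]] <- data.frame(subject_id = sid, group = grp,
                              word_count = tr$word_count,
                              stringsAsFactors = FALSE)
    }
  }
  corpus <- new_corpus(transcripts, do.call(rbind, c(md, list(make.row.names = FALSE))))
  attr(corpus, "seed") <- seed
  corpus
}

#' Write a corpus to disk in the transcript/metadata format
#'
#' One `<subject_id>.txt` per transcript, a `metadata.csv`, and a
#' `manifest.json` recording the seed and package version; the tree
#' round-trips through [load_corpus()].
#'
#' @param corpus A `speech_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in corpus$transcripts)
    writeLines(serialize_transcript(tr), file.path(dir, paste0(tr$subject_id, ".txt")))
  utils::write.csv(corpus$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(package = "speechgraph",
         version = as.character(utils::packageVersion("speechgraph")),
         seed = attr(corpus, "seed"),
         n = length(corpus$transcripts),
         groups = as.list(table(corpus$metadata$group))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
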
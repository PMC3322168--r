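#' Parse an annotated transcript into a speech transcript object
#'
#' A transcript file holds one report already parsed into canonical
#' grammatical elements (lexemes), separated by `sep` and/or whitespace.
#' Spans where the speaker deviates from the anchor topic (e.g. waking
#' content inside a dream report) are delimited by `open` ... `close`
#' markers.  Every element is labeled `anchor` or `deviation`; the labels
#' are exhaustive and binary.
#'
#' @param text Annotated transcript string (non-empty).
#' @param subject_id Subject identifier attached to the transcript.
#' @param group Group label, one of `"schizophrenic"`, `"manic"`,
#'   `"control"`, `"unlabeled"`.
#' @param word_count Raw word count of the original report.  If `NULL`
#'   (default) it is computed from `text` with [count_words()].  Elements
#'   and raw words may legitimately differ: elements are parsed lexemes,
#'   words are raw tokens.
#' @param open,close Deviation-span delimiters (single characters, default
#'   `"["` and `"]"`).  Nested or unbalanced markers are rejected.
#' @param sep Element separator character (default `"/"`); whitespace
#'   always separates as well.
#' @return An object of class `speech_transcript`: a list with
#'   `subject_id`, `group`, `elements` (data.frame with columns `lexeme`,
#'   `segment`, `position`) and `word_count`.
#' @examples
#' t <- parse_transcript("I walked / I found / I hugged / [ I woke ]")
#' table(t$elements$segment)
#' @export
parse_transcript <- function(text, subject_id = "unknown", group = "unlabeled",
                             word_count = NULL,
                             open = "[", close = "]", sep = "/") {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    sg_error("EmptyTranscript", "transcript text is empty")
  group <- match.arg(group, GROUP_LEVELS)

  # pad markers and separators so they tokenize on whitespace
  padded <- text
  for (ch in c(open, close, sep))
    padded <- gsub(ch, paste0(" ", ch, " "), padded, fixed = TRUE)
  tokens <- strsplit(trimws(padded), "\\s+")[[1]]

  lex <- character(0)
  seg <- character(0)
  depth <- 0L
  skipped <- 0L
  for (tok in tokens) {
    if (tok == open) {
      depth <- depth + 1L
      if (depth > 1L)
        sg_error("MarkupError", "nested deviation markers are not allowed")
    } else if (tok == close) {
      depth <- depth - 1L
      if (depth < 0L)
        sg_error("MarkupError", sprintf("unmatched '%s'", close))
    } else if (tok == sep) {
      # pure separator: an empty element between two separators is skipped
      NULL
    } else if (nzchar(tok)) {
      lex <- c(lex, tok)
      seg <- c(seg, if (depth > 0L) "deviation" else "anchor")
    } else {
      skipped <- skipped + 1L
    }
  }
  if (depth != 0L)
    sg_error("MarkupError", sprintf("unclosed '%s'", open))
  if (length(lex) == 0L)
    sg_error("EmptyTranscript", "transcript contains no elements")
  if (skipped > 0L)
    warning(sprintf("%d empty element(s) skipped", skipped))

  if (is.null(word_count)) word_count <- count_words(text, strip = c(open, close, sep))
  new_transcript(subject_id, group,
                 data.frame(lexeme = lex, segment = seg,
                            position = seq_along(lex) - 1L,
                            stringsAsFactors = FALSE),
                 word_count)
}

new_transcript <- function(subject_id, group, elements, word_count) {
  if (!is.numeric(word_count) || word_count < 1)
    sg_error("InvalidWordCount", "word_count must be a positive integer")
  structure(list(subject_id = subject_id, group = group,
                 elements = elements, word_count = as.integer(word_count)),
            class = "speech_transcript")
}

#' @export
print.speech_transcript <- function(x, ...) {
  cat(sprintf("<speech_transcript> subject=%s group=%s elements=%d words=%d (%d deviation)\n",
              x$subject_id, x$group, nrow(x$elements), x$word_count,
              sum(x$elements$segment == "deviation")))
  invisible(x)
}

#' Serialize a transcript back to its annotated text form
#'
#' Inverse of [parse_transcript()]: elements joined by the separator with
#' consecutive deviation elements wrapped in marker spans.  Parsing the
#' result recovers the element sequence and segment labels exactly.
#'
#' @inheritParams parse_transcript
#' @param t A `speech_transcript`.
#' @return A single string.
#' @export
serialize_transcript <- function(t, open = "[", close = "]", sep = "/") {
  lex <- t$elements$lexeme
  dev <- t$elements$segment == "deviation"
  out <- character(0)
  i <- 1L
  n <- length(lex)
  while (i <= n) {
    if (dev[i]) {
      j <- i
      while (j < n && dev[j + 1L]) j <- j + 1L
      out <- c(out, paste(open, paste(lex[i:j], collapse = paste0(" ", sep, " ")), close))
      i <- j + 1L
    } else {
      out <- c(out, lex[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = paste0(" ", sep, " "))
}

#' Replace surface forms by canonical lexemes
#'
#' Applies a user-supplied surface-to-lexeme table after lowercasing.
#' Unmapped surfaces pass through (lowercased), so an empty map is the
#' identity up to case.  Element count, order and segment labels are
#' unchanged.
#'
#' @param t A `speech_transcript`.
#' @param map Named character vector: `names(map)` are surface forms,
#'   values are canonical lexemes.  Matching is case-insensitive.
#' @return The transcript with lexemes replaced.
#' @export
apply_lexeme_map <- function(t, map = character(0)) {
  if (length(map) > 0 && any(!nzchar(map)))
    sg_error("InvalidLexeme", "lexeme map contains mapping to empty string")
  lower <- tolower(t$elements$lexeme)
  names(map) <- tolower(names(map))
  hit <- lower %in% names(map)
  lower[hit] <- unname(map[lower[hit]])
  t$elements$lexeme <- lower
  t
}

#' Count raw words in a report
#'
#' Whitespace-delimited token count, after stripping markup characters.
#' Invariant to leading/trailing whitespace.
#'
#' @param raw_report Report text.
#' @param strip Characters removed before tokenizing (markup).
#' @return Positive integer word count.
#' @export
count_words <- function(raw_report, strip = c("[", "]")) {
  if (length(raw_report) != 1L || is.na(raw_report))
    sg_error("EmptyTranscript", "report is empty")
  x <- raw_report
  for (ch in strip) x <- gsub(ch, " ", x, fixed = TRUE)
  x <- trimws(x)
  if (!nzchar(x)) sg_error("EmptyTranscript", "report is empty")
  length(strsplit(x, "\\s+")[[1]])
}

#' Load a transcript corpus with its metadata table
#'
#' Reads a metadata CSV (header columns `subject_id`, `group`, and
#' optionally `word_count`, `bprs`, `panss`) and one transcript file
#' `<subject_id>.txt` per row from `transcript_dir`.  A metadata
#' `word_count` wins over the count computed from the file (counts from
#' original recordings may be supplied); the computed count is the
#' fallback.  Order of the result is CSV order.
#'
#' @param transcript_dir Directory of transcript files.
#' @param metadata_csv Path to the metadata CSV.
#' @inheritParams parse_transcript
#' @return A `speech_corpus`: list with `transcripts` (named list of
#'   `speech_transcript`) and `metadata` (data.frame with columns
#'   `subject_id`, `group`, `word_count`, `bprs`, `panss`).
#' @export
load_corpus <- function(transcript_dir, metadata_csv,
                        open = "[", close = "]", sep = "/") {
  md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(md)))
    sg_error("MetadataError", "metadata CSV must have subject_id and group columns")
  if (anyDuplicated(md$subject_id))
    sg_error("DuplicateSubject",
             paste("duplicate subject_id:",
                   paste(unique(md$subject_id[duplicated(md$subject_id)]), collapse = ", ")))
  bad <- setdiff(unique(md$group), GROUP_LEVELS)
  if (length(bad))
    sg_error("InvalidGroup", paste("unknown group label(s):", paste(bad, collapse = ", ")))
  for (col in c("word_count", "bprs", "panss"))
    if (is.null(md[[col]])) md[[col]] <- NA_real_

  transcripts <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    path <- file.path(transcript_dir, paste0(md$subject_id[i], ".txt"))
    if (!file.exists(path))
      sg_error("MissingTranscript", paste("no transcript file for subject", md$subject_id[i]))
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    wc <- if (is.na(md$word_count[i])) NULL else md$word_count[i]
    tr <- parse_transcript(text, subject_id = md$subject_id[i],
                           group = md$group[i], word_count = wc,
                           open = open, close = close, sep = sep)
    md$word_count[i] <- tr$word_count
    transcripts[[i]] <- tr
  }
  names(transcripts) <- md$subject_id
  new_corpus(transcripts, md)
}

new_corpus <- function(transcripts, metadata) {
  structure(list(transcripts = transcripts, metadata = metadata),
            class = "speech_corpus")
}

#' @export
print.speech_corpus <- function(x, ...) {
  cat(sprintf("<speech_corpus> %d transcripts: %s\n", length(x$transcripts),
              paste(sprintf("%s=%d", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = " ")))
  invisible(x)
}
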
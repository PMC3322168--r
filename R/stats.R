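#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction; p from the chi-square approximation
#' with (groups - 1) degrees of freedom.  Missing values are dropped.
#' When every observation is identical the mean ranks are equal by
#' construction and (H, p) = (0, 1).
#'
#' @param samples List of numeric vectors, one per group (>= 2 groups,
#'   each with >= 1 observation after NA removal).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(samples) {
  samples <- lapply(samples, function(x) x[!is.na(x)])
  if (length(samples) < 2L || any(lengths(samples) == 0L))
    sg_error("InsufficientData", "need >= 2 groups with >= 1 observation each")
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  grp <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(values, grp)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation distribution when both samples have n <= 10 and the
#' pooled data are tie-free (the normal approximation is poor at the
#' study's n = 8 per group); otherwise normal approximation with tie and
#' continuity correction.
#'
#' @param a,b Numeric vectors (>= 1 observation each after NA removal).
#' @return List with `statistic` (Mann-Whitney W for the first sample),
#'   `p`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    sg_error("InsufficientData", "both samples need >= 1 observation")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 10L && length(b) <= 10L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Bonferroni-corrected significance threshold
#'
#' Family alpha divided by the number of comparisons.  For reporting, the
#' threshold is truncated (not rounded) to 4 decimals, so three pairwise
#' comparisons at alpha = 0.05 display as 0.0166.
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return Corrected alpha (numeric, full precision) with attribute
#'   `display` holding the truncated 4-decimal string.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  ca <- alpha / m
  attr(ca, "display") <- formatC(floor(ca * 1e4) / 1e4, format = "f", digits = 4)
  ca
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with p from the t approximation, after
#' pairwise deletion of incomplete pairs.  Zero variance in either vector
#' leaves rho undefined (`NA`).
#'
#' @param x,y Paired numeric vectors, n >= 3 complete pairs.
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    sg_error("InsufficientData", "need >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Group comparison battery over a measure table
#'
#' For each measure column: a Kruskal-Wallis test across all groups, then
#' all pairwise Wilcoxon rank-sum tests.  A pairwise difference is flagged
#' significant when the omnibus p is below `alpha` and the pairwise p is
#' below the Bonferroni-corrected threshold `alpha / n_pairs` (0.0166 for
#' three groups at alpha = 0.05).  Applied identically to raw and
#' word-normalized columns; a column entirely missing is skipped with a
#' warning.
#'
#' @param table Measure table (e.g. from [measure_table()]) with a `group`
#'   column.
#' @param measures Character vector of measure column names.
#' @param groups Group labels to include (default: all present).
#' @param alpha Family-wise alpha for the pairwise family per measure.
#' @return A `group_comparison`: list with `kw` (measure, H, p), `pairwise`
#'   (measure, group_a, group_b, statistic, p, method, significant),
#'   `corrected_alpha` and its `display` string.
#' @export
compare_groups <- function(table, measures = MEASURE_NAMES,
                           groups = NULL, alpha = 0.05) {
  if (is.null(groups)) groups <- unique(table$group)
  if (length(groups) < 2L)
    sg_error("InsufficientData", "need >= 2 groups")
  table <- table[table$group %in% groups, , drop = FALSE]
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  ca <- bonferroni_alpha(alpha, length(pairs))

  kw_rows <- list()
  pw_rows <- list()
  for (m in measures) {
    if (is.null(table[[m]]) || all(is.na(table[[m]]))) {
      warning(sprintf("measure '%s' missing; skipped", m))
      next
    }
    samples <- lapply(groups, function(gr) table[[m]][table$group == gr])
    kw <- kruskal_wallis(samples)
    kw_rows[[m]] <- data.frame(measure = m, H = kw$H, p = kw$p)
    for (pr in pairs) {
      wr <- wilcoxon_ranksum(table[[m]][table$group == pr[1]],
                             table[[m]][table$group == pr[2]])
      pw_rows[[paste(m, pr[1], pr[2])]] <- data.frame(
        measure = m, group_a = pr[1], group_b = pr[2],
        statistic = wr$statistic, p = wr$p, method = wr$method,
        significant = kw$p < alpha && wr$p < ca)
    }
  }
  structure(list(kw = do.call(rbind, c(kw_rows, list(make.row.names = FALSE))),
                 pairwise = do.call(rbind, c(pw_rows, list(make.row.names = FALSE))),
                 corrected_alpha = as.numeric(ca),
                 corrected_alpha_display = attr(ca, "display"),
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d measures, corrected alpha = %s\n",
              nrow(x$kw), x$corrected_alpha_display))
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant pairwise differences:\n")
    print(sig[, c("measure", "group_a", "group_b", "p")], row.names = FALSE)
  } else cat("no significant pairwise differences\n")
  invisible(x)
}

#' Spearman correlations of measures against psychometric scales
#'
#' One rho/p pair per measure x scale combination, with the same
#' Bonferroni display convention as [compare_groups()].
#'
#' @param table Measure table containing measure and scale columns.
#' @param measures Measure column names.
#' @param scales Scale column names (e.g. `c("bprs", "panss")`).
#' @return data.frame with columns `measure`, `scale`, `rho`, `p`.
#' @export
correlate_scales <- function(table, measures = paste0(MEASURE_NAMES, "_per_word"),
                             scales = c("bprs", "panss")) {
  scales <- intersect(scales, names(table))
  if (!length(scales)) {
    warning("no scale columns present; correlation table omitted")
    return(NULL)
  }
  rows <- list()
  for (m in measures) for (s in scales) {
    sc <- spearman_correlation(table[[m]], table[[s]])
    rows[[paste(m, s)]] <- data.frame(measure = m, scale = s, rho = sc$rho, p = sc$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
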
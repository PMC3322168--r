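#' Gaussian naive Bayes classifier contract
#'
#' The classifier contract is a list with `fit(x, labels) -> model` and
#' `score(model, x) -> numeric in [0, 1]` (probability of the positive
#' class, the first factor level).  Any external classifier honouring the
#' contract can be plugged into [cross_validate()] and [run_comparison()];
#' Gaussian naive Bayes is the native implementation.
#'
#' @param priors Optional fixed class priors (named by class or in factor
#'   level order).  `NULL` estimates them from each training fold.  Under
#'   leave-one-out CV on a balanced cohort, fold-estimated priors
#'   systematically disfavour the held-out subject's own class (its
#'   training fold is one subject short), which biases null-data AUC
#'   below 0.5; [cross_validate()] therefore fixes the priors at the
#'   whole-cohort class frequencies by default.
#' @return A classifier contract list with elements `fit`, `score`, `name`.
#' @export
nb_classifier <- function(priors = NULL) {
  list(name = "gaussian_nb",
       fit = function(x, labels) nb_fit(x, labels, priors = priors),
       score = function(model, x) nb_posterior(model, x))
}

#' Fit a Gaussian naive Bayes model
#'
#' Class priors are the training class frequencies; each feature gets a
#' per-class Gaussian with the training mean and standard deviation.  To
#' avoid degenerate densities, each sd is floored at
#' `1e-6 * (global feature sd, or 1 if that is zero)`.
#'
#' @param x Numeric matrix or data.frame of features (rows = subjects).
#' @param labels Factor or character class labels, 2 classes with >= 2
#'   rows each; the first level is the positive class.
#' @param priors Optional fixed class priors (see [nb_classifier()]);
#'   default `NULL` uses the training class frequencies.
#' @return An `nb_model`: list with `classes`, `priors`, `mean`, `sd`
#'   (class x feature matrices) and `features`.
#' @export
nb_fit <- function(x, labels, priors = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L))
    sg_error("InsufficientData", "need >= 2 classes with >= 2 rows each")
  if (anyNA(x))
    sg_error("InsufficientData", "feature matrix contains missing values")
  classes <- levels(labels)
  global_sd <- apply(x, 2, stats::sd)
  floor_sd <- 1e-6 * ifelse(global_sd > 0, global_sd, 1)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE])))
  sg <- do.call(rbind, lapply(classes, function(cl)
    apply(x[labels == cl, , drop = FALSE], 2, stats::sd)))
  sg <- pmax(sg, matrix(floor_sd, nrow(sg), ncol(sg), byrow = TRUE))
  if (is.null(priors)) {
    priors <- as.numeric(table(labels)[classes]) / length(labels)
  } else {
    if (!is.null(names(priors))) priors <- priors[classes]
    priors <- as.numeric(priors) / sum(priors)
  }
  structure(list(classes = classes,
                 priors = priors,
                 mean = mu, sd = sg, features = colnames(x)),
            class = "nb_model")
}

#' Posterior probability of the positive class
#'
#' Per-feature Gaussian densities are multiplied with the class prior and
#' normalized over classes, all in log space for numerical stability.
#' Posteriors over the classes sum to 1.
#'
#' @param model An `nb_model`.
#' @param x Feature matrix / data.frame / single numeric vector with the
#'   model's features.
#' @return Numeric vector: P(first class | x) per row.
#' @export
nb_posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, model$features))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(model$features))
    x <- x[, model$features, drop = FALSE]
  loglik <- vapply(seq_along(model$classes), function(k) {
    rowSums(stats::dnorm(x,
                         mean = matrix(model$mean[k, ], nrow(x), ncol(x), byrow = TRUE),
                         sd = matrix(model$sd[k, ], nrow(x), ncol(x), byrow = TRUE),
                         log = TRUE)) + log(model$priors[k])
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  (post / rowSums(post))[, 1L]
}

#' Cross-validated per-subject classifier scores
#'
#' Each subject is scored by a model trained without it.  The default
#' scheme is leave-one-out, which makes full use of small samples (the
#' study design has 8 subjects per group); stratified k-fold with a
#' recorded seed is available.  Deterministic given the seed.  The
#' default classifier is Gaussian naive Bayes with class priors fixed at
#' the whole-sample class frequencies, so that fold-to-fold prior
#' perturbation (which penalizes the held-out class under leave-one-out)
#' does not leak into the scores.
#'
#' @param x Feature matrix (rows = subjects).
#' @param labels Binary class labels; first factor level is positive.
#' @param classifier A classifier contract, see [nb_classifier()];
#'   `NULL` (default) uses naive Bayes with whole-sample priors.
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed for fold assignment (ignored for `"loo"`).
#' @return Numeric score per row (`NA` for rows in skipped folds).
#' @export
cross_validate <- function(x, labels, classifier = NULL,
                           scheme = c("loo", "kfold"), k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x)
  if (is.null(classifier))
    classifier <- nb_classifier(priors = table(labels) / n)
  folds <- if (scheme == "loo") seq_len(n) else {
    set.seed(seed)
    # stratified: assign folds within each class
    f <- integer(n)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  }
  scores <- rep(NA_real_, n)
  for (fold in unique(folds)) {
    test <- folds == fold
    train_labels <- droplevels(labels[!test])
    if (nlevels(train_labels) < 2L) {
      warning(sprintf("fold %s lost an entire class; skipped", fold))
      next
    }
    model <- classifier$fit(x[!test, , drop = FALSE], labels[!test])
    scores[test] <- classifier$score(model, x[test, , drop = FALSE])
  }
  scores
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique scores (equal scores grouped into one
#' threshold step), yielding points (false-positive rate, true-positive
#' rate) from (0, 0) to (1, 1); AUC by the trapezoid rule.  AUC equals
#' the probability that a random positive outscores a random negative
#' (ties counting one half).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels; `positive` names the positive class
#'   (default: first factor level).
#' @param positive Positive class label.
#' @return List with `roc_points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- factor(labels[ok])
  if (is.null(positive)) positive <- levels(labels)[1L]
  pos <- labels == positive
  if (!any(pos) || all(pos))
    sg_error("InsufficientData", "both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  sc <- scores[ord]
  # one step per distinct score value
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, cumsum(pos)[last] / sum(pos))
  fpr <- c(0, cumsum(!pos)[last] / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Sensitivity and specificity at an operating threshold
#'
#' Sensitivity = TP/(TP + FN), specificity = TN/(TN + FP), predicting
#' positive when the score is at or above `threshold` (default 0.5 on the
#' posterior scale).
#'
#' @inheritParams roc_auc
#' @param threshold Score threshold for predicting the positive class.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5, positive = NULL) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- factor(labels[ok])
  if (is.null(positive)) positive <- levels(labels)[1L]
  pos <- labels == positive
  pred <- scores >= threshold
  c(sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products.  Values around 0.6 indicate good
#' and above 0.8 excellent agreement.  When both raters are constant and
#' equal (p_e = 1), kappa is defined as 1.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Numeric kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  lev <- union(levels(factor(predicted)), levels(factor(truth)))
  p <- factor(predicted, levels = lev)
  t <- factor(truth, levels = lev)
  tab <- table(p, t) / length(p)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

COMPARISON_GROUPS <- list(SxM = c("schizophrenic", "manic"),
                          SxC = c("schizophrenic", "control"),
                          MxC = c("manic", "control"))

# Word-normalized feature subsets that best separated each pair of groups
DEFAULT_FEATURES <- list(
  SxM = c("N_per_word", "E_per_word", "ATD_per_word"),
  SxC = c("N_per_word", "L1_per_word", "L2_per_word"),
  MxC = c("L1_per_word", "L2_per_word", "L3_per_word"))

#' Cross-validated binary classification of two diagnostic groups
#'
#' Runs the full classification battery for one binary comparison:
#' cross-validated scores, ROC/AUC, sensitivity/specificity at the 0.5
#' posterior operating point, and Cohen's kappa against the group labels.
#' Features default to the word-normalized subset established for each
#' comparison: N, E, ATD for schizophrenic vs manic; N, L1, L2 for
#' schizophrenic vs control; L1, L2, L3 for manic vs control.  Only
#' interpretation-free measures are used (never WN/WE).  The first group
#' of the comparison is the positive class.
#'
#' @param table Measure table (e.g. from [measure_table()]).
#' @param comparison `"SxM"`, `"SxC"` or `"MxC"`.
#' @param features Feature column names (default per comparison).
#' @param classifier Classifier contract; `NULL` (default) is Gaussian
#'   naive Bayes with whole-cohort priors, see [cross_validate()].
#' @param scheme,k,seed Cross-validation controls, see [cross_validate()].
#' @param threshold Operating point for sensitivity/specificity.
#' @return A `classifier_report`: comparison, features, scheme, seed,
#'   per-subject `scores` and `labels`, `sensitivity`, `specificity`,
#'   `roc_points`, `auc`, `kappa`.
#' @export
run_comparison <- function(table, comparison = c("SxM", "SxC", "MxC"),
                           features = NULL, classifier = NULL,
                           scheme = "loo", k = 5L, seed = 1L,
                           threshold = 0.5) {
  comparison <- match.arg(comparison)
  groups <- COMPARISON_GROUPS[[comparison]]
  if (is.null(features)) features <- DEFAULT_FEATURES[[comparison]]
  missing_feat <- setdiff(features, names(table))
  if (length(missing_feat))
    sg_error("UnknownFeature",
             paste("unknown feature(s):", paste(missing_feat, collapse = ", ")))
  sub <- table[table$group %in% groups, , drop = FALSE]
  if (length(unique(sub$group)) < 2L)
    sg_error("InsufficientData",
             paste("both groups must be present for", comparison))
  x <- as.matrix(sub[, features, drop = FALSE])
  labels <- factor(sub$group, levels = groups)  # first group = positive
  if (is.null(classifier))
    classifier <- nb_classifier(priors = table(labels) / length(labels))
  scores <- cross_validate(x, labels, classifier, scheme = scheme, k = k, seed = seed)
  roc <- roc_auc(scores, labels, positive = groups[1])
  ss <- sens_spec(scores, labels, threshold = threshold, positive = groups[1])
  pred <- ifelse(scores >= threshold, groups[1], groups[2])
  structure(list(comparison = comparison, features = features,
                 classifier = classifier$name, scheme = scheme, seed = seed,
                 subject_id = sub$subject_id, scores = scores,
                 labels = as.character(labels),
                 sensitivity = unname(ss["sensitivity"]),
                 specificity = unname(ss["specificity"]),
                 roc_points = roc$roc_points, auc = roc$auc,
                 kappa = cohen_kappa(pred, as.character(labels))),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s (%s, %s CV)\n", x$comparison,
              x$classifier, x$scheme))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  AUC = %.3f  sensitivity = %.3f  specificity = %.3f  kappa = %.3f\n",
              x$auc, x$sensitivity, x$specificity, x$kappa))
  invisible(x)
}
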
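feat <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "f"))

test_that("naive Bayes estimates priors and per-class Gaussians", {
  m <- nb_fit(feat(c(0, 0, 1, 1)), c("a", "a", "b", "b"))
  expect_equal(m$priors, c(0.5, 0.5))
  expect_equal(unname(m$mean[, 1]), c(0, 1))
  expect_true(all(m$sd > 0))   # floored, never degenerate

  m2 <- nb_fit(feat(rnorm(8)), rep(c("a", "b"), c(6, 2)))
  expect_equal(m2$priors, c(0.75, 0.25))

  # fixed priors override training frequencies
  m3 <- nb_fit(feat(rnorm(8)), rep(c("a", "b"), c(6, 2)), priors = c(a = 1, b = 1))
  expect_equal(m3$priors, c(0.5, 0.5))

  expect_error(nb_fit(feat(1:3), c("a", "a", "b")), class = "InsufficientData")
  expect_error(nb_fit(feat(c(1, NA, 3, 4)), c("a", "a", "b", "b")),
               class = "InsufficientData")
})

test_that("posterior is symmetric at the midpoint and normalized", {
  m <- nb_fit(feat(c(-1, -1.5, 1, 1.5)), c("a", "a", "b", "b"))
  expect_equal(nb_posterior(m, feat(0)), 0.5, tolerance = 1e-10)
  # query at class-a mean with well-separated classes
  ma <- nb_fit(feat(c(0, 0.1, -0.1, 10, 10.1, 9.9)), rep(c("a", "b"), each = 3))
  expect_gt(nb_posterior(ma, feat(0)), 0.99)
  # posteriors over both classes sum to 1 (second class = 1 - first)
  set.seed(41)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  lab <- rep(c("a", "b"), 10)
  m4 <- nb_fit(x, lab)
  p_a <- nb_posterior(m4, x)
  m4_flip <- nb_fit(x, factor(lab, levels = c("b", "a")))
  expect_equal(p_a + nb_posterior(m4_flip, x), rep(1, 20), tolerance = 1e-10)
})

test_that("native posteriors agree with an independent naive Bayes", {
  skip_if_not_installed("e1071")
  set.seed(42)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  lab <- factor(rep(c("p", "q"), 10))
  ours <- nb_posterior(nb_fit(x, lab), x)
  ref <- predict(e1071::naiveBayes(x, lab), x, type = "raw")[, "p"]
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("cross-validation scores every subject out of fold, deterministically", {
  set.seed(43)
  x <- feat(c(rnorm(8, 0), rnorm(8, 10)))
  lab <- rep(c("a", "b"), each = 8)
  sc <- cross_validate(x, lab)
  expect_length(sc, 16)
  expect_false(anyNA(sc))
  expect_true(all(sc[1:8] > 0.5) && all(sc[9:16] < 0.5))  # separable 1-D
  expect_identical(sc, cross_validate(x, lab))            # deterministic

  kf1 <- cross_validate(x, lab, scheme = "kfold", k = 4, seed = 9)
  kf2 <- cross_validate(x, lab, scheme = "kfold", k = 4, seed = 9)
  expect_identical(kf1, kf2)
})

test_that("trapezoid AUC equals the Mann-Whitney pairwise-win fraction", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), factor(c("p", "p", "n", "n"), c("p", "n")))
  expect_equal(r$auc, 1)
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]), c(fpr = 1, tpr = 1))
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2),
                       factor(c("n", "n", "p", "p"), c("p", "n")))$auc, 0)

  set.seed(44)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 2)           # rounding forces score ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    lab <- factor(ifelse(pos, "p", "n"), c("p", "n"))
    r <- roc_auc(scores, lab)
    expect_equal(r$auc, oracle_auc(scores, pos))
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(45)
  scores <- rnorm(30)
  lab <- factor(sample(c("p", "n"), 30, TRUE), c("p", "n"))
  base <- roc_auc(scores, lab)$auc
  for (f in list(function(x) 1 / (1 + exp(-x)), function(x) x^3, exp))
    expect_equal(roc_auc(f(scores), lab)$auc, base)
})

test_that("sensitivity and specificity count the confusion quadrants", {
  lab <- factor(rep(c("p", "n"), each = 4), c("p", "n"))
  expect_equal(sens_spec(c(rep(0.9, 4), rep(0.1, 4)), lab),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(rep(0.9, 8), lab), c(sensitivity = 1, specificity = 0))
  # TP=15 FN=1 TN=15 FP=1 -> 0.938 / 0.938
  lab2 <- factor(rep(c("p", "n"), each = 16), c("p", "n"))
  sc2 <- c(rep(0.9, 15), 0.1, rep(0.1, 15), 0.9)
  expect_equal(round(sens_spec(sc2, lab2), 3),
               c(sensitivity = 0.938, specificity = 0.938))
})

test_that("Cohen's kappa corrects agreement for chance", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_equal(cohen_kappa(rep(c("a", "b"), c(4, 4)),
                           rep(c("a", "b", "a", "b"), c(3, 1, 1, 3))), 0.5)
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5)), 1)  # p_e = 1 edge case
  set.seed(46)
  k <- cohen_kappa(sample(c("a", "b"), 4000, TRUE), sample(c("a", "b"), 4000, TRUE))
  expect_lt(abs(k), 0.06)   # independent raters: near zero
})

test_that("comparison reports assemble the full classification battery", {
  tab <- measure_table(generate_cohort(n_per_group = 8, seed = 47))
  rep <- run_comparison(tab, "SxM")
  expect_s3_class(rep, "classifier_report")
  expect_equal(rep$features, c("N_per_word", "E_per_word", "ATD_per_word"))
  expect_gte(rep$auc, 0.75)
  expect_true(rep$sensitivity >= 0 && rep$sensitivity <= 1)
  expect_true(rep$kappa >= -1 && rep$kappa <= 1)
  expect_length(rep$scores, 16)
  # default feature subsets per comparison
  expect_equal(run_comparison(tab, "SxC")$features,
               c("N_per_word", "L1_per_word", "L2_per_word"))
  expect_equal(run_comparison(tab, "MxC")$features,
               c("L1_per_word", "L2_per_word", "L3_per_word"))
  # identical seeds give identical reports
  expect_identical(run_comparison(tab, "SxM"), run_comparison(tab, "SxM"))

  expect_error(run_comparison(tab, "SxM", features = "nope"),
               class = "UnknownFeature")
  expect_error(run_comparison(tab[tab$group == "manic", ], "SxM"),
               class = "InsufficientData")
})

test_that("an external classifier can be plugged in through the contract", {
  skip_if_not_installed("e1071")
  svm_contract <- list(
    name = "svm",
    fit = function(x, labels) e1071::svm(x, labels, probability = TRUE),
    score = function(model, x) {
      p <- attr(predict(model, x, probability = TRUE), "probabilities")
      p[, colnames(p)[1]]
    })
  tab <- measure_table(generate_cohort(n_per_group = 8, seed = 48))
  rep <- run_comparison(tab, "SxM", classifier = svm_contract)
  expect_equal(rep$classifier, "svm")
  expect_true(rep$auc >= 0 && rep$auc <= 1)
})
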
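# Published cross-validation confusion counts for the curated interaction
# set, with the printed metric strings they imply. Three printed cells are
# internally inconsistent with their own counts and are excluded: the
# SVM-RBF row (its counts sum to 2,655, not 2,652), the SVM-polynomial
# cross-feeding F1 (printed 0.88, implied 0.93) and the gradient-boosting
# balanced accuracy (printed 0.9, implied 0.89).
published_rows <- list(
  knn = list(counts = c(401, 145, 130, 1976),
             display = c(p_co = "0.76", r_co = "0.73", f_co = "0.74",
                         p_cf = "0.93", r_cf = "0.94", f_cf = "0.93",
                         acc = "0.9", bacc = "0.84")),
  svm_linear = list(counts = c(369, 177, 104, 2002),
                    display = c(p_co = "0.78", r_co = "0.68", f_co = "0.72",
                                p_cf = "0.92", r_cf = "0.95", f_cf = "0.93",
                                acc = "0.89", bacc = "0.81")),
  svm_polynomial = list(counts = c(376, 170, 140, 1966),
                        display = c(p_co = "0.73", r_co = "0.69",
                                    f_co = "0.71", p_cf = "0.92",
                                    r_cf = "0.93", f_cf = NA,
                                    acc = "0.88", bacc = "0.81")),
  svm_sigmoid = list(counts = c(158, 388, 176, 1930),
                     display = c(p_co = "0.47", r_co = "0.29", f_co = "0.36",
                                 p_cf = "0.83", r_cf = "0.92", f_cf = "0.87",
                                 acc = "0.79", bacc = "0.6")),
  xgboost = list(counts = c(445, 101, 80, 2026),
                 display = c(p_co = "0.85", r_co = "0.82", f_co = "0.83",
                             p_cf = "0.95", r_cf = "0.96", f_cf = "0.96",
                             acc = "0.93", bacc = NA)),
  random_forest = list(counts = c(429, 117, 119, 1987),
                       display = c(p_co = "0.78", r_co = "0.79",
                                   f_co = "0.78", p_cf = "0.94",
                                   r_cf = "0.94", f_cf = "0.94",
                                   acc = "0.91", bacc = "0.86"))
)

panel_display <- function(panel) {
  c(p_co = panel$display$precision[["competition"]],
    r_co = panel$display$recall[["competition"]],
    f_co = panel$display$f1[["competition"]],
    p_cf = panel$display$precision[["cross_feeding"]],
    r_cf = panel$display$recall[["cross_feeding"]],
    f_cf = panel$display$f1[["cross_feeding"]],
    acc = panel$display$accuracy,
    bacc = panel$display$balanced_accuracy)
}

test_that("the metric panel reproduces every printed value from the published counts", {
  for (row in names(published_rows)) {
    counts <- do.call(confusion_counts,
                      as.list(published_rows[[row]]$counts))
    expect_equal(counts$tp_co + counts$fn_co, 546L)
    expect_equal(counts$fn_cf + counts$tp_cf, 2106L)
    got <- panel_display(panel_from_counts(counts))
    want <- published_rows[[row]]$display
    keep <- !is.na(want)
    expect_equal(got[keep], want[keep], label = row)
  }
})

test_that("panel numerics match their published full-precision values for the baseline", {
  panel <- panel_from_counts(confusion_counts(401, 145, 130, 1976))
  expect_equal(panel$precision[["competition"]], 401 / 531,
               tolerance = 1e-12)
  expect_equal(panel$recall[["competition"]], 401 / 546, tolerance = 1e-12)
  expect_equal(panel$accuracy, 2377 / 2652, tolerance = 1e-12)
  expect_equal(panel$balanced_accuracy,
               (401 / 546 + 1976 / 2106) / 2, tolerance = 1e-12)
})

test_that("random prediction precision equals class prevalence", {
  counts <- c(cross_feeding = 2106, competition = 546)
  base <- random_baseline_precision(counts)
  expect_equal(format_metric(base[["competition"]]), "0.21")
  expect_equal(format_metric(base[["cross_feeding"]]), "0.79")
  expect_equal(sum(base), 1)
  expect_equal(unname(random_baseline_precision(c(cross_feeding = 10))), 1)
})

test_that("degenerate constant predictors produce flagged zero-denominator metrics", {
  # always predict cross-feeding: no competition predictions at all
  counts <- counts_from_predictions(
    truth = c(rep(CO, 30), rep(CF, 70)),
    predicted = rep(CF, 100))
  panel <- panel_from_counts(counts)
  expect_equal(panel$recall[["competition"]], 0)
  expect_equal(panel$precision[["cross_feeding"]], 0.7)
  expect_equal(panel$recall[["cross_feeding"]], 1)
  expect_true("precision.competition" %in% panel$zero_denominator)
  expect_error(panel_from_counts(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("display rounding is half-up with trailing zeros trimmed", {
  expect_equal(format_metric(0.896), "0.9")
  expect_equal(format_metric(0.755), "0.76")
  expect_equal(format_metric(0.205882), "0.21")
  expect_equal(format_metric(1), "1")
  expect_equal(format_metric(0.005), "0.01")
})

test_that("ROC area is exact for separable scores and equals the rank statistic", {
  truth <- c(rep(CF, 5), rep(CO, 5))
  perfect <- c(rep(0.9, 5), rep(0.1, 5))
  expect_equal(roc_curve_and_auc(perfect, truth, CF)$auc, 1)
  expect_equal(roc_curve_and_auc(perfect, truth, CO)$auc, 1)

  # hand-worked 6-point instance with a tie, against the pairwise oracle
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  truth6 <- c(CF, CO, CF, CF, CO, CO)
  want <- mann_whitney_auc(scores[truth6 == CF], scores[truth6 == CO])
  expect_equal(roc_curve_and_auc(scores, truth6, CF)$auc, want)
})

test_that("ROC area is invariant under monotone transforms and class complement", {
  set.seed(5)
  scores <- runif(80)
  truth <- sample(c(CF, CO), 80, replace = TRUE, prob = c(0.7, 0.3))
  a1 <- roc_curve_and_auc(scores, truth, CF)$auc
  a2 <- roc_curve_and_auc(plogis(5 * scores - 2), truth, CF)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # the two target classes give the same ROC area on one prediction set
  expect_equal(roc_curve_and_auc(scores, truth, CO)$auc, a1,
               tolerance = 1e-12)
})

test_that("permuted labels give chance-level ROC area and prevalence-level PR area", {
  set.seed(9)
  n <- 120L
  truth <- c(rep(CO, 30), rep(CF, 90))
  scores <- runif(n)
  roc_areas <- pr_areas <- numeric(500)
  for (i in seq_len(500)) {
    t_perm <- sample(truth)
    roc_areas[i] <- roc_curve_and_auc(scores, t_perm, CO)$auc
    pr_areas[i] <- pr_curve_and_auc(scores, t_perm, CO)$auc
  }
  expect_lt(abs(mean(roc_areas) - 0.5), 0.05)
  expect_lt(abs(mean(pr_areas) - 0.25), 0.05)
})

test_that("PR area follows the step-wise average-precision convention", {
  truth <- c(rep(CF, 3), rep(CO, 3))
  perfect <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  expect_equal(pr_curve_and_auc(perfect, truth, CF)$auc, 1)

  # hand-worked: scores ranked for target cf: 0.9(cf) 0.8(co) 0.7(cf)
  # 0.6(cf) 0.2(co) 0.1(co); AP = 1/3*(1) + 1/3*(2/3) + 1/3*(3/4)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1)
  truth6 <- c(CF, CO, CF, CF, CO, CO)
  want <- (1 + 2 / 3 + 3 / 4) / 3
  expect_equal(pr_curve_and_auc(scores, truth6, CF)$auc, want,
               tolerance = 1e-12)
})

test_that("curve implementations agree with the reference ROC library", {
  set.seed(13)
  scores <- runif(150)
  truth <- sample(c(CF, CO), 150, replace = TRUE, prob = c(0.75, 0.25))
  ours <- roc_curve_and_auc(scores, truth, CF)$auc
  ref <- suppressMessages(
    pROC::auc(pROC::roc(response = truth == CF, predictor = scores,
                        direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("balanced accuracy equals accuracy for balanced classes", {
  set.seed(3)
  for (i in 1:20) {
    tp_co <- sample(0:50, 1); fn_co <- 50 - tp_co
    tp_cf <- sample(0:50, 1); fn_cf <- 50 - tp_cf
    panel <- panel_from_counts(confusion_counts(tp_co, fn_co, fn_cf, tp_cf))
    expect_equal(panel$balanced_accuracy, panel$accuracy, tolerance = 1e-12)
  }
})

test_that("curve construction needs both classes present", {
  expect_error(roc_curve_and_auc(c(0.2, 0.4), c(CF, CF), CF),
               "both classes")
  expect_error(pr_curve_and_auc(c(0.2, 0.4), c(CO, CO), CO),
               "both classes")
})
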
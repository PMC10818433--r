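test_that("binary confusion counts match hand tallies", {
  cm <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1), "wheeze_binary")
  expect_equal(cm$TP, 1); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)
  expect_equal(cm$n, 4)

  perfect <- confusion_counts(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE),
                              "crackle_binary")
  expect_equal(perfect$FP + perfect$FN, 0)

  # label-string inputs reduce by presence of the target sound
  cm2 <- confusion_counts(c("wheeze", "both", "normal", "crackle"),
                          c("wheeze", "normal", "normal", "wheeze"),
                          "wheeze_binary")
  expect_equal(cm2$TP, 1)   # wheeze hit
  expect_equal(cm2$FN, 1)   # both missed
  expect_equal(cm2$TN, 1)   # normal correct (crackle pred wheeze -> FP)
  expect_equal(cm2$FP, 1)

  expect_error(confusion_counts(c(0, 2), c(0, 1), "wheeze_binary"), "\\[2\\]")
  expect_error(confusion_counts(c("up"), c("normal"), "four_class"),
               "y_true\\[1\\]")
})

test_that("four-class confusion keeps the 4x4 table and the ICBHI reduction", {
  yt <- c("normal", "normal", "crackle", "wheeze", "both", "both")
  yp <- c("normal", "wheeze", "crackle", "crackle", "both", "wheeze")
  cm <- confusion_counts(yt, yp, "four_class")
  expect_equal(dim(cm$table), c(4, 4))
  expect_equal(sum(cm$table), 6)
  # exact-match adventitious: crackle + both = 2
  expect_equal(cm$TP, 2)
  # wheeze->crackle and both->wheeze are errors on adventitious cycles
  expect_equal(cm$FN, 2)
  expect_equal(cm$TN, 1)
  expect_equal(cm$FP, 1)
  # under this reduction Acc equals overall 4-class accuracy
  expect_equal(compute_metrics(cm)$Acc, mean(yt == yp))

  all_norm <- confusion_counts(rep("normal", 5), rep("normal", 5),
                               "four_class")
  expect_equal(all_norm$TN, 5)
  expect_equal(all_norm$TP + all_norm$FP + all_norm$FN, 0)
})

test_that("metrics follow their defining ratios and the score identity", {
  even <- compute_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(unlist(even), c(Acc = 0.5, Sen = 0.5, Spe = 0.5,
                               Pre = 0.5, Sco = 0.5))

  m <- compute_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(m$Sen, 0.9)
  expect_equal(m$Spe, 0.8)
  expect_equal(m$Sco, 0.85)
  expect_equal(m$Acc, 0.85)
  expect_equal(m$Pre, 9 / 11)
  expect_identical(m$Sco, (m$Sen + m$Spe) / 2)

  # zero denominators surface as NA with a warning, never silent zeros
  expect_warning(z <- compute_metrics(list(TP = 0, FN = 0, TN = 5, FP = 1)),
                 "sensitivity")
  expect_true(is.na(z$Sen))
  z2 <- suppressWarnings(compute_metrics(list(TP = 0, FN = 0, TN = 5,
                                              FP = 0)))
  expect_true(is.na(z2$Sen) && is.na(z2$Pre))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)))
})

test_that("printed score cells are audited against (Sen + Spe)/2", {
  chk <- check_score_consistency(
    sen = c(76.0, 71.9, 56.6, 65.2),
    spe = c(91.0, 85.0, 71.3, 80.2),
    sco = c(83.5, 78.5, 64.0, 71.7))
  expect_equal(chk$sco_computed, c(83.5, 78.45, 63.95, 72.7))
  expect_identical(chk$consistent, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("fold assignment partitions patients with near-equal sizes", {
  ids <- sprintf("P%03d", 1:126)
  fs <- make_folds(ids, k = 10, repeats = 1, seed = 5)
  sizes <- sort(as.integer(table(fs$assignments[[1]])), decreasing = TRUE)
  expect_identical(sizes, c(rep(13L, 6), rep(12L, 4)))

  # partition property over 100 seeds
  for (s in 1:100) {
    a <- make_folds(ids, k = 10, repeats = 1, seed = s)$assignments[[1]]
    expect_length(a, 126)
    expect_setequal(names(a), ids)
    expect_true(all(a %in% 1:10))
    expect_lte(diff(range(table(a))), 1)
  }

  # deterministic under the seed, distinct across repeats
  f2 <- make_folds(ids, k = 10, repeats = 2, seed = 5)
  expect_identical(f2$assignments[[1]], fs$assignments[[1]])
  expect_false(identical(f2$assignments[[1]], f2$assignments[[2]]))

  expect_error(make_folds(sprintf("P%d", 1:5), k = 10), "fewer")
})

# simple classifiers for exercising the cross-validation plumbing
constant_model <- function(label) {
  structure(list(label = label), class = "constant_model")
}
predict.constant_model <- function(object, newdata, ...) {
  rep(object$label, length(newdata))
}
oracle_model <- function() structure(list(), class = "oracle_model")
predict.oracle_model <- function(object, newdata, ...) {
  vapply(newdata, identity, "")   # inputs are the true labels themselves
}
.S3method("predict", "constant_model", predict.constant_model)
.S3method("predict", "oracle_model", predict.oracle_model)

test_that("cross-validation respects patient disjointness and degenerate classifiers", {
  ids <- sprintf("P%02d", 1:20)
  pat <- rep(ids, each = 4)
  n <- length(pat)
  y <- rep("normal", n)
  x <- as.list(y)                  # oracle input: the labels themselves
  folds <- make_folds(pat, k = 5, repeats = 1, seed = 2)

  # constant "normal" classifier on an all-normal set is always right
  rep_const <- cross_validate(
    x, y, pat, folds,
    function(xt, yt, xv, yv) constant_model("normal"),
    task = "four_class")
  expect_true(all(rep_const$per_fold$Acc == 1))

  # oracle classifier on a mixed set: all metrics hit 1
  set.seed(6)
  y2 <- sample(c("normal", "crackle", "wheeze", "both"), n, replace = TRUE)
  x2 <- as.list(y2)
  rep_oracle <- cross_validate(
    x2, y2, pat, folds, function(xt, yt, xv, yv) oracle_model(),
    task = "four_class")
  agg <- rep_oracle$aggregate
  expect_equal(agg$Acc, 1); expect_equal(agg$Sen, 1)
  expect_equal(agg$Spe, 1); expect_equal(agg$Sco, 1)

  # structural patient-disjointness: every sample's patient is in exactly
  # one test fold, and folds never share patients
  a <- folds$assignments[[1]]
  expect_setequal(names(a), ids)
  expect_equal(sum(table(a)), length(ids))

  # aggregate Acc lies between per-fold extremes
  pf <- rep_const$per_fold$Acc
  expect_gte(rep_const$aggregate$Acc, min(pf))
  expect_lte(rep_const$aggregate$Acc, max(pf))
})

test_that("model comparison reproduces exact small-sample distributions", {
  # complete dominance, 3 vs 3: U counts all 9 pairwise wins
  cmp <- compare_models(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(cmp$u_statistic, 9)

  # identical vectors: all paired differences are zero -> null retained
  same <- compare_models(c(0.5, 0.6, 0.7, 0.8), c(0.5, 0.6, 0.7, 0.8))
  expect_equal(same$v_p, 1)
  expect_identical(same$verdict, "indistinguishable")

  # exact p-values match brute-force enumeration for n <= 8 (tie-free)
  set.seed(14)
  for (i in 1:5) {
    a <- round(runif(6), 3); b <- round(runif(6) + 0.15, 3)
    if (any(duplicated(c(a, b))) || any(a == b)) next
    cmp <- compare_models(a, b)
    expect_equal(cmp$u_p, mw_exact_p(a, b), tolerance = 1e-12)
    expect_equal(cmp$v_p, sr_exact_p(a, b), tolerance = 1e-12)
  }

  # two-sided symmetry under relabeling a <-> b
  a <- c(0.91, 0.85, 0.88, 0.95, 0.80)
  b <- c(0.70, 0.72, 0.65, 0.77, 0.69)
  expect_equal(compare_models(a, b)$u_p, compare_models(b, a)$u_p)
  expect_equal(compare_models(a, b)$v_p, compare_models(b, a)$v_p)
  expect_identical(compare_models(a, b)$verdict, "a")
  expect_identical(compare_models(b, a)$verdict, "b")

  expect_error(compare_models(c(1, 2), c(3, 4)), "at least 3")
})

test_that("evaluation reports serialize to JSON", {
  ids <- sprintf("P%02d", 1:10)
  pat <- rep(ids, each = 2)
  y <- rep("normal", 20)
  folds <- make_folds(pat, k = 5, repeats = 1, seed = 3)
  rep1 <- cross_validate(as.list(y), y, pat, folds,
                         function(xt, yt, xv, yv) constant_model("normal"),
                         task = "four_class")
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$task, "four_class")
  expect_equal(parsed$aggregate$Acc, 1)
})
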
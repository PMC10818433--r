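# Evaluation layer: confusion-matrix metrics, patient-wise k-fold
# cross-validation, and non-parametric pairwise significance testing.

.four_classes <- c("normal", "crackle", "wheeze", "both")

#' Confusion counts for a classification task
#'
#' Binary tasks (`"wheeze_binary"`, `"crackle_binary"`): positive means the
#' target sound is present; labels may be logical, 0/1, or the class strings
#' themselves.
#'
#' For `"four_class"` the full 4 x 4 count matrix is kept and a binary
#' reduction is derived with the ICBHI challenge convention: TP counts
#' adventitious cycles classified *exactly* right (predicting only one of
#' two co-occurring sounds is an error), FN the remaining adventitious
#' cycles, TN normal cycles predicted normal, FP normal cycles predicted as
#' any adventitious class. Under this reduction Acc equals the overall
#' four-class accuracy.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param task One of `"wheeze_binary"`, `"crackle_binary"`, `"four_class"`.
#' @return An object of class `confusion_counts` with `TP`, `TN`, `FP`,
#'   `FN`, `n` and (for four_class) `table`.
#' @export
confusion_counts <- function(y_true, y_pred,
                             task = c("wheeze_binary", "crackle_binary",
                                      "four_class")) {
  task <- match.arg(task)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (task == "four_class") {
    chk <- function(v, nm) {
      bad <- which(!as.character(v) %in% .four_classes)
      if (length(bad))
        stop(sprintf("%s[%d] = '%s' is not a four-class label",
                     nm, bad[1], as.character(v)[bad[1]]))
    }
    chk(y_true, "y_true"); chk(y_pred, "y_pred")
    tt <- factor(as.character(y_true), levels = .four_classes)
    pp <- factor(as.character(y_pred), levels = .four_classes)
    tab <- table(true = tt, pred = pp)
    adv <- .four_classes[-1]
    TP <- sum(diag(tab[adv, adv]))
    FN <- sum(tab[adv, ]) - TP
    TN <- tab["normal", "normal"]
    FP <- sum(tab["normal", adv])
    out <- list(task = task, TP = TP, TN = TN, FP = FP, FN = FN,
                n = length(tt), table = unclass(tab))
  } else {
    to_bin <- function(v, nm) {
      if (is.logical(v)) return(v)
      if (is.numeric(v)) {
        bad <- which(!v %in% c(0, 1))
        if (length(bad))
          stop(sprintf("%s[%d] is not a 0/1 label", nm, bad[1]))
        return(v == 1)
      }
      target <- if (task == "wheeze_binary") "wheeze" else "crackle"
      v <- as.character(v)
      bad <- which(!v %in% .four_classes)
      if (length(bad))
        stop(sprintf("%s[%d] = '%s' is not a recognised label",
                     nm, bad[1], v[bad[1]]))
      v %in% c(target, "both")
    }
    tt <- to_bin(y_true, "y_true"); pp <- to_bin(y_pred, "y_pred")
    out <- list(task = task,
                TP = sum(tt & pp), TN = sum(!tt & !pp),
                FP = sum(!tt & pp), FN = sum(tt & !pp),
                n = length(tt), table = NULL)
  }
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %s: TP %d  TN %d  FP %d  FN %d (n = %d)\n",
              x$task, x$TP, x$TN, x$FP, x$FN, x$n))
  if (!is.null(x$table)) print(x$table)
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision, and the score
#' `Sco = (Sen + Spe) / 2`. Cells with a zero denominator are reported as
#' `NA` with a warning, never silently as 0.
#'
#' @param cm A [confusion_counts] object (or a list with TP/TN/FP/FN).
#' @return An object of class `metric_set`: named numeric vector-like list
#'   with `Acc`, `Sen`, `Spe`, `Pre`, `Sco` as proportions in \[0, 1\].
#' @export
compute_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("confusion counts are all zero")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA",
                      name))
      return(NA_real_)
    }
    num / den
  }
  Sen <- ratio(TP, TP + FN, "sensitivity")
  Spe <- ratio(TN, TN + FP, "specificity")
  structure(list(Acc = (TP + TN) / total, Sen = Sen, Spe = Spe,
                 Pre = ratio(TP, TP + FP, "precision"),
                 Sco = (Sen + Spe) / 2),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s %5.1f%%", names(v), 100 * v), collapse = "  "),
      "\n")
  invisible(x)
}

#' Check a printed sensitivity/specificity/score triple for consistency
#'
#' Recomputes `Sco = (Sen + Spe)/2` and flags values that differ from the
#' printed score by more than rounding at the printed precision can
#' explain. Useful for auditing published results tables.
#'
#' @param sen,spe,sco Printed values (same units, e.g. percent), vectorized.
#' @param digits Decimal digits of the printed values (default 1).
#' @return Data frame with `sen`, `spe`, `sco_printed`, `sco_computed`,
#'   `consistent`.
#' @export
check_score_consistency <- function(sen, spe, sco, digits = 1) {
  computed <- (sen + spe) / 2
  tol <- 0.5 * 10^(-digits) + 1e-9
  data.frame(sen = sen, spe = spe, sco_printed = sco,
             sco_computed = computed,
             consistent = abs(computed - sco) <= tol)
}

#' Patient-wise k-fold assignments
#'
#' Each repetition is a seeded random partition of the patients into `k`
#' folds whose sizes differ by at most one; every patient appears in
#' exactly one fold per repetition.
#'
#' @param patient_ids Character vector (duplicates allowed; the unique set
#'   is partitioned).
#' @param k Fold count (default 10).
#' @param repeats Number of independent repetitions (default 5, giving
#'   `k * repeats` fold-level evaluation points).
#' @param seed Integer seed.
#' @return An object of class `fold_split`: `k`, `repeats`, `patients`,
#'   and `assignments` (list of named fold-index vectors, one per repeat).
#' @export
make_folds <- function(patient_ids, k = 10, repeats = 5, seed = 1L) {
  up <- unique(as.character(patient_ids))
  n <- length(up)
  if (n < k) stop("fewer distinct patients than folds")
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + (r - 1L))
    sizes <- rep(n %/% k, k)
    if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    # assign shuffled patients to fold blocks
    a <- integer(n)
    a[sample(n)] <- rep(seq_len(k), times = sizes)
    names(a) <- up
    assignments[[r]] <- a
  }
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 patients = up, assignments = assignments,
                 seed = as.integer(seed)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d patients, %d folds x %d repeats\n",
              length(x$patients), x$k, x$repeats))
  invisible(x)
}

#' Patient-wise cross-validation
#'
#' For every repetition and fold, models are trained on the training-fold
#' patients' samples (with 10% of the training patients carved out as a
#' validation set for early stopping) and evaluated on the test-fold
#' patients' samples. Both the aggregate metrics (from the summed confusion
#' matrix, the headline figure) and the mean of per-fold metrics are
#' reported, since the two differ in general.
#'
#' @param x List of inputs (images / patch matrices), one per sample.
#' @param y Labels, one per sample.
#' @param patients Patient id per sample; every id must appear in `folds`.
#' @param folds A [fold_split] from [make_folds()].
#' @param model_factory `function(x_train, y_train, x_val, y_val)` returning
#'   a fitted object usable with `predict(model, x_test)`.
#' @param task Metric task, see [confusion_counts()].
#' @return An object of class `evaluation_report`: `per_fold` data frame,
#'   `aggregate` metric set, `mean_metrics`, `confusion` (summed counts).
#' @export
cross_validate <- function(x, y, patients, folds, model_factory,
                           task = c("wheeze_binary", "crackle_binary",
                                    "four_class")) {
  task <- match.arg(task)
  stopifnot(inherits(folds, "fold_split"))
  patients <- as.character(patients)
  if (!all(patients %in% folds$patients))
    stop("some samples' patients are missing from the fold split")
  rows <- list()
  agg <- list(TP = 0, TN = 0, FP = 0, FN = 0, n = 0)
  agg_tab <- NULL
  for (r in seq_len(folds$repeats)) {
    a <- folds$assignments[[r]]
    for (f in seq_len(folds$k)) {
      test_p <- names(a)[a == f]
      train_p <- names(a)[a != f]
      set.seed(folds$seed + 1000L * r + f)
      val_p <- sample(train_p, max(1L, ceiling(0.1 * length(train_p))))
      fit_p <- setdiff(train_p, val_p)
      i_tr <- which(patients %in% fit_p)
      i_va <- which(patients %in% val_p)
      i_te <- which(patients %in% test_p)
      if (length(i_te) == 0L)
        stop(sprintf("repeat %d fold %d has no test cycles", r, f))
      if (length(i_tr) == 0L)
        stop(sprintf("repeat %d fold %d has no training cycles", r, f))
      model <- model_factory(x[i_tr], y[i_tr], x[i_va], y[i_va])
      preds <- predict(model, x[i_te])
      cm <- confusion_counts(y[i_te], preds, task)
      ms <- suppressWarnings(compute_metrics(cm))
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = r, fold = f, n_test = cm$n,
        Acc = ms$Acc, Sen = ms$Sen, Spe = ms$Spe, Pre = ms$Pre,
        Sco = ms$Sco)
      for (nm in c("TP", "TN", "FP", "FN", "n"))
        agg[[nm]] <- agg[[nm]] + cm[[nm]]
      if (!is.null(cm$table))
        agg_tab <- if (is.null(agg_tab)) cm$table else agg_tab + cm$table
    }
  }
  per_fold <- do.call(rbind, rows)
  agg$task <- task; agg$table <- agg_tab
  class(agg) <- "confusion_counts"
  structure(list(per_fold = per_fold,
                 aggregate = suppressWarnings(compute_metrics(agg)),
                 mean_metrics = colMeans(
                   per_fold[, c("Acc", "Sen", "Spe", "Pre", "Sco")],
                   na.rm = TRUE),
                 confusion = agg, task = task),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s over %d fold evaluations\n",
              x$task, nrow(x$per_fold)))
  cat("aggregate: "); print(x$aggregate)
  cat("mean of per-fold metrics:\n")
  print(round(100 * x$mean_metrics, 1))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- list(task = report$task,
              aggregate = unclass(report$aggregate),
              mean_metrics = as.list(report$mean_metrics),
              confusion = report$confusion[c("TP", "TN", "FP", "FN", "n")],
              per_fold = report$per_fold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Compare two classifiers' per-fold scores
#'
#' Runs the (unpaired) Mann-Whitney U test and the paired Wilcoxon
#' signed-rank test, both two-sided. Exact p-values are used for small
#' tie-free samples (n <= 12), otherwise the normal approximation with
#' continuity and tie correction. The verdict at `alpha` is `"a"` or `"b"`
#' (the one with the larger median) when the Mann-Whitney test rejects,
#' else `"indistinguishable"`; the signed-rank p-value is reported
#' alongside (its exact two-sided p cannot fall below 0.05 for fewer than
#' six pairs, so it does not gate the verdict).
#'
#' @param scores_a,scores_b Per-fold score vectors. Must have equal length
#'   (paired) for the signed-rank test; at least 3 points each.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `model_comparison` with `u_statistic`, `u_p`,
#'   `v_statistic`, `v_p`, `alpha`, `verdict`.
#' @export
compare_models <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) < 3 || length(scores_b) < 3)
    stop("need at least 3 points per model")
  exact_u <- max(length(scores_a), length(scores_b)) <= 12 &&
    !any(duplicated(c(scores_a, scores_b)))
  mw <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, exact = exact_u,
                       correct = TRUE))
  v_stat <- NA_real_; v_p <- NA_real_
  if (length(scores_a) == length(scores_b)) {
    d <- scores_a - scores_b
    if (all(d == 0)) {
      v_stat <- 0; v_p <- 1                 # no differences: null holds
    } else {
      exact_v <- length(d) <= 12 && all(d != 0) &&
        !any(duplicated(abs(d)))
      sr <- suppressWarnings(
        stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                           exact = exact_v, correct = TRUE))
      v_stat <- unname(sr$statistic); v_p <- sr$p.value
    }
  }
  verdict <- if (mw$p.value < alpha) {
    if (stats::median(scores_a) >= stats::median(scores_b)) "a" else "b"
  } else "indistinguishable"
  structure(list(u_statistic = unname(mw$statistic), u_p = mw$p.value,
                 v_statistic = v_stat, v_p = v_p,
                 alpha = alpha, verdict = verdict),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (p = %.4g); signed-rank V = %g (p = %.4g)\n",
              x$u_statistic, x$u_p, x$v_statistic, x$v_p))
  cat(sprintf("verdict at alpha = %g: %s\n", x$alpha, x$verdict))
  invisible(x)
}
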
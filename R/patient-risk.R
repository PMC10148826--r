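#' Aggregate cell subgroup labels to patient counts
#'
#' Builds the per-patient total / C1 / C2 CTC counts from labelled cells.
#' Patients listed in `all_patients` but absent from the cell table get
#' zero counts and are flagged CTC-negative (to be excluded from
#' count-classifier evaluation).
#'
#' @param cells A [single_cell_matrix()] (only its annotations are used).
#' @param subgroup_labels Per-cell labels in `{"C1", "C2"}`.
#' @param all_patients Optional full patient roster.
#' @return data.frame: patient_id, total_ctc_count, c1_count, c2_count,
#'   ctc_negative.
#' @export
aggregate_patient_counts <- function(cells, subgroup_labels,
                                     all_patients = NULL) {
  stopifnot(inherits(cells, "single_cell_matrix"))
  labs <- as.character(subgroup_labels)
  if (length(labs) != length(cells$patient_id)) {
    stop("one subgroup label per cell is required")
  }
  if (!all(labs %in% c("C1", "C2"))) {
    stop("subgroup labels must be 'C1' or 'C2'")
  }
  pid <- cells$patient_id
  if (anyNA(pid) || any(pid == "")) stop("cell with unknown patient")
  roster <- if (is.null(all_patients)) unique(pid) else as.character(all_patients)
  if (!all(pid %in% roster)) {
    stop("cell(s) assigned to patients outside the roster: ",
         paste(setdiff(pid, roster), collapse = ", "))
  }
  c1 <- tapply(labs == "C1", pid, sum)
  c2 <- tapply(labs == "C2", pid, sum)
  out <- data.frame(patient_id = roster,
                    total_ctc_count = 0L, c1_count = 0L, c2_count = 0L,
                    ctc_negative = TRUE, stringsAsFactors = FALSE)
  idx <- match(names(c1), roster)
  out$c1_count[idx] <- as.integer(c1)
  out$c2_count[idx] <- as.integer(c2)
  out$total_ctc_count <- out$c1_count + out$c2_count
  out$ctc_negative <- out$total_ctc_count == 0L
  out
}

#' ROC curve and Mann-Whitney AUC
#'
#' The AUC is the Mann-Whitney probability that a positive patient's value
#' exceeds a negative's, with ties credited 0.5. ROC points are reported at
#' every distinct threshold. `direction = "greater"` treats higher values
#' as more positive (the default for total and C2 counts);
#' `direction = "less"` reverses the orientation (used for C1 counts,
#' where low counts are unfavorable).
#'
#' @param values Per-patient statistic.
#' @param outcomes Binary outcomes (1 = event).
#' @param direction `"greater"` or `"less"`.
#' @return List with `auc` and `roc` (data.frame threshold, sensitivity,
#'   specificity).
#' @export
roc_auc <- function(values, outcomes, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  outcomes <- as.integer(outcomes)
  stopifnot(length(values) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  if (length(unique(outcomes)) != 2) stop("both outcome classes must be present")
  v <- if (direction == "less") -as.numeric(values) else as.numeric(values)
  pos <- v[outcomes == 1]
  neg <- v[outcomes == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(v), decreasing = TRUE)
  roc <- data.frame(
    threshold = if (direction == "less") -thr else thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1))
  )
  list(auc = auc, roc = roc, direction = direction)
}

#' Youden-optimal count cutoff
#'
#' Maximizes `J = sensitivity + specificity - 1` over the observed count
#' values under the count-classifier rule: positive iff `count > cutoff`
#' for `direction = "greater"` (total and C2 counts) or `count < cutoff`
#' for `direction = "less"` (C1 counts). Ties go to the smallest cutoff.
#'
#' @param counts Integer counts.
#' @param outcomes Binary outcomes (1 = event).
#' @param direction `"greater"` or `"less"`.
#' @return Integer cutoff.
#' @export
optimal_count_cutoff <- function(counts, outcomes,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  outcomes <- as.integer(outcomes)
  if (length(unique(outcomes)) != 2) stop("both outcome classes must be present")
  cand <- sort(unique(counts))
  if (length(cand) < 2) stop("counts are constant; no cutoff exists")
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  # integer J numerator: exact tie handling (smallest tied cutoff wins)
  j_num <- vapply(cand, function(c) {
    pred <- classify_patients(counts, c, direction)
    sum(pred == 1 & outcomes == 1) * n_neg +
      sum(pred == 0 & outcomes == 0) * n_pos
  }, numeric(1))
  cand[which.max(j_num)]
}

#' Apply a count cutoff to patients
#'
#' Positive (unfavorable, metastasis-prone) iff `count > cutoff` under
#' `direction = "greater"`, or `count < cutoff` under `direction = "less"`.
#' A count exactly at the cutoff is negative in both directions.
#'
#' @param counts Integer counts.
#' @param cutoff Integer cutoff (>= 0).
#' @param direction `"greater"` or `"less"`.
#' @return Integer 0/1 predictions.
#' @export
classify_patients <- function(counts, cutoff,
                              direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(cutoff >= 0)
  if (direction == "greater") as.integer(counts > cutoff)
  else as.integer(counts < cutoff)
}

#' Confusion matrix and classification rates
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/n` from binary predictions and outcomes, with the percentage
#' forms rounded to one decimal.
#'
#' @param predictions,outcomes Equal-length binary vectors (1 = positive).
#' @param auc Optional AUC to carry along in the result.
#' @return An object of class `performance_metrics` with `confusion`
#'   (tp/fp/tn/fn), `sensitivity`, `specificity`, `accuracy` (fractions),
#'   and `*_pct` one-decimal percentages.
#' @export
performance_metrics <- function(predictions, outcomes, auc = NA_real_) {
  predictions <- as.integer(predictions)
  outcomes <- as.integer(outcomes)
  stopifnot(length(predictions) == length(outcomes))
  if (length(predictions) == 0) stop("empty input")
  if (!all(c(predictions, outcomes) %in% c(0L, 1L))) {
    stop("predictions and outcomes must be binary 0/1")
  }
  tp <- sum(predictions == 1 & outcomes == 1)
  fp <- sum(predictions == 1 & outcomes == 0)
  tn <- sum(predictions == 0 & outcomes == 0)
  fn <- sum(predictions == 0 & outcomes == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(outcomes)
  structure(list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = round(100 * sens, 1),
                 specificity_pct = round(100 * spec, 1),
                 accuracy_pct = round(100 * acc, 1),
                 auc = auc, n = length(outcomes)),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
              x$confusion[["tp"]], x$confusion[["fp"]], x$confusion[["tn"]],
              x$confusion[["fn"]], x$n))
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct))
  if (is.finite(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Reconstruct the integer confusion matrix behind printed rates
#'
#' Given a classifier's printed sensitivity and specificity (percent) and
#' the outcome group sizes, recovers the implied integer confusion matrix
#' (`TP = round(sens * n_pos)`, `TN = round(spec * n_neg)`) and re-derives
#' all rates from it with [performance_metrics()].
#'
#' @param sensitivity_pct,specificity_pct Printed percentages.
#' @param n_positive,n_negative Outcome group sizes.
#' @return A [performance_metrics()] object.
#' @export
implied_confusion <- function(sensitivity_pct, specificity_pct,
                              n_positive, n_negative) {
  tp <- round(sensitivity_pct / 100 * n_positive)
  tn <- round(specificity_pct / 100 * n_negative)
  fn <- n_positive - tp
  fp <- n_negative - tn
  predictions <- rep(c(1L, 0L, 0L, 1L), c(tp, fn, tn, fp))
  outcomes <- rep(c(1L, 1L, 0L, 0L), c(tp, fn, tn, fp))
  performance_metrics(predictions, outcomes)
}

#' Univariate and multivariate logistic association
#'
#' For each predictor: a univariate logistic fit of the outcome, and one
#' joint multivariate fit with all predictors entered together. Odds
#' ratios are `exp` of the natural-log coefficients with Wald 95%
#' confidence intervals. Separation triggers a flagged ridge-penalized
#' fallback (no CIs).
#'
#' @param patient_table data.frame with the outcome column and predictor
#'   columns.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the binary outcome column (default "outcome").
#' @return List with `univariate` and `multivariate` data.frames
#'   (predictor, odds_ratio, ci_low, ci_high, p_value, separation).
#' @export
logistic_association <- function(patient_table, predictors,
                                 outcome = "outcome") {
  stopifnot(is.data.frame(patient_table),
            all(c(predictors, outcome) %in% names(patient_table)))
  if (nrow(patient_table) < 10) stop("at least 10 patients are required")
  y <- as.integer(patient_table[[outcome]])
  if (length(unique(y)) != 2) stop("both outcome classes must be present")
  for (p in predictors) {
    if (length(unique(patient_table[[p]])) < 2) {
      stop("constant predictor: ", p)
    }
  }
  one_fit <- function(vars) {
    X <- patient_table[, vars, drop = FALSE]
    f <- safe_logistic(X, y)
    if (is.null(f$fit)) {
      co <- f$coef[match(make.names(vars), names(f$coef))]
      return(data.frame(predictor = vars, odds_ratio = exp(co),
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, separation = TRUE,
                        row.names = NULL))
    }
    sm <- summary(f$fit)$coefficients
    idx <- match(make.names(vars), rownames(sm))
    est <- sm[idx, 1]; se <- sm[idx, 2]; pv <- sm[idx, 4]
    data.frame(predictor = vars,
               odds_ratio = exp(est),
               ci_low = exp(est - 1.959964 * se),
               ci_high = exp(est + 1.959964 * se),
               p_value = pv, separation = f$separation, row.names = NULL)
  }
  uni <- do.call(rbind, lapply(predictors, one_fit))
  multi <- one_fit(predictors)
  list(univariate = uni, multivariate = multi)
}
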
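#' Single-cell metabolite concentration matrix
#'
#' Cells x metabolites matrix of non-negative concentrations (mM) with
#' per-cell patient and batch annotations.
#'
#' @param concentrations Cells x metabolites numeric matrix with rownames
#'   (cell ids) and colnames (metabolite names); entries >= 0.
#' @param patient_id Patient identifier per cell.
#' @param batch Batch label per cell.
#' @return An object of class `single_cell_matrix`.
#' @export
single_cell_matrix <- function(concentrations, patient_id,
                               batch = rep("B1", nrow(concentrations))) {
  concentrations <- as.matrix(concentrations)
  n <- nrow(concentrations)
  stopifnot(is.numeric(concentrations), length(patient_id) == n,
            length(batch) == n)
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations))) {
    stop("concentrations must carry cell ids (rownames) and metabolite names (colnames)")
  }
  if (anyDuplicated(rownames(concentrations))) stop("duplicated cell ids")
  if (anyNA(concentrations) || any(concentrations < 0)) {
    stop("concentrations must be non-negative and complete")
  }
  structure(list(concentrations = concentrations,
                 cell_ids = rownames(concentrations),
                 patient_id = as.character(patient_id),
                 batch = as.character(batch),
                 metabolite_names = colnames(concentrations)),
            class = "single_cell_matrix")
}

#' @export
print.single_cell_matrix <- function(x, ...) {
  cat(sprintf("single_cell_matrix: %d cells x %d metabolites, %d patients\n",
              nrow(x$concentrations), ncol(x$concentrations),
              length(unique(x$patient_id))))
  invisible(x)
}

as_nonneg_matrix <- function(x) {
  v <- if (inherits(x, "single_cell_matrix")) x$concentrations else as.matrix(x)
  if (anyNA(v) || any(v < 0)) stop("NMF input must be non-negative and complete")
  v
}

#' Non-negative matrix factorization (multiplicative updates)
#'
#' Lee–Seung multiplicative updates minimizing the squared Frobenius
#' reconstruction error of `V ~ W H`, with `W` (cells x k) and `H`
#' (k x metabolites) non-negative. The objective is non-increasing across
#' iterations; iteration stops when the relative improvement drops below
#' `tol` or at `max_iter`.
#'
#' @param x A [single_cell_matrix()] or non-negative matrix (rows =
#'   cells/observations).
#' @param k Factorization rank, `0 < k < min(dim)`.
#' @param seed Integer seed for the uniform random initialization.
#' @param max_iter Iteration cap (default 2000).
#' @param tol Relative-improvement stopping tolerance (default 1e-5).
#' @return An object of class `nmf_result` with `W`, `H`,
#'   `objective_trace`, `k`, `seed`, and `cluster` (argmax-of-W row
#'   labels).
#' @export
nmf <- function(x, k, seed = 1, max_iter = 2000, tol = 1e-5) {
  V <- as_nonneg_matrix(x)
  n <- nrow(V); p <- ncol(V)
  if (k <= 0 || k >= min(n, p)) stop("rank k must satisfy 0 < k < min(dim(V))")
  eps <- .Machine$double.eps
  with_seed(seed, {
    scale0 <- sqrt(mean(V) / k)
    W <- matrix(stats::runif(n * k, 0, 2 * scale0), n, k)
    H <- matrix(stats::runif(k * p, 0, 2 * scale0), k, p)
    obj <- numeric(max_iter)
    prev <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sum((V - W %*% H)^2)
      obj[it] <- err
      if (it >= max_iter) break
      if (is.finite(prev) && (prev - err) <= tol * max(prev, eps)) break
      prev <- err
    }
    structure(list(W = W, H = H, objective_trace = obj[seq_len(it)],
                   k = k, seed = seed,
                   cluster = max.col(W, ties.method = "first")),
              class = "nmf_result")
  })
}

#' Consensus NMF clustering with cophenetic rank selection
#'
#' For each candidate rank, runs `n_runs` NMF fits from distinct seeds,
#' converts each run's argmax-of-W labels into a cell x cell connectivity
#' matrix, and averages them into a consensus matrix. The cophenetic
#' coefficient of a rank is the Pearson correlation between the consensus
#' dissimilarity `1 - consensus` and the cophenetic distances of its
#' average-linkage dendrogram. The selected rank maximizes the cophenetic
#' coefficient (ties go to the smaller rank) and cell labels come from
#' cutting that dendrogram into `selected_rank` clusters.
#'
#' @param x A [single_cell_matrix()] or non-negative matrix.
#' @param k_range Candidate ranks (default 2:6).
#' @param n_runs NMF restarts per rank (default 30).
#' @param seed Root seed; run seeds are derived from it.
#' @param ... Passed to [nmf()] (`max_iter`, `tol`).
#' @return An object of class `consensus_result` with per-rank consensus
#'   matrices and cophenetic coefficients, `selected_rank`, and
#'   `cell_labels`.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_runs = 30, seed = 1, ...) {
  V <- as_nonneg_matrix(x)
  n <- nrow(V)
  if (n_runs < 2) stop("n_runs must be at least 2")
  if (any(k_range <= 0) || max(k_range) >= min(dim(V))) {
    stop("k_range must satisfy 0 < k < min(dim(V))")
  }
  if (n < 2 * max(k_range)) stop("need at least 2 * max(k_range) cells")
  run_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, length(k_range) * n_runs))
  consensus <- list()
  cophenetic <- stats::setNames(numeric(length(k_range)),
                                as.character(k_range))
  dendro <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cons <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      fit <- nmf(V, k, seed = run_seeds[(i - 1L) * n_runs + r], ...)
      lab <- fit$cluster
      cons <- cons + outer(lab, lab, `==`)
    }
    cons <- cons / n_runs
    dimnames(cons) <- list(rownames(V), rownames(V))
    d_cons <- stats::as.dist(1 - cons)
    hc <- stats::hclust(d_cons, method = "average")
    d_coph <- stats::cophenetic(hc)
    cophenetic[i] <- if (stats::sd(d_cons) < 1e-12 ||
                         stats::sd(d_coph) < 1e-12) {
      # degenerate: all pairwise consensus identical; call it perfect
      # agreement only when the tree reproduces the distances exactly
      if (max(abs(d_cons - d_coph)) < 1e-12) 1 else 0
    } else {
      stats::cor(d_cons, d_coph)
    }
    consensus[[as.character(k)]] <- cons
    dendro[[as.character(k)]] <- hc
  }
  best <- k_range[which.max(cophenetic)]   # which.max takes the first tie
  labels <- stats::cutree(dendro[[as.character(best)]], k = best)
  structure(list(consensus = consensus, cophenetic = cophenetic,
                 k_range = k_range, selected_rank = best,
                 cell_labels = labels, dendrograms = dendro),
            class = "consensus_result")
}

#' Cell labels from a consensus dendrogram cut
#'
#' Cuts the average-linkage dendrogram of a stored consensus matrix into
#' `k` clusters. Useful to obtain the binary C1/C2 partition when the
#' cophenetic criterion selects a finer rank: the risk-score subgrouping is
#' two-class by definition, so downstream modelling uses the `k = 2` cut of
#' the rank-2 consensus.
#'
#' @param result A [consensus_cluster()] result.
#' @param k Number of clusters; must be one of the searched ranks.
#' @return Integer cluster labels named by cell id.
#' @export
consensus_labels <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  key <- as.character(k)
  if (!key %in% names(result$dendrograms)) {
    stop("rank ", k, " was not part of the searched range")
  }
  stats::cutree(result$dendrograms[[key]], k = k)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus NMF clustering\n  cophenetic by rank: ",
      paste(sprintf("k=%s: %.3f", names(x$cophenetic), x$cophenetic),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  selected rank: %d\n", x$selected_rank))
  invisible(x)
}

# logistic fit with ridge fallback on (quasi-)separation; returns the glm
# (or glmnet-backed coefficients) plus a `separation` flag
safe_logistic <- function(X, y, penalize_on_separation = TRUE) {
  df <- data.frame(y = y, X, check.names = TRUE)  # coef names = make.names()
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 20 /
                                 pmax(apply(as.matrix(X), 2, stats::sd), 1e-8))
  if (sep && penalize_on_separation && ncol(as.matrix(X)) >= 2 &&
      requireNamespace("glmnet", quietly = TRUE)) {
    gfit <- glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = TRUE)
    co <- as.numeric(stats::coef(gfit))
    nm <- rownames(stats::coef(gfit))
    names(co) <- c(nm[1], make.names(nm[-1]))  # align with glm's term names
    return(list(coef = co, fit = NULL, separation = TRUE))
  }
  list(coef = stats::coef(fit), fit = fit, separation = sep)
}

#' Backward-eliminated metabolite fingerprint
#'
#' Logistic regression of the two-level cell cluster label on all
#' standardized panel metabolites, followed by backward elimination: while
#' any Wald p-value is at or above `alpha`, the metabolite with the largest
#' p is dropped and the model refitted. Survivors are returned ordered by
#' decreasing absolute standardized coefficient.
#'
#' @param x A [single_cell_matrix()].
#' @param cell_labels Two-level labels, one per cell.
#' @param alpha Retention threshold on Wald p-values (default 0.05).
#' @return Character vector of metabolite names (possibly empty), with a
#'   `separation` attribute flagging a penalized fallback.
#' @export
select_fingerprint <- function(x, cell_labels, alpha = 0.05) {
  stopifnot(inherits(x, "single_cell_matrix"))
  labs <- as.character(cell_labels)
  lv <- sort(unique(labs))
  if (length(lv) != 2) stop("select_fingerprint requires exactly 2 label values")
  y <- as.integer(labs == lv[2])
  Xz <- scale(x$concentrations)
  keep <- colnames(Xz)[apply(Xz, 2, function(c) stats::sd(c) > 0 && !anyNA(c))]
  Xz <- Xz[, keep, drop = FALSE]
  separation_seen <- FALSE
  current <- colnames(Xz)
  while (length(current) > 0) {
    f <- safe_logistic(Xz[, current, drop = FALSE], y)
    separation_seen <- separation_seen || f$separation
    if (is.null(f$fit)) {
      # penalized fit has no Wald p-values; keep all remaining terms
      break
    }
    sm <- summary(f$fit)$coefficients
    pv <- sm[match(make.names(current), rownames(sm)), 4]
    pv[is.na(pv)] <- 1
    if (all(pv < alpha)) break
    current <- current[-which.max(pv)]
  }
  if (length(current) == 0) {
    out <- character(0)
  } else {
    f <- safe_logistic(Xz[, current, drop = FALSE], y)
    co <- f$coef[match(make.names(current), names(f$coef))]
    out <- current[order(abs(co), decreasing = TRUE)]
  }
  attr(out, "separation") <- separation_seen
  out
}

#' Logistic risk model on a base-10 logit scale
#'
#' Holds a per-cell metabolic risk score of the form
#' \deqn{\log_{10}\frac{s}{1-s} = \sum_i \beta_i x_i + \beta_0,}
#' with abundances `x` in mM, together with the score threshold separating
#' the low-risk (C1) and high-risk (C2) subgroups.
#'
#' @param metabolite_names Ordered metabolite names.
#' @param coefficients Base-10 logit coefficients (per mM), one per
#'   metabolite.
#' @param intercept Base-10 logit intercept.
#' @param threshold Score threshold in (0, 1).
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(metabolite_names, coefficients, intercept, threshold) {
  stopifnot(length(metabolite_names) == length(coefficients),
            is.finite(intercept), threshold > 0, threshold < 1)
  structure(list(metabolite_names = as.character(metabolite_names),
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                metabolite_names),
                 intercept = as.numeric(intercept),
                 threshold = as.numeric(threshold),
                 logit_base = 10),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3f x [%s]", x$coefficients, x$metabolite_names),
                 collapse = " ")
  cat("risk_model (base-10 logit):\n  log10(s/(1-s)) =", terms,
      sprintf("%+.3f\n", x$intercept))
  cat(sprintf("  threshold: C2 iff score >= %.3f\n", x$threshold))
  invisible(x)
}

#' The published four-metabolite CTC risk model
#'
#' The fixed classifier
#' `log10(s/(1-s)) = -0.932*glutamic + 3.967*malic - 0.166*aspartic
#'  - 1.822*lactic - 3.694` with abundances in mM, and subgroup threshold
#' `s >= 0.420` for the high-risk C2 subgroup.
#'
#' @return A [risk_model()].
#' @export
published_risk_model <- function() {
  risk_model(
    metabolite_names = c("glutamic acid", "malic acid", "aspartic acid",
                         "lactic acid"),
    coefficients = c(-0.932, 3.967, -0.166, -1.822),
    intercept = -3.694,
    threshold = 0.420
  )
}

#' Evaluate a risk model on metabolite abundances
#'
#' Computes `s = 10^eta / (1 + 10^eta)` with
#' `eta = sum(coef * abundance) + intercept`. Abundances are matched to the
#' model's metabolites by name, never by position; a missing metabolite is
#' an error (no silent imputation).
#'
#' @param model A [risk_model()].
#' @param abundances Named numeric vector, named matrix (cells x
#'   metabolites), or [single_cell_matrix()] covering all model
#'   metabolites; mM.
#' @return Risk score(s) in (0, 1).
#' @export
risk_score <- function(model, abundances) {
  stopifnot(inherits(model, "risk_model"))
  if (inherits(abundances, "single_cell_matrix")) {
    abundances <- abundances$concentrations
  }
  if (is.matrix(abundances) || is.data.frame(abundances)) {
    abundances <- as.matrix(abundances)
    missing <- setdiff(model$metabolite_names, colnames(abundances))
    if (length(missing) > 0) {
      stop("missing metabolite(s): ", paste(missing, collapse = ", "))
    }
    X <- abundances[, model$metabolite_names, drop = FALSE]
    if (anyNA(X)) stop("abundances contain NA; quantify or drop those cells first")
    eta <- as.numeric(X %*% model$coefficients + model$intercept)
  } else {
    missing <- setdiff(model$metabolite_names, names(abundances))
    if (length(missing) > 0) {
      stop("missing metabolite(s): ", paste(missing, collapse = ", "))
    }
    x <- abundances[model$metabolite_names]
    if (anyNA(x)) stop("abundances contain NA")
    eta <- sum(x * model$coefficients) + model$intercept
  }
  stats::plogis(eta * log(10))
}

#' Youden-index cutoff on scores
#'
#' Scans the unique observed scores as candidate cutoffs under the rule
#' "positive iff score >= cutoff" and returns the cutoff maximizing
#' `J = sensitivity + specificity - 1`; ties go to the smallest cutoff.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical), 1 = positive class.
#' @return The selected cutoff.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) != 2) stop("both label values must be present")
  cand <- sort(unique(scores))
  if (length(cand) < 2) stop("scores are all identical; no cutoff exists")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  # exact integer numerator of J over the common denominator n_pos * n_neg,
  # so ties are exact and the smallest tied cutoff wins deterministically
  j_num <- vapply(cand, function(c) {
    pred <- scores >= c
    sum(pred & labels == 1) * n_neg + sum(!pred & labels == 0) * n_pos
  }, numeric(1))
  cand[which.max(j_num)]   # which.max returns the first (smallest) maximizer
}

#' Assign cells to the C1/C2 subgroups
#'
#' C2 (high risk) iff `score >= threshold`; the boundary is closed, so a
#' score exactly at the threshold is C2.
#'
#' @param scores Risk scores in (0, 1).
#' @param threshold Score threshold (default 0.420).
#' @return Character vector in `{"C1", "C2"}`.
#' @export
assign_subgroups <- function(scores, threshold = 0.420) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(scores >= threshold, "C2", "C1")
}

#' Fit a logistic risk model from cluster labels
#'
#' Maximum-likelihood logistic regression of the two-level cell label on
#' the raw (mM) fingerprint abundances. Natural-log coefficients are
#' divided by `ln(10)` so the stored model is on the base-10 logit scale.
#' The high-risk orientation is fixed so that, after a provisional fit, the
#' cluster with the higher mean score is the positive (C2) class; when
#' per-cell training outcomes are supplied, the orientation is instead
#' chosen so the score correlates positively with them. The threshold is
#' the [youden_cutoff()] of the training scores against the oriented
#' labels.
#'
#' @param x A [single_cell_matrix()].
#' @param cell_labels Two-level cluster labels per cell.
#' @param fingerprint Metabolite subset to use (default
#'   [select_fingerprint()] order is the caller's responsibility).
#' @param outcomes Optional per-cell binary outcome used only to orient the
#'   high-risk class.
#' @return A [risk_model()] with attributes `positive_cluster` and
#'   `separation`.
#' @export
fit_risk_model <- function(x, cell_labels, fingerprint, outcomes = NULL) {
  stopifnot(inherits(x, "single_cell_matrix"))
  if (!all(fingerprint %in% x$metabolite_names)) {
    stop("fingerprint metabolites missing from the panel")
  }
  labs <- as.character(cell_labels)
  lv <- sort(unique(labs))
  if (length(lv) != 2) stop("fit_risk_model requires exactly 2 label values")
  X <- x$concentrations[, fingerprint, drop = FALSE]
  y <- as.integer(labs == lv[2])
  f <- safe_logistic(as.data.frame(X, check.names = FALSE), y)
  co <- f$coef
  beta <- co[match(make.names(fingerprint), names(co))]
  names(beta) <- fingerprint
  beta0 <- co[["(Intercept)"]]
  # orientation: positive class = high-risk
  eta <- as.numeric(X %*% beta + beta0)
  flip <- FALSE
  if (!is.null(outcomes)) {
    flip <- stats::cor(eta, as.numeric(outcomes)) < 0
  } else {
    flip <- mean(eta[y == 1]) < mean(eta[y == 0])
  }
  positive <- if (flip) lv[1] else lv[2]
  if (flip) {
    beta <- -beta; beta0 <- -beta0
    y <- 1L - y
    eta <- -eta
  }
  model <- risk_model(fingerprint, beta / log(10), beta0 / log(10),
                      threshold = 0.5)
  scores <- stats::plogis(eta)
  model$threshold <- tryCatch(youden_cutoff(scores, y), error = function(e) 0.5)
  attr(model, "positive_cluster") <- positive
  attr(model, "separation") <- f$separation
  model
}
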
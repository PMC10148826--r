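#' Bulk metabolomics feature matrix
#'
#' Container for an untargeted metabolomics screen: a features x samples
#' intensity matrix (NA = not detected) with per-sample group, batch, QC
#' flag and protein amount, plus the identifier of the internal-standard
#' feature (which must be fully observed).
#'
#' @param intensities Features x samples numeric matrix with rownames
#'   (feature ids) and colnames (sample ids); `NA` marks missing peaks.
#' @param group Group label per sample (e.g. "primary"/"metastatic"; QC
#'   samples conventionally "QC").
#' @param batch Batch label per sample.
#' @param is_qc Logical per sample.
#' @param protein_ug Protein amount per sample in micrograms (> 0).
#' @param is_feature_id Row name of the internal-standard feature (e.g.
#'   spiked acetaminophen), or `NA` if the matrix carries none.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(intensities, group, batch = rep("B1", ncol(intensities)),
                           is_qc = rep(FALSE, ncol(intensities)),
                           protein_ug = rep(1, ncol(intensities)),
                           is_feature_id = NA_character_) {
  intensities <- as.matrix(intensities)
  n <- ncol(intensities)
  stopifnot(is.numeric(intensities), length(group) == n, length(batch) == n,
            length(is_qc) == n, length(protein_ug) == n)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must carry feature ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(intensities))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(intensities))) stop("duplicated sample ids")
  if (any(protein_ug <= 0)) stop("protein_ug must be positive for every sample")
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  if (!is.na(is_feature_id)) {
    if (!is_feature_id %in% rownames(intensities)) {
      stop("is_feature_id not found among the features")
    }
    if (anyNA(intensities[is_feature_id, ])) {
      stop("internal-standard feature must be observed in every sample")
    }
  }
  structure(list(intensities = intensities,
                 feature_ids = rownames(intensities),
                 sample_ids = colnames(intensities),
                 group = as.character(group),
                 batch = as.character(batch),
                 is_qc = as.logical(is_qc),
                 protein_ug = as.numeric(protein_ug),
                 is_feature_id = is_feature_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples (%d QC), %d batches\n",
              nrow(x$intensities), ncol(x$intensities), sum(x$is_qc),
              length(unique(x$batch))))
  invisible(x)
}

replace_intensities <- function(fm, values, keep = NULL) {
  fm$intensities <- values
  if (!is.null(keep)) {
    fm$feature_ids <- rownames(values)
  }
  fm$feature_ids <- rownames(fm$intensities)
  fm
}

biological_cols <- function(fm) !fm$is_qc

#' Detection and signal-to-noise feature filtering
#'
#' A feature is removed when its detection fraction is below
#' `min_detect_frac` in every (non-QC) group, or when its maximum observed
#' intensity is below `min_snr` times its blank noise level. Remaining
#' features keep their original order.
#'
#' @param fm A [feature_matrix()].
#' @param min_detect_frac Detection-fraction threshold in (0, 1]
#'   (default 0.8).
#' @param min_snr Signal-to-noise threshold (default 3).
#' @param blank_profile Named per-feature noise level (e.g. the average
#'   signal across blank runs); features absent from it are exempt from the
#'   S/N rule.
#' @return Filtered `feature_matrix`.
#' @export
filter_features <- function(fm, min_detect_frac = 0.8, min_snr = 3,
                            blank_profile = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (min_detect_frac <= 0 || min_detect_frac > 1) {
    stop("min_detect_frac must lie in (0, 1]")
  }
  bio <- biological_cols(fm)
  groups <- unique(fm$group[bio])
  if (length(groups) == 0) stop("no non-QC samples to filter on")
  detect_ok <- rep(FALSE, nrow(fm$intensities))
  for (g in groups) {
    sel <- bio & fm$group == g
    frac <- rowMeans(!is.na(fm$intensities[, sel, drop = FALSE]))
    detect_ok <- detect_ok | frac >= min_detect_frac
  }
  snr_ok <- rep(TRUE, nrow(fm$intensities))
  if (!is.null(blank_profile)) {
    idx <- match(rownames(fm$intensities), names(blank_profile))
    maxint <- suppressWarnings(
      apply(fm$intensities[, bio, drop = FALSE], 1, max, na.rm = TRUE))
    has_noise <- !is.na(idx)
    snr_ok[has_noise] <- is.finite(maxint[has_noise]) &
      maxint[has_noise] >= min_snr * blank_profile[idx[has_noise]]
  }
  keep <- detect_ok & snr_ok
  if (!is.na(fm$is_feature_id)) keep[rownames(fm$intensities) == fm$is_feature_id] <- TRUE
  fm$intensities <- fm$intensities[keep, , drop = FALSE]
  fm$feature_ids <- rownames(fm$intensities)
  fm
}

#' Minimum-based missing value imputation
#'
#' Each missing entry is replaced by one tenth of that feature's minimum
#' observed intensity; observed entries are untouched.
#'
#' @param fm A [feature_matrix()].
#' @return Imputed `feature_matrix` (no remaining `NA`).
#' @export
impute_missing <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$intensities
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("feature(s) with no observed value: ",
         paste(rownames(v)[all_missing], collapse = ", "),
         " (should have been filtered)")
  }
  mins <- apply(v, 1, min, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx) > 0) v[idx] <- mins[idx[, 1]] / 10
  fm$intensities <- v
  fm
}

#' Protein / internal-standard / QC normalization
#'
#' Per sample, intensities are divided by the protein amount and by the
#' sample's internal-standard intensity; then, per batch, each feature is
#' divided by its median across the batch's QC samples. The
#' internal-standard feature is removed from the output.
#'
#' @param fm A [feature_matrix()] with an internal-standard feature and at
#'   least one QC sample per batch.
#' @return Normalized `feature_matrix` (QC columns retained, IS row
#'   removed).
#' @export
normalize_bulk <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.na(fm$is_feature_id)) stop("no internal-standard feature defined")
  is_int <- fm$intensities[fm$is_feature_id, ]
  if (any(is_int <= 0)) stop("internal-standard intensity must be positive in every sample")
  v <- sweep(fm$intensities, 2, fm$protein_ug, `/`)
  v <- sweep(v, 2, is_int, `/`)
  for (b in unique(fm$batch)) {
    qc_sel <- fm$batch == b & fm$is_qc
    if (!any(qc_sel)) stop("batch ", b, " has no QC sample")
    qc_med <- apply(v[, qc_sel, drop = FALSE], 1, stats::median, na.rm = TRUE)
    bad <- !is.finite(qc_med) | qc_med <= 0
    qc_med[bad] <- 1
    v[, fm$batch == b] <- v[, fm$batch == b, drop = FALSE] / qc_med
  }
  keep <- rownames(v) != fm$is_feature_id
  fm$intensities <- v[keep, , drop = FALSE]
  fm$feature_ids <- rownames(fm$intensities)
  fm$is_feature_id <- NA_character_
  fm
}

# NIPALS O-PLS for a single binary response. X: n x p (rows samples),
# y: numeric +/-1 style coding. Returns predictive weights/scores/loadings,
# orthogonal components, and cumulative R2/Q2 statistics.
opls_core <- function(X, y, n_orth) {
  # unit-norm weight vector; a zero covariance vector (y orthogonal to every
  # feature) degenerates to a flat direction with ~zero predictive scores
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv < 1e-300) rep(1 / sqrt(length(v)), length(v))
    else v / nv
  }
  Xd <- X
  w <- unit(crossprod(Xd, y))
  To <- Po <- Wo <- NULL
  if (n_orth > 0) {
    for (i in seq_len(n_orth)) {
      t_p <- Xd %*% w
      p_p <- crossprod(Xd, t_p) / sum(t_p^2)
      w_o <- p_p - as.numeric(crossprod(w, p_p)) * w
      nw <- sqrt(sum(w_o^2))
      if (!is.finite(nw) || nw < 1e-12) break
      w_o <- w_o / nw
      t_o <- Xd %*% w_o
      p_o <- crossprod(Xd, t_o) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      To <- cbind(To, t_o); Po <- cbind(Po, p_o); Wo <- cbind(Wo, w_o)
      w <- unit(crossprod(Xd, y))
    }
  }
  t_p <- Xd %*% w
  p_p <- crossprod(Xd, t_p) / sum(t_p^2)
  q <- as.numeric(crossprod(y, t_p) / sum(t_p^2))
  list(w = w, t = t_p, p = p_p, q = q, To = To, Po = Po, Wo = Wo,
       X_deflated = Xd)
}

opls_predict <- function(fit, Xnew) {
  Xd <- Xnew
  if (!is.null(fit$Wo)) {
    for (i in seq_len(ncol(fit$Wo))) {
      t_o <- Xd %*% fit$Wo[, i, drop = FALSE]
      Xd <- Xd - t_o %*% t(fit$Po[, i, drop = FALSE])
    }
  }
  as.numeric((Xd %*% fit$w) * fit$q)
}

#' Orthogonal PLS discriminant analysis
#'
#' NIPALS O-PLS with one predictive component for a two-group comparison.
#' Features are mean-centered and unit-variance scaled internally; constant
#' features are dropped with a warning. Orthogonal components are added
#' while the 7-fold cross-validated Q2 improves by more than `q2_gain`
#' (capped at `max_orth`). VIP scores are computed from the predictive
#' component, so the mean squared VIP is exactly 1.
#'
#' @param fm A [feature_matrix()] (imputed; QC samples are ignored).
#' @param group_labels Optional two-level labels for the non-QC samples
#'   (defaults to the matrix's own `group`).
#' @param n_folds Cross-validation folds (default 7).
#' @param q2_gain Minimum Q2 improvement to accept another orthogonal
#'   component (default 0.01).
#' @param max_orth Cap on orthogonal components (default 5).
#' @return An object of class `opls_model` with `vip`, `r2x_cum`,
#'   `r2y_cum`, `q2_cum`, scores and loadings.
#' @export
opls_da <- function(fm, group_labels = NULL, n_folds = 7, q2_gain = 0.01,
                    max_orth = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  bio <- biological_cols(fm)
  X <- t(fm$intensities[, bio, drop = FALSE])
  if (anyNA(X)) stop("opls_da requires an imputed matrix (no NA)")
  labs <- if (is.null(group_labels)) fm$group[bio] else as.character(group_labels)
  lv <- sort(unique(labs))
  if (length(lv) != 2) stop("opls_da requires exactly 2 groups")
  if (min(table(labs)) < 3) stop("each group needs at least 3 samples")
  y <- ifelse(labs == lv[2], 1, -1)
  y <- y - mean(y)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  const <- sdv < 1e-12
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped from OPLS-DA")
    X <- X[, !const, drop = FALSE]
    mu <- mu[!const]; sdv <- sdv[!const]
  }
  Xs <- scale(X, center = mu, scale = sdv)
  n <- nrow(Xs)
  ss_y <- sum(y^2)

  cv_q2 <- function(n_orth) {
    folds <- rep_len(seq_len(min(n_folds, n)), n)
    # deterministic interleaved folds keep both groups in every fold
    folds <- folds[order(order(labs, seq_len(n)))]
    press <- 0
    for (f in unique(folds)) {
      tr <- folds != f
      mu_t <- colMeans(X[tr, , drop = FALSE])
      sd_t <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd_t[sd_t < 1e-12] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu_t, sd_t)
      ytr <- y[tr] - mean(y[tr])
      fit <- opls_core(Xtr, ytr, n_orth)
      Xte <- scale(X[!tr, , drop = FALSE], mu_t, sd_t)
      pred <- opls_predict(fit, Xte)
      press <- press + sum(((y[!tr] - mean(y[tr])) - pred)^2)
    }
    1 - press / ss_y
  }

  q2 <- cv_q2(0)
  n_orth <- 0
  while (n_orth < max_orth) {
    q2_next <- cv_q2(n_orth + 1)
    if (q2_next > q2 + q2_gain) {
      n_orth <- n_orth + 1
      q2 <- q2_next
    } else break
  }
  fit <- opls_core(Xs, y, n_orth)
  y_hat <- as.numeric(fit$t * fit$q)
  r2y <- 1 - sum((y - y_hat)^2) / ss_y
  ss_x <- sum(Xs^2)
  expl <- sum((fit$t %*% t(fit$p))^2)
  if (!is.null(fit$To)) expl <- expl + sum((fit$To %*% t(fit$Po))^2)
  vip <- sqrt(length(fit$w)) * abs(fit$w) / sqrt(sum(fit$w^2))
  vip_full <- stats::setNames(rep(0, length(const)), names(const))
  vip_full[!const] <- as.numeric(vip)
  structure(list(weights = fit$w, scores = fit$t, loadings = fit$p,
                 orth_scores = fit$To, orth_loadings = fit$Po,
                 n_orth = n_orth,
                 r2x_cum = expl / ss_x, r2y_cum = r2y, q2_cum = q2,
                 vip = vip_full,
                 groups = lv, positive_group = lv[2]),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA (%s vs %s): 1 predictive + %d orthogonal component(s)\n",
    x$groups[1], x$groups[2], x$n_orth))
  cat(sprintf("  R2X(cum) = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f\n",
              x$r2x_cum, x$r2y_cum, x$q2_cum))
  invisible(x)
}

#' Differential abundance table
#'
#' Per feature: log2 fold change of linear-scale group means (metastatic
#' over primary), a two-tailed equal-variance Student's t-test on log10
#' intensities, the OPLS-DA VIP, and the selection flag
#' `|log2FC| > 1 & p < 0.05 & VIP > 1` (all inequalities strict).
#'
#' @param fm An imputed, normalized [feature_matrix()].
#' @param opls An [opls_da()] model fitted on the same features.
#' @param numerator_group Group treated as the fold-change numerator
#'   (default "metastatic").
#' @param log2fc_min,p_max,vip_min Selection thresholds (defaults 1, 0.05,
#'   1).
#' @return data.frame with feature_id, log2_fold_change, p_value, vip,
#'   selected.
#' @export
differential_table <- function(fm, opls, numerator_group = "metastatic",
                               log2fc_min = 1, p_max = 0.05, vip_min = 1) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(opls, "opls_model"))
  bio <- biological_cols(fm)
  labs <- fm$group[bio]
  lv <- unique(labs)
  if (length(lv) != 2) stop("differential_table requires exactly 2 groups")
  if (!numerator_group %in% lv) {
    stop("numerator_group '", numerator_group, "' not among the groups")
  }
  denom_group <- setdiff(lv, numerator_group)
  v <- fm$intensities[, bio, drop = FALSE]
  if (anyNA(v)) stop("differential_table requires an imputed matrix")
  num <- v[, labs == numerator_group, drop = FALSE]
  den <- v[, labs == denom_group, drop = FALSE]
  m_num <- rowMeans(num)
  m_den <- rowMeans(den)
  if (any(m_num <= 0) || any(m_den <= 0)) stop("zero group mean intensity")
  l2fc <- log2(m_num / m_den)
  # equal-variance two-sample t on log10 intensities, computed directly so
  # degenerate (zero-spread) features yield p = 1 or p = 0 instead of erroring
  pvals <- vapply(seq_len(nrow(v)), function(i) {
    x <- log10(pmax(num[i, ], .Machine$double.xmin))
    y <- log10(pmax(den[i, ], .Machine$double.xmin))
    n1 <- length(x); n2 <- length(y)
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
    d <- mean(x) - mean(y)
    if (sp2 < 1e-28) return(if (abs(d) < 1e-14) 1 else 0)
    tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
    2 * stats::pt(-abs(tt), df)
  }, numeric(1))
  vip <- opls$vip[rownames(v)]
  vip[is.na(vip)] <- 0
  data.frame(feature_id = rownames(v),
             log2_fold_change = unname(l2fc),
             p_value = pvals,
             vip = unname(vip),
             selected = abs(l2fc) > log2fc_min & pvals < p_max & vip > vip_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersection of differential panels
#'
#' Feature ids selected in both differential tables, sorted
#' lexicographically.
#'
#' @param table_a,table_b [differential_table()] results on a common
#'   feature namespace.
#' @return Character vector of shared selected feature ids.
#' @export
shared_panel <- function(table_a, table_b) {
  sel_a <- table_a$feature_id[table_a$selected]
  sel_b <- table_b$feature_id[table_b$selected]
  sort(intersect(sel_a, sel_b))
}

#' Per-feature z-score transform
#'
#' Centers and scales each feature across all samples.
#'
#' @param fm A [feature_matrix()] (or plain features x samples matrix).
#' @return Features x samples matrix of z-scores.
#' @export
zscore_transform <- function(fm) {
  v <- if (inherits(fm, "feature_matrix")) fm$intensities else as.matrix(fm)
  if (anyNA(v)) stop("zscore_transform requires a complete matrix")
  sdv <- apply(v, 1, stats::sd)
  if (any(sdv < 1e-14)) {
    stop("zero-variance feature(s): ",
         paste(rownames(v)[sdv < 1e-14], collapse = ", "))
  }
  (v - rowMeans(v)) / sdv
}
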
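# in-code fixtures shared across test files

# tiny feature matrix with explicit values; vals is features x samples
make_fm <- function(vals, group, batch = NULL, is_qc = NULL,
                    protein = NULL, is_id = NA_character_) {
  n <- ncol(vals)
  if (is.null(rownames(vals))) rownames(vals) <- paste0("f", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("s", seq_len(n))
  feature_matrix(vals, group = group,
                 batch = if (is.null(batch)) rep("B1", n) else batch,
                 is_qc = if (is.null(is_qc)) rep(FALSE, n) else is_qc,
                 protein_ug = if (is.null(protein)) rep(1, n) else protein,
                 is_feature_id = is_id)
}

# two clearly separated non-negative cell blocks for clustering tests
make_blocks <- function(n_per = 25, p = 11, shift = 6, noise = 0.05,
                        seed = 1) {
  set.seed(seed)
  base <- matrix(1, 2 * n_per, p)
  base[seq_len(n_per), seq_len(4)] <- shift
  v <- base * matrix(exp(rnorm(2 * n_per * p, 0, noise)), 2 * n_per, p)
  dimnames(v) <- list(sprintf("c%03d", seq_len(2 * n_per)),
                      paste0("m", seq_len(p)))
  v
}

# brute-force Mann-Whitney AUC by pair enumeration (independent oracle)
auc_bruteforce <- function(values, outcomes) {
  pos <- values[outcomes == 1]
  neg <- values[outcomes == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# exhaustive Youden search under "positive iff score >= cutoff"; J compared
# through its exact integer numerator so tied cutoffs resolve deterministically
youden_bruteforce <- function(scores, labels) {
  cand <- sort(unique(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  best_j <- -Inf
  best <- NA_real_
  for (c in cand) {
    pred <- scores >= c
    j <- sum(pred[labels == 1]) * n_neg + sum(!pred[labels == 0]) * n_pos
    if (j > best_j) {
      best_j <- j
      best <- c
    }
  }
  best
}
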
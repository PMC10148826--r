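test_that("NMF reconstructs exact low-rank structure", {
  set.seed(2)
  w <- runif(30, 0.5, 2)
  h <- runif(8, 0.5, 2)
  V <- w %o% h
  dimnames(V) <- list(paste0("c", 1:30), paste0("m", 1:8))
  fit <- nmf(V, 1, seed = 1)
  rel_err <- sqrt(sum((V - fit$W %*% fit$H)^2) / sum(V^2))
  expect_lt(rel_err, 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("NMF objective trace is non-increasing across random problems", {
  set.seed(3)
  for (i in 1:20) {
    V <- matrix(runif(50 * 11), 50, 11,
                dimnames = list(paste0("c", 1:50), paste0("m", 1:11)))
    fit <- nmf(V, sample(2:4, 1), seed = i, max_iter = 300)
    expect_true(all(diff(fit$objective_trace) <= 1e-9 *
                      fit$objective_trace[1]))
  }
  expect_error(nmf(matrix(-1, 4, 4), 2), "non-negative")
  expect_error(nmf(matrix(1, 4, 4,
                          dimnames = list(1:4, 1:4)), 0), "rank")
})

test_that("NMF labels recover planted block structure", {
  V <- make_blocks(n_per = 25, shift = 6, noise = 0.05, seed = 4)
  fit <- nmf(V, 2, seed = 9)
  truth <- rep(c(1, 2), each = 25)
  agree <- max(mean(fit$cluster == truth), mean(fit$cluster == 3 - truth))
  expect_equal(agree, 1)
})

test_that("consensus is binary and cophenetic is 1 when runs agree", {
  V <- make_blocks(n_per = 15, shift = 8, noise = 0.02, seed = 5)
  res <- consensus_cluster(V, k_range = 2:3, n_runs = 5, seed = 1)
  cons2 <- res$consensus[["2"]]
  expect_true(all(cons2 %in% c(0, 1)))
  expect_equal(unname(res$cophenetic[["2"]]), 1.0)
  expect_identical(res$selected_rank, 2L)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(res$cell_labels == truth),
               mean(res$cell_labels == 3 - truth))
  expect_equal(agree, 1)
  expect_error(consensus_cluster(V, n_runs = 1), "at least 2")
})

test_that("structureless noise never looks more stable than real structure", {
  set.seed(6)
  noise <- matrix(runif(60 * 11, 0.5, 1.5), 60, 11,
                  dimnames = list(paste0("c", 1:60), paste0("m", 1:11)))
  res_noise <- consensus_cluster(noise, k_range = 2:4, n_runs = 10, seed = 2)
  V <- make_blocks(n_per = 30, shift = 6, noise = 0.1, seed = 7)
  res_sig <- consensus_cluster(V, k_range = 2:4, n_runs = 10, seed = 2)
  expect_true(all(res_noise$cophenetic <= res_sig$cophenetic[["2"]]))
})

test_that("the published risk model carries the printed constants", {
  m <- published_risk_model()
  expect_identical(m$metabolite_names,
                   c("glutamic acid", "malic acid", "aspartic acid",
                     "lactic acid"))
  expect_identical(unname(m$coefficients), c(-0.932, 3.967, -0.166, -1.822))
  expect_identical(m$intercept, -3.694)
  expect_identical(m$threshold, 0.420)
  expect_identical(m$logit_base, 10)
})

test_that("risk scores evaluate the base-10 logit and are name-keyed", {
  m <- published_risk_model()
  zero <- c("glutamic acid" = 0, "malic acid" = 0, "aspartic acid" = 0,
            "lactic acid" = 0)
  expect_equal(risk_score(m, zero), 10^-3.694 / (1 + 10^-3.694),
               tolerance = 1e-12)
  # malic acid alone cancels the intercept: logit 0, score one half
  half <- zero
  half[["malic acid"]] <- 3.694 / 3.967
  expect_equal(risk_score(m, half), 0.5, tolerance = 1e-9)
  # order of named inputs is irrelevant
  expect_equal(risk_score(m, rev(half)), risk_score(m, half))
  set.seed(8)
  X <- matrix(rlnorm(40, 0, 1), 10, 4,
              dimnames = list(NULL, m$metabolite_names))
  s <- risk_score(m, X)
  expect_true(all(s > 0 & s < 1))
  expect_equal(risk_score(m, X[, c(3, 1, 4, 2)]), s)
  expect_error(risk_score(m, zero[1:3]), "missing metabolite")
})

test_that("Youden cutoffs equal exhaustive search and its hand cases", {
  expect_equal(youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.8)
  expect_equal(youden_cutoff(c(0.1, 0.5, 0.9), c(0, 1, 1)), 0.5)
  set.seed(9)
  for (i in 1:25) {
    sc <- round(runif(50), 2)
    lab <- rbinom(50, 1, 0.4)
    if (length(unique(lab)) < 2 || length(unique(sc)) < 2) next
    expect_equal(youden_cutoff(sc, lab), youden_bruteforce(sc, lab))
  }
  # invariance under a joint strictly increasing transform
  sc <- c(0.05, 0.2, 0.3, 0.55, 0.7, 0.9)
  lab <- c(0, 0, 1, 0, 1, 1)
  expect_equal(qlogis(youden_cutoff(sc, lab)),
               youden_cutoff(qlogis(sc), lab))
  expect_error(youden_cutoff(c(1, 1), c(0, 1)), "identical")
})

test_that("subgroup assignment is closed at the 0.420 boundary", {
  expect_identical(assign_subgroups(c(0.420, 0.419, 0.05, 0.99)),
                   c("C2", "C1", "C1", "C2"))
  expect_identical(assign_subgroups(c(0.1, 0.2)), c("C1", "C1"))
})

test_that("backward elimination recovers a planted fingerprint", {
  # at alpha = 0.05 each of the 7 null metabolites survives elimination
  # with probability ~ alpha, so the informative quartet is always kept
  # while exact recovery happens at roughly the 0.95^7 ~ 70% familywise rate
  set.seed(10)
  superset <- exact <- 0
  for (i in 1:10) {
    n <- 2000
    X <- matrix(rlnorm(n * 11, 0, 0.5), n, 11,
                dimnames = list(sprintf("c%04d", 1:n), ctc_panel()))
    Z <- scale(X)
    eta <- 1.2 * Z[, 1] - 1.0 * Z[, 2] + 0.8 * Z[, 3] - 0.6 * Z[, 4]
    y <- rbinom(n, 1, plogis(eta))
    scm <- single_cell_matrix(X, patient_id = rep("P1", n))
    got <- select_fingerprint(scm, y)
    if (all(ctc_fingerprint() %in% got)) superset <- superset + 1
    if (setequal(got, ctc_fingerprint())) exact <- exact + 1
  }
  expect_gte(superset, 9)
  expect_gte(exact, 5)
})

test_that("null labels usually eliminate every metabolite", {
  set.seed(12)
  empty <- 0
  for (i in 1:10) {
    n <- 400
    X <- matrix(rlnorm(n * 11, 0, 0.5), n, 11,
                dimnames = list(sprintf("c%04d", 1:n), ctc_panel()))
    y <- rbinom(n, 1, 0.5)
    got <- select_fingerprint(single_cell_matrix(X, rep("P1", n)), y)
    if (length(got) == 0) empty <- empty + 1
  }
  expect_gte(empty, 6)
})

test_that("a perfectly separating metabolite is ranked first", {
  n <- 100
  X <- matrix(rlnorm(n * 4, 0, 0.3), n, 4,
              dimnames = list(sprintf("c%03d", 1:n), ctc_fingerprint()))
  y <- rep(c(0, 1), each = n / 2)
  X[, "malic acid"] <- ifelse(y == 1, 5, 1) * X[, "malic acid"]
  got <- select_fingerprint(single_cell_matrix(X, rep("P1", n)), y)
  expect_identical(got[1], "malic acid")
})

test_that("fitted risk models point in the direction of separation", {
  set.seed(14)
  n <- 500
  X <- matrix(rlnorm(n * 4, 0, 0.4), n, 4,
              dimnames = list(sprintf("c%04d", 1:n), ctc_fingerprint()))
  eta <- 2 * (X[, "malic acid"] - 1)
  y <- rbinom(n, 1, plogis(eta))
  scm <- single_cell_matrix(X, rep("P1", n))
  fit <- fit_risk_model(scm, y, "malic acid")
  expect_gt(fit$coefficients[["malic acid"]], 0)
  expect_true(fit$threshold > 0 && fit$threshold < 1)
  # deterministic relabelling from its own scores leaves the boundary fixed
  scores <- risk_score(fit, X)
  relab <- as.integer(scores >= fit$threshold)
  refit <- fit_risk_model(scm, relab, "malic acid")
  rescored <- risk_score(refit, X)
  expect_gte(mean((rescored >= refit$threshold) == (relab == 1)), 0.99)
})

test_that("subtyping recovers planted subgroups end to end", {
  # at the default biological noise (RSD 60%) the chain
  # consensus -> fingerprint -> risk model recovers cell membership with
  # ~90% mean agreement; every seed must stay above 85%
  agree <- numeric(8)
  for (i in 1:8) {
    co <- generate_ctc_cohort(cohort_sim_config(n_patients = 60,
                                                seed = 500 + i))
    cons <- consensus_cluster(co$cells, seed = 600 + i)
    labels2 <- if (cons$selected_rank == 2L) cons$cell_labels
               else consensus_labels(cons, 2L)
    fp <- select_fingerprint(co$cells, labels2)
    if (length(fp) == 0) fp <- co$cells$metabolite_names
    fit <- fit_risk_model(co$cells, labels2, fp)
    got <- assign_subgroups(risk_score(fit, co$cells), fit$threshold)
    truth <- co$truth$cell_subgroup
    agree[i] <- max(mean(got == truth),
                    mean(got == ifelse(truth == "C1", "C2", "C1")))
  }
  expect_gte(mean(agree), 0.9)
  expect_true(all(agree >= 0.85))
})
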
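test_that("detection and S/N filtering follows the group-wise rule", {
  # 6 features x 10 samples (5 per group), hand-enumerated outcomes:
  # f1 fully observed, strong signal            -> kept
  # f2 60% detection in both groups             -> removed (below 80% in all)
  # f3 60% in group1 but 100% in group2         -> kept (one group reaches 80%)
  # f4 fully observed but max intensity < 3*SN  -> removed
  # f5 80% in group1 exactly                    -> kept (>= 0.8 boundary)
  # f6 fully observed, moderate signal          -> kept
  v <- matrix(100, 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  grp <- rep(c("g1", "g2"), each = 5)
  v[2, c(1, 2, 6, 7)] <- NA
  v[3, c(1, 2)] <- NA
  v[4, ] <- 5
  v[5, 1] <- NA
  fm <- make_fm(v, grp)
  noise <- setNames(rep(2, 6), paste0("f", 1:6))
  kept <- filter_features(fm, blank_profile = noise)
  expect_identical(kept$feature_ids, c("f1", "f3", "f5", "f6"))

  # filtering its own output is a no-op
  expect_identical(filter_features(kept, blank_profile = noise)$intensities,
                   kept$intensities)
  expect_error(filter_features(fm, min_detect_frac = 0), "0, 1")
})

test_that("missing values are imputed at one tenth of the feature minimum", {
  v <- matrix(c(10, 20, NA,
                0.5, NA, NA,
                1, 2, 3), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:3)))
  fm <- make_fm(v, rep("g1", 3))
  imp <- impute_missing(fm)
  expect_equal(unname(imp$intensities["a", 3]), 1.0)
  expect_equal(unname(imp$intensities["b", 2:3]), c(0.05, 0.05))
  expect_equal(imp$intensities["c", ], fm$intensities["c", ])
  # idempotent: no NA left, so re-imputation changes nothing
  expect_identical(impute_missing(imp), imp)

  v["c", ] <- NA
  expect_error(impute_missing(make_fm(v, rep("g1", 3))), "no observed value")
})

test_that("normalization divides by protein, IS, and per-batch QC medians", {
  v <- matrix(c(4, 4, 4, 4,
                8, 8, 8, 8,
                1, 1, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("f1", "f2", "IS"), paste0("s", 1:4)))
  fm <- make_fm(v, c("g1", "g2", "g1", "QC"),
                is_qc = c(FALSE, FALSE, FALSE, TRUE), is_id = "IS")
  out <- normalize_bulk(fm)
  expect_identical(out$feature_ids, c("f1", "f2"))
  expect_equal(unname(out$intensities), matrix(1, 2, 4))

  # doubling one sample's protein amount halves its intensities
  fm2 <- make_fm(v, c("g1", "g2", "g1", "QC"),
                 is_qc = c(FALSE, FALSE, FALSE, TRUE),
                 protein = c(2, 1, 1, 1), is_id = "IS")
  out2 <- normalize_bulk(fm2)
  expect_equal(out2$intensities[, 1] / out$intensities[, 1], c(f1 = 0.5, f2 = 0.5))

  expect_error(normalize_bulk(make_fm(v, c("g1", "g2", "g1", "g2"),
                                      is_id = "IS")), "no QC sample")
})

test_that("internal-standard drift cancels exactly under normalization", {
  set.seed(5)
  p <- 20; n <- 12
  clean <- matrix(rlnorm(p * n, 8, 0.4), p, n,
                  dimnames = list(paste0("f", 1:p), paste0("s", 1:n)))
  build <- function(drift) {
    vals <- rbind(sweep(clean, 2, drift, `*`), IS = 1e5 * drift)
    qc <- rowMeans(vals)
    vals <- cbind(vals, QC1 = qc)
    make_fm(vals, c(rep(c("g1", "g2"), each = n / 2), "QC"),
            is_qc = c(rep(FALSE, n), TRUE), is_id = "IS")
  }
  no_drift <- normalize_bulk(build(rep(1, n)))
  with_drift <- normalize_bulk(build(rep(c(1, 2), each = n / 2)))
  cv <- function(fm) apply(fm$intensities[, !fm$is_qc], 1, function(x) sd(x) / mean(x))
  expect_equal(cv(with_drift), cv(no_drift), tolerance = 1e-9)
})

test_that("OPLS-DA satisfies the VIP identity and finds a lone predictor", {
  set.seed(11)
  n <- 60
  grp <- rep(c("g1", "g2"), each = n / 2)
  x1 <- ifelse(grp == "g2", 4, 1) + rnorm(n, 0, 0.05)
  noise <- matrix(rnorm(3 * n), n)
  v <- t(cbind(x1, noise))
  rownames(v) <- paste0("f", 1:4)
  colnames(v) <- paste0("s", 1:n)
  fm <- make_fm(abs(v) + 5, grp)
  fm$intensities[1, ] <- x1 + 5
  op <- opls_da(fm)
  expect_equal(sum(op$vip^2), 4, tolerance = 1e-8)
  expect_gt(op$vip[["f1"]], 1.95)
  expect_true(all(op$vip[c("f2", "f3", "f4")] < 0.5))
  expect_gt(op$q2_cum, 0.9)
  expect_true(op$q2_cum <= op$r2y_cum)
})

test_that("OPLS-DA cross-validation collapses under permuted labels", {
  set.seed(13)
  s <- generate_bulk_screen(screen_sim_config(n_features = 40,
                                              missing_rate = 0, seed = 17))
  fm <- normalize_bulk(impute_missing(filter_features(s$pair_a)))
  bio <- !fm$is_qc
  q2 <- replicate(20, {
    perm <- sample(fm$group[bio])
    opls_da(fm, group_labels = perm)$q2_cum
  })
  expect_lte(mean(q2), 0.1)
})

test_that("differential selection applies the three-way strict rule", {
  # f1: exact 2x ratio (log2FC = 1, at the boundary), f2: 4x, f3: null
  prim <- c(1, 2, 3, 2, 1.5)
  v <- rbind(f1 = c(2 * prim, prim),
             f2 = c(4 * prim, prim),
             f3 = c(prim, prim) * exp(c(0.01, -0.01, 0.02, -0.02, 0,
                                        0.01, -0.01, 0.02, -0.02, 0)))
  colnames(v) <- paste0("s", 1:10)
  grp <- rep(c("metastatic", "primary"), each = 5)
  fm <- make_fm(v, grp)
  tab <- differential_table(fm, opls_da(fm))
  expect_equal(tab$log2_fold_change[tab$feature_id == "f1"], 1)
  expect_equal(tab$log2_fold_change[tab$feature_id == "f2"], 2)
  expect_lt(tab$p_value[tab$feature_id == "f1"], 0.05)
  # log2FC exactly 1 fails the strict > 1 requirement
  expect_false(tab$selected[tab$feature_id == "f1"])
  expect_true(tab$selected[tab$feature_id == "f2"])
  expect_false(tab$selected[tab$feature_id == "f3"])

  # identical groups: all fold changes zero, nothing selected
  fm0 <- make_fm(rbind(f1 = rep(prim, 2), f2 = rep(2 * prim, 2)), grp)
  tab0 <- differential_table(fm0, opls_da(fm0))
  expect_equal(tab0$log2_fold_change, c(0, 0))
  expect_false(any(tab0$selected))
})

test_that("panel intersection is a sorted set intersection", {
  mk <- function(ids, sel) data.frame(feature_id = ids, selected = sel)
  a <- mk(c("m1", "m2", "m3", "m4"), c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c("m1", "m2", "m3", "m4"), c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(shared_panel(a, b), c("m2", "m3"))
  expect_identical(shared_panel(a, a), c("m1", "m2", "m3"))
  disj <- mk(c("m1", "m2", "m3", "m4"), c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(shared_panel(a, disj), character(0))
})

test_that("z-score transform standardizes each feature", {
  v <- rbind(f1 = c(1, 2, 3), f2 = c(10, 30, 20))
  colnames(v) <- paste0("s", 1:3)
  z <- zscore_transform(make_fm(v, rep("g", 3)))
  expect_equal(unname(z["f1", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
  # shift invariance and idempotence
  expect_equal(zscore_transform(v + 100), z)
  expect_equal(zscore_transform(z), z)
  expect_error(zscore_transform(rbind(f1 = c(1, 1, 1))), "zero-variance")
})

test_that("planted differential features are recovered across seeds", {
  recall <- fsr <- numeric(20)
  for (i in 1:20) {
    s <- generate_bulk_screen(screen_sim_config(
      n_features = 100, frac_differential = 0.1, log2fc_effect = 2,
      noise_cv = 0.2, missing_rate = 0, seed = 1000 + i))
    fm <- normalize_bulk(impute_missing(filter_features(s$pair_a)))
    tab <- differential_table(fm, opls_da(fm))
    sel <- tab$feature_id[tab$selected]
    truth <- s$truth$differential_feature_ids
    recall[i] <- mean(truth %in% sel)
    fsr[i] <- if (length(sel) > 0) mean(!sel %in% truth) else 0
  }
  expect_gte(mean(recall), 0.9)
  expect_lte(mean(fsr), 0.1)
})
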
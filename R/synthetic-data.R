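#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# log-normal parameterized by its arithmetic mean m and coefficient of
# variation cv, so that E[X] = m exactly and sd(X)/E[X] = cv.
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Default 11-metabolite CTC panel
#'
#' The panel monitored in single CTCs: the four fingerprint metabolites
#' (glutamic acid, malic acid, aspartic acid, lactic acid — amino acid
#' metabolism, glutathione metabolism and the Warburg effect) plus seven
#' further pathway members. Names beyond the four fingerprint metabolites
#' are representative pathway members, not a published enumeration.
#'
#' @return Character vector of 11 metabolite names.
#' @export
ctc_panel <- function() {
  c("glutamic acid", "malic acid", "aspartic acid", "lactic acid",
    "glutathione", "glucose", "glycine", "cysteine",
    "pyruvic acid", "fumaric acid", "citric acid")
}

#' Fingerprint subset of the CTC panel
#' @return Character vector of the 4 fingerprint metabolite names.
#' @export
ctc_fingerprint <- function() {
  c("glutamic acid", "malic acid", "aspartic acid", "lactic acid")
}

# baseline (subgroup C1) centroids in mM, single-CTC scale
default_centroids <- function(panel) {
  base <- c("glutamic acid" = 0.40, "malic acid" = 0.50,
            "aspartic acid" = 0.50, "lactic acid" = 0.60,
            "glutathione" = 1.00, "glucose" = 2.00, "glycine" = 0.80,
            "cysteine" = 0.30, "pyruvic acid" = 0.50,
            "fumaric acid" = 0.20, "citric acid" = 0.40)
  out <- base[panel]
  out[is.na(out)] <- 0.5
  names(out) <- panel
  out
}

#' Configuration for a synthetic bulk screening experiment
#'
#' Describes one two-cell-line-pair untargeted screen: a primary and a
#' metastatic line measured with `n_replicates_per_line` independent
#' replicates each, with a fraction of features planted as differential at a
#' fixed log2 fold change, multiplicative log-normal noise, missing values
#' completely at random, and per-batch log-space intensity shifts.
#'
#' @param n_features Number of metabolic features (> 0).
#' @param n_replicates_per_line Replicates per cell line (> 0; 9 by
#'   default, matching a 9-replicate screen design).
#' @param frac_differential Fraction of features planted as differential.
#' @param log2fc_effect Planted |log2 fold change| (metastatic over
#'   primary; planted features are elevated in the metastatic line).
#' @param noise_cv Multiplicative biological/technical noise as a
#'   coefficient of variation.
#' @param missing_rate Missing-completely-at-random rate in `[0, 1)`.
#' @param n_batches Number of measurement batches.
#' @param batch_shift_sd Log-space standard deviation of per-batch,
#'   per-feature location shifts.
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_features = 500,
                              n_replicates_per_line = 9,
                              frac_differential = 0.1,
                              log2fc_effect = 2,
                              noise_cv = 0.2,
                              missing_rate = 0.05,
                              n_batches = 3,
                              batch_shift_sd = 0.2,
                              seed = 1) {
  stopifnot(n_features >= 1, n_replicates_per_line >= 1,
            frac_differential >= 0, frac_differential <= 1,
            log2fc_effect > 0, noise_cv >= 0,
            missing_rate >= 0, missing_rate < 1,
            n_batches >= 1, batch_shift_sd >= 0)
  if (frac_differential > 0 && round(frac_differential * n_features) < 1) {
    stop("frac_differential * n_features must round to at least 1")
  }
  structure(as.list(environment()), class = "screen_sim_config")
}

#' Simulate two cell-line-pair screening matrices
#'
#' Generates two [feature_matrix()] objects sharing one feature namespace —
#' one per cell-line pair (e.g. primary/metastatic pair A and pair B) —
#' with a common set of planted differential features elevated by
#' `2^log2fc_effect` in the metastatic line of both pairs. Each matrix
#' carries an always-observed internal-standard feature, per-sample protein
#' amounts, per-batch QC samples defined as the batch's feature-wise mean
#' profile, and MCAR missingness.
#'
#' @param config A [screen_sim_config()].
#' @return List with `pair_a`, `pair_b` (feature matrices) and `truth`
#'   (list with `differential_feature_ids`).
#' @export
generate_bulk_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    p <- config$n_features
    feature_ids <- sprintf("F%04d", seq_len(p))
    n_diff <- round(config$frac_differential * p)
    diff_ids <- if (n_diff > 0) sample(feature_ids, n_diff) else character(0)
    base_mu <- 10^stats::runif(p, 4, 6)
    names(base_mu) <- feature_ids
    fc <- rep(1, p)
    names(fc) <- feature_ids
    fc[diff_ids] <- 2^config$log2fc_effect

    make_pair <- function(pair_name) {
      n_rep <- config$n_replicates_per_line
      n_bio <- 2L * n_rep
      group <- rep(c("primary", "metastatic"), each = n_rep)
      batch <- rep_len(paste0("B", seq_len(config$n_batches)), n_bio)
      mu <- base_mu %o% rep(1, n_bio)   # p x n expected intensities
      mu[, group == "metastatic"] <- mu[, group == "metastatic"] * fc
      vals <- matrix(rlnorm_cv(length(mu), 1, config$noise_cv),
                     nrow = p) * mu
      # per-batch, per-feature multiplicative (log-location) shift
      if (config$batch_shift_sd > 0) {
        for (b in unique(batch)) {
          shift <- exp(stats::rnorm(p, 0, config$batch_shift_sd))
          vals[, batch == b] <- vals[, batch == b] * shift
        }
      }
      # internal-standard feature: constant spike-in with technical noise
      is_row <- 1e6 * rlnorm_cv(n_bio, 1, config$noise_cv / 4)
      # MCAR missingness on biological features only
      if (config$missing_rate > 0) {
        drop <- matrix(stats::runif(length(vals)) < config$missing_rate,
                       nrow = p)
        vals[drop] <- NA_real_
      }
      # per-batch QC sample = feature-wise mean of the batch's samples
      qc_vals <- sapply(unique(batch), function(b) {
        rowMeans(vals[, batch == b, drop = FALSE], na.rm = TRUE)
      })
      qc_vals[!is.finite(qc_vals)] <- NA_real_
      qc_is <- sapply(unique(batch), function(b) mean(is_row[batch == b]))

      all_vals <- rbind(cbind(vals, qc_vals),
                        c(is_row, qc_is))
      rownames(all_vals) <- c(feature_ids, "IS_acetaminophen")
      n_qc <- length(unique(batch))
      sample_ids <- c(paste0(pair_name, "_", group, "_", seq_len(n_bio)),
                      paste0(pair_name, "_QC_", seq_len(n_qc)))
      colnames(all_vals) <- sample_ids
      protein <- if (config$noise_cv > 0) {
        100 * rlnorm_cv(n_bio + n_qc, 1, 0.1)
      } else rep(100, n_bio + n_qc)
      feature_matrix(
        intensities = all_vals,
        group = c(group, rep("QC", n_qc)),
        batch = c(batch, unique(batch)),
        is_qc = c(rep(FALSE, n_bio), rep(TRUE, n_qc)),
        protein_ug = protein,
        is_feature_id = "IS_acetaminophen"
      )
    }
    list(pair_a = make_pair("A"),
         pair_b = make_pair("B"),
         truth = list(differential_feature_ids = sort(diff_ids)))
  })
}

#' Configuration for a synthetic CTC cohort
#'
#' Emulates a CTC-positive patient cohort: per-patient CTC counts drawn
#' from a categorical distribution over 1–6 cells per blood draw
#' (default 1: 3.3%, 2: 6.7%, 3: 30.0%, >=4: 60.0%), each cell assigned to
#' one of two latent metabolic subgroups, C2 cells shifted multiplicatively
#' on the informative metabolites, multiplicative log-normal biological
#' noise (default RSD 60%), per-batch log-location shifts, and a metastasis
#' outcome drawn from a logistic model of the patient's C2 cell count.
#'
#' @param n_patients Number of CTC-positive patients.
#' @param ctc_count_distribution Named probability vector over counts 1..6;
#'   must sum to 1.
#' @param panel Metabolite panel (default [ctc_panel()]).
#' @param informative Informative sublist of the panel (default
#'   [ctc_fingerprint()]).
#' @param c2_centroid_shift Multiplicative centroid factor applied to C2
#'   cells; a scalar (applied to the informative metabolites) or a named
#'   per-metabolite vector.
#' @param c2_prevalence Probability that a cell belongs to subgroup C2.
#' @param biological_rsd Within-subgroup coefficient of variation.
#' @param intra_patient_rsd_max Upper plausibility bound on intra-patient
#'   RSD; `biological_rsd` must not exceed it.
#' @param outcome_model Length-2 numeric `c(intercept, slope)` on the
#'   natural logit scale linking C2 count to metastasis probability.
#' @param n_batches Number of measurement batches (cells assigned
#'   round-robin by patient).
#' @param batch_shift_sd Log-space sd of per-batch, per-metabolite shifts.
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 60,
                              ctc_count_distribution = c(
                                "1" = 0.033, "2" = 0.067, "3" = 0.300,
                                "4" = 0.350, "5" = 0.150, "6" = 0.100),
                              panel = ctc_panel(),
                              informative = ctc_fingerprint(),
                              c2_centroid_shift = 4,
                              c2_prevalence = 0.4,
                              biological_rsd = 0.60,
                              intra_patient_rsd_max = 1.243,
                              outcome_model = c(intercept = -2.2,
                                                slope = 1.1),
                              n_batches = 3,
                              batch_shift_sd = 0.1,
                              seed = 1) {
  stopifnot(n_patients >= 1, length(panel) >= 1,
            biological_rsd >= 0, intra_patient_rsd_max > 0,
            length(outcome_model) == 2, n_batches >= 1,
            batch_shift_sd >= 0,
            c2_prevalence > 0, c2_prevalence < 1)
  if (abs(sum(ctc_count_distribution) - 1) > 1e-8) {
    stop("ctc_count_distribution probabilities must sum to 1")
  }
  if (any(ctc_count_distribution < 0)) {
    stop("ctc_count_distribution probabilities must be non-negative")
  }
  if (!all(informative %in% panel)) {
    stop("informative metabolites must be a subset of the panel")
  }
  if (biological_rsd > intra_patient_rsd_max) {
    stop("biological_rsd exceeds intra_patient_rsd_max")
  }
  if (length(c2_centroid_shift) == 1L && is.null(names(c2_centroid_shift))) {
    shift <- rep(1, length(panel))
    names(shift) <- panel
    shift[informative] <- c2_centroid_shift
    c2_centroid_shift <- shift
  } else {
    if (!all(panel %in% names(c2_centroid_shift))) {
      stop("named c2_centroid_shift must cover the whole panel")
    }
    c2_centroid_shift <- c2_centroid_shift[panel]
  }
  if (any(c2_centroid_shift <= 0)) stop("centroid shifts must be positive")
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a single-CTC cohort with latent metabolic subgroups
#'
#' @param config A [cohort_sim_config()].
#' @return List with `cells` (a [single_cell_matrix()]), `patients` (a
#'   patient table data.frame: patient_id, total_ctc_count, c1_count,
#'   c2_count, outcome), and `truth` (cell subgroup labels and per-patient
#'   outcome probabilities).
#' @export
generate_ctc_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    counts <- sample(as.integer(names(config$ctc_count_distribution)),
                     config$n_patients, replace = TRUE,
                     prob = config$ctc_count_distribution)
    patient_id <- sprintf("P%03d", seq_len(config$n_patients))
    cell_patient <- rep(patient_id, counts)
    n_cells <- length(cell_patient)
    cell_ids <- sprintf("C%04d", seq_len(n_cells))
    subgroup <- ifelse(stats::runif(n_cells) < config$c2_prevalence,
                       "C2", "C1")

    centroids <- default_centroids(config$panel)
    p <- length(config$panel)
    conc <- matrix(0, n_cells, p,
                   dimnames = list(cell_ids, config$panel))
    for (j in seq_len(p)) {
      mu <- ifelse(subgroup == "C2",
                   centroids[j] * config$c2_centroid_shift[j], centroids[j])
      conc[, j] <- rlnorm_cv(n_cells, 1, config$biological_rsd) * mu
    }
    batch <- paste0("B", (match(cell_patient, patient_id) - 1L) %%
                      config$n_batches + 1L)
    if (config$batch_shift_sd > 0 && config$n_batches > 1L) {
      for (b in unique(batch)) {
        shift <- exp(stats::rnorm(p, 0, config$batch_shift_sd))
        conc[batch == b, ] <- sweep(conc[batch == b, , drop = FALSE],
                                    2, shift, `*`)
      }
    }
    c2_count <- as.integer(tapply(subgroup == "C2", cell_patient, sum)[patient_id])
    c1_count <- counts - c2_count
    eta <- config$outcome_model[[1]] + config$outcome_model[[2]] * c2_count
    p_out <- stats::plogis(eta)
    outcome <- as.integer(stats::runif(config$n_patients) < p_out)

    cells <- single_cell_matrix(conc, patient_id = cell_patient,
                                batch = batch)
    patients <- data.frame(patient_id = patient_id,
                           total_ctc_count = counts,
                           c1_count = c1_count,
                           c2_count = c2_count,
                           outcome = outcome,
                           stringsAsFactors = FALSE)
    list(cells = cells, patients = patients,
         truth = list(cell_subgroup = stats::setNames(subgroup, cell_ids),
                      patient_outcome_probability =
                        stats::setNames(p_out, patient_id)))
  })
}

#' Simulate a calibration point table
#'
#' Responses follow `slope * concentration + intercept` plus Gaussian noise,
#' replicated at each level.
#'
#' @param true_slope,true_intercept Generating line.
#' @param levels Calibration concentrations (at least 2 distinct).
#' @param noise_sd Gaussian response noise (>= 0).
#' @param n_replicates Replicates per level.
#' @param seed Integer seed.
#' @return data.frame with columns concentration, response, replicate.
#' @export
generate_calibration <- function(true_slope, true_intercept, levels,
                                 noise_sd = 0, n_replicates = 3, seed = 1) {
  if (length(unique(levels)) < 2) {
    stop("at least two distinct calibration levels are required")
  }
  stopifnot(noise_sd >= 0, n_replicates >= 1)
  with_seed(seed, {
    conc <- rep(levels, each = n_replicates)
    resp <- true_slope * conc + true_intercept +
      stats::rnorm(length(conc), 0, noise_sd)
    data.frame(concentration = conc, response = resp,
               replicate = rep(seq_len(n_replicates), times = length(levels)))
  })
}

#' Simulate cells from a logistic risk model
#'
#' Draws per-cell metabolite concentrations from independent log-normal
#' distributions and samples a binary subgroup label from the Bernoulli
#' probability given by the model's risk score. Default dispersions are set
#' by a design power analysis so every coefficient is identifiable at a few
#' thousand cells: the metabolite with the smallest coefficient magnitude
#' (aspartic acid) gets the widest dispersion (RSD 125%, the upper range of
#' intrapatient variability), and the mean vector centres the linear
#' predictor near zero.
#'
#' @param model A [risk_model()]; scores are on its base-10 logit scale.
#' @param n Number of cells.
#' @param conc_mean,conc_sd Named vectors (over `model$metabolite_names`)
#'   of arithmetic means and sds of the log-normal concentrations (mM).
#' @param seed Integer seed.
#' @return List with `concentrations` (n x length(fingerprint) matrix) and
#'   `labels` (0/1 integer vector; 1 = high risk).
#' @export
simulate_from_risk_model <- function(model, n,
                                     conc_mean = NULL, conc_sd = NULL,
                                     seed = 1) {
  stopifnot(inherits(model, "risk_model"), n >= 1)
  mets <- model$metabolite_names
  if (is.null(conc_mean)) {
    conc_mean <- c("glutamic acid" = 0.40, "malic acid" = 1.2361,
                   "aspartic acid" = 1.20, "lactic acid" = 0.35)[mets]
    if (anyNA(conc_mean)) conc_mean[is.na(conc_mean)] <- 1
    names(conc_mean) <- mets
  }
  if (is.null(conc_sd)) {
    conc_sd <- c("glutamic acid" = 0.30, "malic acid" = 0.12,
                 "aspartic acid" = 1.50, "lactic acid" = 0.20)[mets]
    if (anyNA(conc_sd)) conc_sd[is.na(conc_sd)] <- 0.5
    names(conc_sd) <- mets
  }
  with_seed(seed, {
    conc <- sapply(mets, function(m) {
      rlnorm_cv(n, conc_mean[[m]], conc_sd[[m]] / conc_mean[[m]])
    })
    conc <- matrix(conc, nrow = n,
                   dimnames = list(sprintf("C%05d", seq_len(n)), mets))
    scores <- risk_score(model, conc)
    labels <- as.integer(stats::runif(n) < scores)
    list(concentrations = conc, labels = labels)
  })
}
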
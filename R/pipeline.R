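# delimiter from file extension: .tsv/.tab -> tab, otherwise comma
delim_for <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "", quote = "\"", comment.char = "")
}

write_table_auto <- function(df, path) {
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
}

check_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicated ", what, ": ", paste(unique(dup), collapse = ", "))
  }
}

numeric_block <- function(df, id_col, path) {
  block <- df[, setdiff(names(df), id_col), drop = FALSE]
  for (cn in names(block)) {
    v <- block[[cn]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0) {
        stop("non-numeric value in column '", cn, "', row ", bad[1],
             " of ", path)
      }
      block[[cn]] <- parsed
    }
  }
  m <- as.matrix(block)
  rownames(m) <- df[[id_col]]
  m
}

#' Read / write a single-cell matrix
#'
#' The values file holds one row per cell (first column `cell_id`, one
#' numeric column per metabolite); the annotation file holds `cell_id`,
#' `patient_id` and optionally `batch`. The delimiter is inferred from the
#' extension (`.tsv`/`.tab` = tab, otherwise comma); a written matrix reads
#' back with full precision and unchanged ordering.
#'
#' @param values_path,annotations_path File paths.
#' @return A [single_cell_matrix()].
#' @export
read_single_cell_matrix <- function(values_path, annotations_path) {
  vals <- read_table_auto(values_path)
  if (names(vals)[1] != "cell_id") stop("first column must be 'cell_id'")
  check_ids(vals$cell_id, "cell_id")
  m <- numeric_block(vals, "cell_id", values_path)
  ann <- read_table_auto(annotations_path)
  if (!all(c("cell_id", "patient_id") %in% names(ann))) {
    stop("annotations need 'cell_id' and 'patient_id' columns")
  }
  check_ids(ann$cell_id, "cell_id")
  idx <- match(rownames(m), ann$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from annotations: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  }
  batch <- if ("batch" %in% names(ann)) ann$batch[idx] else rep("B1", nrow(m))
  single_cell_matrix(m, patient_id = ann$patient_id[idx], batch = batch)
}

#' @rdname read_single_cell_matrix
#' @param x A [single_cell_matrix()].
#' @export
write_single_cell_matrix <- function(x, values_path, annotations_path) {
  stopifnot(inherits(x, "single_cell_matrix"))
  vals <- data.frame(cell_id = x$cell_ids,
                     x$concentrations, check.names = FALSE)
  write_table_auto(format_numeric_df(vals), values_path)
  ann <- data.frame(cell_id = x$cell_ids, patient_id = x$patient_id,
                    batch = x$batch)
  write_table_auto(ann, annotations_path)
  invisible(c(values_path, annotations_path))
}

# serialize numerics at full double precision
format_numeric_df <- function(df) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) {
      df[[cn]] <- vapply(df[[cn]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17)
      }, character(1))
    }
  }
  df
}

#' Read / write a bulk feature matrix
#'
#' The intensities file holds one row per feature (first column
#' `feature_id`); the sample annotation file holds `sample_id`, `group`,
#' `batch`, `is_qc`, `protein_ug`. Empty fields encode missing peaks.
#'
#' @param intensities_path,annotations_path File paths.
#' @param is_feature_id Internal-standard feature id (or `NA`).
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(intensities_path, annotations_path,
                                is_feature_id = NA_character_) {
  vals <- read_table_auto(intensities_path)
  if (names(vals)[1] != "feature_id") stop("first column must be 'feature_id'")
  check_ids(vals$feature_id, "feature_id")
  m <- numeric_block(vals, "feature_id", intensities_path)
  ann <- read_table_auto(annotations_path)
  need <- c("sample_id", "group", "batch", "is_qc", "protein_ug")
  if (!all(need %in% names(ann))) {
    stop("sample annotations need columns: ", paste(need, collapse = ", "))
  }
  check_ids(ann$sample_id, "sample_id")
  idx <- match(colnames(m), ann$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from annotations: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  }
  feature_matrix(m, group = ann$group[idx], batch = ann$batch[idx],
                 is_qc = as.logical(ann$is_qc[idx]),
                 protein_ug = ann$protein_ug[idx],
                 is_feature_id = is_feature_id)
}

#' @rdname read_feature_matrix
#' @param fm A [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, intensities_path, annotations_path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- data.frame(feature_id = fm$feature_ids,
                     fm$intensities, check.names = FALSE)
  write_table_auto(format_numeric_df(vals), intensities_path)
  ann <- data.frame(sample_id = fm$sample_ids, group = fm$group,
                    batch = fm$batch, is_qc = fm$is_qc,
                    protein_ug = fm$protein_ug)
  write_table_auto(ann, annotations_path)
  invisible(c(intensities_path, annotations_path))
}

#' Serialize a risk model to / from JSON
#'
#' @param model A [risk_model()].
#' @param path JSON file path.
#' @return `read_risk_model` returns a [risk_model()].
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(metabolite_names = model$metabolite_names,
         coefficients = unname(model$coefficients),
         intercept = model$intercept,
         threshold = model$threshold,
         logit_base = model$logit_base),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.numeric(j$logit_base), 10)) {
    stop("risk model JSON must declare logit_base = 10")
  }
  risk_model(j$metabolite_names, j$coefficients, j$intercept, j$threshold)
}

#' Pipeline configuration
#'
#' Central configuration for [run_pipeline()]. Defaults reproduce the
#' published constants: selection rule |log2FC| > 1, p < 0.05, VIP > 1;
#' risk-score threshold 0.420; count cutoffs 3 (total), 1 (C1), 1 (C2).
#' Unknown keys are rejected.
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @param stages Stages to run, subset of
#'   `c("simulate", "screen", "subtype", "classify")`.
#' @param use_published_model Use the fixed published classifier instead of
#'   refitting on consensus clusters.
#' @param risk_threshold Score threshold in (0, 1).
#' @param count_cutoffs Named integer vector `c(total=, c1=, c2=)`.
#' @param log2fc_min,p_max,vip_min Differential selection thresholds.
#' @param consensus_k_range,consensus_runs Consensus clustering controls.
#' @param cohort A [cohort_sim_config()] (its seed is overridden by
#'   `seed`).
#' @param screen_sim A [screen_sim_config()] (its seed is overridden).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param ... Unknown keys: rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("simulate", "screen", "subtype",
                                       "classify"),
                            use_published_model = FALSE,
                            risk_threshold = 0.420,
                            count_cutoffs = c(total = 3L, c1 = 1L, c2 = 1L),
                            log2fc_min = 1, p_max = 0.05, vip_min = 1,
                            consensus_k_range = 2:6, consensus_runs = 30,
                            cohort = cohort_sim_config(),
                            screen_sim = screen_sim_config(),
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(all(stages %in% c("simulate", "screen", "subtype", "classify")))
  if (!is.numeric(risk_threshold) || risk_threshold <= 0 ||
      risk_threshold >= 1) {
    stop("risk_threshold must lie strictly inside (0, 1)")
  }
  if (!all(c("total", "c1", "c2") %in% names(count_cutoffs)) ||
      any(count_cutoffs < 0)) {
    stop("count_cutoffs must be a non-negative vector with names total, c1, c2")
  }
  stopifnot(inherits(cohort, "cohort_sim_config"),
            inherits(screen_sim, "screen_sim_config"))
  structure(list(seed = as.integer(seed), stages = stages,
                 use_published_model = use_published_model,
                 risk_threshold = risk_threshold,
                 count_cutoffs = count_cutoffs,
                 log2fc_min = log2fc_min, p_max = p_max, vip_min = vip_min,
                 consensus_k_range = consensus_k_range,
                 consensus_runs = consensus_runs,
                 cohort = cohort, screen_sim = screen_sim,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the optional
#' `cohort` and `screen_sim` maps are passed to [cohort_sim_config()] and
#' [screen_sim_config()]. Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_sim_config, y$cohort)
  if (!is.null(y$screen_sim)) {
    y$screen_sim <- do.call(screen_sim_config, y$screen_sim)
  }
  if (!is.null(y$count_cutoffs)) y$count_cutoffs <- unlist(y$count_cutoffs)
  do.call(pipeline_config, y)
}

derive_seed <- function(root, offset) (root * 1009L + offset * 9973L) %% 2147483647L

#' Run the CTC metabolic-typing pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic bulk screen
#' and CTC cohort), screen (filter, impute, normalize, OPLS-DA,
#' differential selection, panel intersection), subtype (consensus NMF +
#' risk model, or the published model), classify (patient counts, ROC/AUC,
#' count-cutoff metrics) — and returns a report bundle. When
#' `config$out_dir` is set, tables, the risk-model JSON, metrics JSON and a
#' run log are written there.
#'
#' @param config A [pipeline_config()].
#' @param cells,patients Optional user-supplied [single_cell_matrix()] and
#'   patient table (required when "simulate" is not among the stages and
#'   "subtype"/"classify" are).
#' @return A list (invisible) with the stage outputs.
#' @export
run_pipeline <- function(config, cells = NULL, patients = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config, seed = config$seed)
  log_lines <- c(sprintf("[%s] run_pipeline seed=%d",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                         config$seed))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  if ("simulate" %in% config$stages) {
    sc <- config$screen_sim; sc$seed <- derive_seed(config$seed, 1L)
    out$screen_data <- generate_bulk_screen(sc)
    cc <- config$cohort; cc$seed <- derive_seed(config$seed, 2L)
    sim <- generate_ctc_cohort(cc)
    cells <- sim$cells
    patients <- sim$patients
    out$cohort_truth <- sim$truth
    say("simulate: %d cells / %d patients, %d screen features",
        nrow(cells$concentrations), nrow(patients),
        config$screen_sim$n_features)
  }

  if ("screen" %in% config$stages) {
    if (is.null(out$screen_data)) stop("screen stage needs simulated or supplied screen data")
    run_screen <- function(fm) {
      fm |> filter_features() |> impute_missing() |> normalize_bulk()
    }
    fa <- run_screen(out$screen_data$pair_a)
    fb <- run_screen(out$screen_data$pair_b)
    ta <- differential_table(fa, opls_da(fa), log2fc_min = config$log2fc_min,
                             p_max = config$p_max, vip_min = config$vip_min)
    tb <- differential_table(fb, opls_da(fb), log2fc_min = config$log2fc_min,
                             p_max = config$p_max, vip_min = config$vip_min)
    out$differential <- list(pair_a = ta, pair_b = tb)
    out$shared_panel <- shared_panel(ta, tb)
    say("screen: %d + %d selected, %d shared",
        sum(ta$selected), sum(tb$selected), length(out$shared_panel))
  }

  if ("subtype" %in% config$stages) {
    if (is.null(cells)) stop("subtype stage needs cells (simulate first or supply them)")
    if (config$use_published_model) {
      out$risk_model <- published_risk_model()
      out$risk_model$threshold <- config$risk_threshold
    } else {
      cons <- consensus_cluster(cells, k_range = config$consensus_k_range,
                                n_runs = config$consensus_runs,
                                seed = derive_seed(config$seed, 3L))
      out$consensus <- cons
      # risk-score subgrouping is binary; use the 2-group consensus cut
      labels2 <- if (cons$selected_rank == 2L) cons$cell_labels
                 else consensus_labels(cons, 2L)
      out$cluster_labels <- labels2
      fp <- select_fingerprint(cells, labels2)
      if (length(fp) == 0) fp <- cells$metabolite_names
      out$fingerprint <- fp
      # orient the high-risk class with training outcomes when available
      cell_outcomes <- if (!is.null(patients)) {
        patients$outcome[match(cells$patient_id, patients$patient_id)]
      }
      out$risk_model <- fit_risk_model(cells, labels2,
                                       fp, outcomes = cell_outcomes)
    }
    out$scores <- risk_score(out$risk_model, cells)
    out$cell_subgroups <- assign_subgroups(out$scores,
                                           out$risk_model$threshold)
    say("subtype: %d C1 / %d C2 cells (threshold %.3f)",
        sum(out$cell_subgroups == "C1"), sum(out$cell_subgroups == "C2"),
        out$risk_model$threshold)
  }

  if ("classify" %in% config$stages) {
    if (is.null(out$cell_subgroups) || is.null(patients)) {
      stop("classify stage needs subtyped cells and a patient table")
    }
    counts <- aggregate_patient_counts(cells, out$cell_subgroups,
                                       all_patients = patients$patient_id)
    tbl <- merge(counts, patients[, c("patient_id", "outcome")],
                 by = "patient_id", sort = FALSE)
    tbl <- tbl[!tbl$ctc_negative, ]
    out$patient_counts <- tbl
    evaluate <- function(vals, cutoff, direction) {
      pred <- classify_patients(vals, cutoff, direction)
      performance_metrics(pred, tbl$outcome,
                          auc = roc_auc(vals, tbl$outcome, direction)$auc)
    }
    out$metrics <- list(
      total = evaluate(tbl$total_ctc_count, config$count_cutoffs[["total"]],
                       "greater"),
      c1 = evaluate(tbl$c1_count, config$count_cutoffs[["c1"]], "less"),
      c2 = evaluate(tbl$c2_count, config$count_cutoffs[["c2"]], "greater"))
    say("classify: AUC total %.3f, C1 %.3f, C2 %.3f",
        out$metrics$total$auc, out$metrics$c1$auc, out$metrics$c2$auc)
  }

  out$log <- log_lines
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    if (!is.null(out$differential)) {
      write_table_auto(out$differential$pair_a, p("differential_pair_a.tsv"))
      write_table_auto(out$differential$pair_b, p("differential_pair_b.tsv"))
    }
    if (!is.null(out$risk_model)) write_risk_model(out$risk_model, p("risk_model.json"))
    if (!is.null(out$cell_subgroups)) {
      write_table_auto(data.frame(cell_id = cells$cell_ids,
                                  patient_id = cells$patient_id,
                                  score = out$scores,
                                  subgroup = out$cell_subgroups),
                       p("cell_subgroups.csv"))
    }
    if (!is.null(out$patient_counts)) {
      write_table_auto(out$patient_counts, p("patient_counts.csv"))
    }
    if (!is.null(out$metrics)) {
      jsonlite::write_json(
        lapply(out$metrics, function(m) {
          list(confusion = as.list(m$confusion),
               sensitivity_pct = m$sensitivity_pct,
               specificity_pct = m$specificity_pct,
               accuracy_pct = m$accuracy_pct, auc = m$auc, n = m$n)
        }),
        p("metrics.json"), auto_unbox = TRUE, digits = NA)
    }
    writeLines(log_lines, p("run.log"))
  }
  invisible(out)
}
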
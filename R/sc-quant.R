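#' Nanocapillary extraction geometry
#'
#' Describes the conical tip of a nanocapillary used for electro-osmotic
#' extraction of cellular content. The tip is modelled as a truncated cone:
#' `a` is the radius of the opening, `alpha` the half-angle between the cone
#' element and its axis, and `h` the height of the liquid meniscus measured
#' along the axis from the opening. The dimensionless fill ratio `L = h / a`
#' is derived.
#'
#' @param a Tip opening radius in micrometers (> 0).
#' @param alpha Cone half-angle in radians, strictly between 0 and pi/2.
#' @param h Meniscus height in micrometers (>= 0).
#' @return An object of class `extraction_geometry`.
#' @examples
#' geom <- extraction_geometry(a = 1, alpha = pi / 4, h = 1)
#' estimate_extraction_volume(geom)
#' @export
extraction_geometry <- function(a, alpha, h) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(h), length(h) == 1L, is.finite(h))
  if (a <= 0) stop("tip radius 'a' must be positive (micrometers)")
  if (alpha <= 0 || alpha >= pi / 2) {
    stop("cone half-angle 'alpha' must lie strictly between 0 and pi/2 radians")
  }
  if (h < 0) stop("meniscus height 'h' must be non-negative")
  structure(list(a = a, alpha = alpha, h = h, L = h / a),
            class = "extraction_geometry")
}

#' Estimate the extracted volume from tip geometry
#'
#' Volume of the liquid column filling a conical nanocapillary tip up to
#' meniscus height `h`:
#' \deqn{V = \frac{\pi a^3}{3 \tan\alpha}\left((1 + L\tan\alpha)^3 - 1\right),
#'   \quad L = h/a,}
#' i.e. the cone-frustum integral \eqn{\int_0^h \pi (a + x\tan\alpha)^2\,dx}.
#' With lengths in micrometers the result is in femtoliters (1 um^3 = 1 fL).
#'
#' @param geometry An [extraction_geometry()] object.
#' @return Volume in femtoliters.
#' @export
estimate_extraction_volume <- function(geometry) {
  stopifnot(inherits(geometry, "extraction_geometry"))
  a <- geometry$a
  t <- tan(geometry$alpha)
  L <- geometry$L
  pi * a^3 / (3 * t) * ((1 + L * t)^3 - 1)
}

#' Solve the meniscus height that yields a target volume
#'
#' Inverts [estimate_extraction_volume()] in `h` for fixed `a` and `alpha`.
#' Useful to reason about extraction settings, e.g. which fill height
#' corresponds to a ~120 fL withdrawal.
#'
#' @param a Tip opening radius (micrometers).
#' @param alpha Cone half-angle (radians).
#' @param volume Target volume in femtoliters (> 0).
#' @return Meniscus height `h` in micrometers.
#' @export
solve_meniscus_height <- function(a, alpha, volume) {
  stopifnot(volume > 0)
  t <- tan(alpha)
  # closed-form inverse of the cubic fill law
  a / t * ((1 + 3 * t * volume / (pi * a^3))^(1 / 3) - 1)
}

#' Fit an internal-standard calibration curve
#'
#' Ordinary least-squares fit of the analyte / internal-standard response
#' ratio against concentration, with blank-based detection limits:
#' LOD = 3.3 sigma_blank / slope and LLOQ = 10 sigma_blank / slope.
#' The reported linear range runs from the LLOQ to the highest calibration
#' level.
#'
#' @param concentration Numeric vector of calibration concentrations (mM),
#'   at least two distinct values.
#' @param response Numeric vector of analyte/IS response ratios, same length.
#' @param blank_sd Standard deviation of the blank response (>= 0).
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `lod`, `lloq`, `linear_range`, and
#'   `quantitative` (`FALSE`, with a warning, when the slope is not
#'   positive).
#' @examples
#' fit_calibration(c(0, 1, 2), c(0.28, 1.22, 2.17), blank_sd = 0.02)
#' @export
fit_calibration <- function(concentration, response, blank_sd = 0) {
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response),
            length(concentration) >= 2, blank_sd >= 0)
  if (length(unique(concentration)) < 2) {
    stop("calibration requires at least two distinct concentrations")
  }
  fit <- stats::lm(response ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  quantitative <- slope > 0
  if (!quantitative) {
    warning("non-positive calibration slope: curve flagged non-quantitative")
    lod <- lloq <- NA_real_
  } else {
    lod <- 3.3 * blank_sd / slope
    lloq <- 10 * blank_sd / slope
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, lod = lod, lloq = lloq,
                 linear_range = c(low = lloq, high = max(concentration)),
                 quantitative = quantitative,
                 n_points = length(concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: y = %.4fx %+ .4f (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  if (isTRUE(x$quantitative)) {
    cat(sprintf("  LOD %.4g, LLOQ %.4g, linear range [%.4g, %.4g]\n",
                x$lod, x$lloq, x$linear_range[["low"]],
                x$linear_range[["high"]]))
  } else {
    cat("  flagged non-quantitative (slope <= 0)\n")
  }
  invisible(x)
}

#' Back-calculate a single-cell concentration
#'
#' Normalizes the analyte peak area to the co-extracted stable-isotope
#' internal standard and inverts the calibration curve. Negative
#' back-calculated values are clamped to zero (concentrations are physical
#' quantities and downstream factorization requires non-negativity); values
#' below the LLOQ are flagged rather than dropped.
#'
#' @param analyte_signal Analyte peak area (>= 0).
#' @param is_signal Internal-standard peak area (> 0); a zero IS signal
#'   means the spike-in was not detected and quantification is refused.
#' @param curve A [fit_calibration()] result with positive slope.
#' @param is_concentration Internal-standard concentration (mM); recorded in
#'   the result for provenance, the ratio math does not depend on it.
#' @return A list with `concentration` (mM), `below_lloq` flag, and
#'   `clamped` flag.
#' @export
quantify_cell <- function(analyte_signal, is_signal, curve,
                          is_concentration = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!isTRUE(curve$quantitative)) {
    stop("calibration curve is non-quantitative (slope <= 0)")
  }
  stopifnot(is.numeric(analyte_signal), is.numeric(is_signal),
            length(analyte_signal) == 1L, length(is_signal) == 1L,
            analyte_signal >= 0)
  if (is_signal <= 0) {
    stop("internal standard not detected (is_signal <= 0); quantification refused")
  }
  ratio <- analyte_signal / is_signal
  conc <- (ratio - curve$intercept) / curve$slope
  clamped <- conc < 0
  if (clamped) conc <- 0
  list(concentration = conc,
       below_lloq = is.finite(curve$lloq) && conc < curve$lloq,
       clamped = clamped,
       is_concentration = is_concentration)
}

#' Batched positive-valued measurement matrix
#'
#' @param values Samples x features numeric matrix of positive values.
#' @param batch Batch label per sample (row).
#' @return An object of class `batched_matrix`.
#' @export
batched_matrix <- function(values, batch) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) == length(batch))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("batched_matrix values must be finite and strictly positive")
  }
  batch <- as.character(batch)
  if (anyNA(batch)) stop("every sample needs a batch label")
  structure(list(values = values, batch = batch), class = "batched_matrix")
}

#' Remove batch effects from positive measurements
#'
#' Location/scale empirical-Bayes batch adjustment (ComBat) applied to
#' log-transformed values, then mapped back to the positive scale. A single
#' batch is returned unchanged. Features with essentially zero within-batch
#' variance in some batch receive a location-only adjustment (their batch
#' means are equalized in log space) because the scale step is undefined for
#' them.
#'
#' @param x A [batched_matrix()] (samples x features).
#' @return A `batched_matrix` with corrected positive values.
#' @export
correct_batches <- function(x) {
  stopifnot(inherits(x, "batched_matrix"))
  batches <- unique(x$batch)
  if (length(batches) < 2L) return(x)
  counts <- table(x$batch)
  if (any(counts < 2L)) {
    stop("each batch needs at least 2 samples for correction; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  logv <- t(log(x$values))                       # features x samples for ComBat
  within_var <- sapply(batches, function(b) {
    apply(logv[, x$batch == b, drop = FALSE], 1L, stats::var)
  })
  degenerate <- apply(within_var < 1e-12, 1L, any)

  out <- logv
  if (any(!degenerate)) {
    out[!degenerate, ] <- suppressMessages(
      sva::ComBat(dat = logv[!degenerate, , drop = FALSE], batch = x$batch)
    )
  }
  if (any(degenerate)) {
    # location-only: shift each batch to the feature's grand mean
    for (f in which(degenerate)) {
      gm <- mean(logv[f, ])
      for (b in batches) {
        sel <- x$batch == b
        out[f, sel] <- logv[f, sel] - mean(logv[f, sel]) + gm
      }
    }
  }
  batched_matrix(t(exp(out)), x$batch)
}

#' Intra- and inter-day precision of replicate measurements
#'
#' Relative standard deviations (RSD, percent of the mean, sample standard
#' deviation) per replicate group (typically per day or per run) and for the
#' pooled values across groups. Groups pass the standard bioanalytical
#' validation criterion when RSD <= 20 percent.
#'
#' @param replicate_groups Named list of numeric vectors, one per day/run,
#'   each with at least two values.
#' @param criterion Pass threshold in percent (default 20).
#' @return A list with `intra_day` (data.frame: group, n, mean, rsd, pass),
#'   `inter_day_rsd`, and `pass` (all intra-day groups and the inter-day RSD
#'   within the criterion).
#' @export
precision_metrics <- function(replicate_groups, criterion = 20) {
  stopifnot(is.list(replicate_groups), length(replicate_groups) >= 1)
  rsd <- function(v) {
    m <- mean(v)
    if (m == 0) stop("replicate group mean is zero; RSD undefined")
    100 * stats::sd(v) / m
  }
  for (g in replicate_groups) {
    if (length(g) < 2) stop("each replicate group needs at least 2 values")
  }
  nm <- names(replicate_groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(replicate_groups))
  intra <- data.frame(
    group = nm,
    n = vapply(replicate_groups, length, integer(1)),
    mean = vapply(replicate_groups, mean, numeric(1)),
    rsd = vapply(replicate_groups, rsd, numeric(1)),
    row.names = NULL
  )
  intra$pass <- intra$rsd <= criterion
  pooled <- unlist(replicate_groups, use.names = FALSE)
  inter <- rsd(pooled)
  list(intra_day = intra,
       inter_day_rsd = inter,
       pass = all(intra$pass) && inter <= criterion)
}
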
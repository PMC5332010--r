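# Hit selection: per-plate normalisation, control-referenced Z-scores,
# threshold hit calling, and the density-dependence regression.

#' Per-plate feature normalisation
#'
#' For every plate and feature column: subtract the plate centre and divide
#' by the plate spread (mean/sd by default; median/MAD with
#' `method = "medianmad"`). Normalised values are appended as
#' `<feature>_norm` columns. Zero-spread features are skipped with a
#' warning. Idempotent up to floating point: normalising an already
#' normalised column reproduces it.
#'
#' @param table data.frame with a `plate` column and numeric feature columns.
#' @param features character vector of feature column names.
#' @param method "meansd" or "medianmad".
#' @return `table` with `<feature>_norm` columns appended.
#' @export
plate_normalise <- function(table, features, method = c("meansd", "medianmad")) {
  method <- match.arg(method)
  stopifnot("plate" %in% names(table), all(features %in% names(table)))
  plates <- unique(table$plate)
  for (f in features) {
    out <- rep(NA_real_, nrow(table))
    skip <- FALSE
    for (p in plates) {
      i <- table$plate == p
      x <- table[[f]][i]
      if (sum(i) < 2) stop("plate ", p, " has fewer than 2 wells")
      ctr <- if (method == "meansd") mean(x, na.rm = TRUE) else median(x, na.rm = TRUE)
      spr <- if (method == "meansd") {
        # population sd: a 3-well plate {1,2,3} maps to {-1.225, 0, 1.225}
        n_ok <- sum(!is.na(x))
        sd(x, na.rm = TRUE) * sqrt((n_ok - 1) / n_ok)
      } else mad(x, na.rm = TRUE)
      if (!is.finite(spr) || spr == 0) { skip <- TRUE; break }
      out[i] <- (x - ctr) / spr
    }
    if (skip) {
      warning("feature '", f, "' has zero spread on a plate; skipped")
      next
    }
    table[[paste0(f, "_norm")]] <- out
  }
  table
}

#' Control-referenced Z-scores
#'
#' `Z = (x - mean(controls)) / sd(controls)`, with the control statistics
#' pooled over all control wells of the screen (all plates of `table`).
#' Zero-variance control features are skipped with a warning.
#'
#' @param table data.frame of (typically plate-normalised) well values.
#' @param features feature column names to score.
#' @param control logical vector marking the control wells of `table`.
#' @return `table` with `<feature>_z` columns appended.
#' @export
zscore_to_controls <- function(table, features, control) {
  stopifnot(length(control) == nrow(table), all(features %in% names(table)))
  if (sum(control) < 3) stop("need at least 3 control wells, got ", sum(control))
  for (f in features) {
    x <- table[[f]]
    mu <- mean(x[control], na.rm = TRUE)
    sig <- sd(x[control], na.rm = TRUE)
    if (!is.finite(sig) || sig == 0) {
      warning("control sd is zero for '", f, "'; skipped")
      next
    }
    table[[paste0(f, "_z")]] <- (x - mu) / sig
  }
  table
}

#' Call hits from control-referenced Z-scores
#'
#' A well is a hit for a feature when `|Z| >= threshold` (1.5 by default).
#' Fold change is computed on the raw (unnormalised) scale relative to the
#' control mean. Returns one row per (well, feature), ranked by |Z| within
#' feature.
#'
#' @param table well table carrying raw features, `<feature>_z` columns, and
#'   a `gene` column.
#' @param features raw feature column names to call on.
#' @param control logical vector marking control wells.
#' @param threshold minimum |Z| for a hit.
#' @return data.frame: `gene`, `well`, `feature`, `z`, `fold_change`,
#'   `direction`, `hit`.
#' @export
call_hits <- function(table, features, control,
                      threshold = default_config()$screen$hit_threshold) {
  rows <- list()
  for (f in features) {
    zc <- paste0(f, "_z")
    if (!zc %in% names(table)) next
    ctrl_mean <- mean(table[[f]][control], na.rm = TRUE)
    z <- table[[zc]]
    df <- data.frame(
      gene = if ("gene" %in% names(table)) table$gene else NA_character_,
      well = if ("well" %in% names(table)) table$well else seq_len(nrow(table)),
      feature = f, z = z,
      fold_change = if (is.finite(ctrl_mean) && ctrl_mean != 0) {
        table[[f]] / ctrl_mean
      } else NA_real_,
      direction = ifelse(z >= 0, "up", "down"),
      hit = abs(z) >= threshold)
    df <- df[order(-abs(df$z)), ]
    rows[[f]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Density-dependence regression of the YAP/TAZ ratio
#'
#' Ordinary least squares of a well statistic (typically the YAP/TAZ ratio)
#' on the plated cell density of the dilution wells, as used to characterise
#' the relationship between YAP/TAZ localisation and cell density.
#'
#' @param cells_plated numeric vector of plated densities.
#' @param value well statistic (same length).
#' @return list: `slope`, `intercept`, `r_squared`, `slope_ci` (95%),
#'   `fit` (the `lm` object), `residuals`.
#' @export
density_regression <- function(cells_plated, value) {
  ok <- is.finite(cells_plated) & is.finite(value)
  if (length(unique(cells_plated[ok])) < 3) {
    stop("need at least 3 distinct plated densities")
  }
  fit <- lm(value ~ cells_plated, subset = ok)
  ci <- suppressWarnings(confint(fit))["cells_plated", ]
  # summary.lm warns on an exactly linear input (the noiseless oracle case)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2,
       slope_ci = unname(ci), fit = fit, residuals = residuals(fit))
}

#' @importFrom stats confint residuals
NULL

#' Simulate well-level screen tables
#'
#' A lightweight Gaussian generator of well-by-feature tables for studying
#' the screen statistics at scale (null hit rates, spike recovery, replicate
#' reproducibility) without rendering images. Each well's feature vector is
#' `plate offset + well effect + noise`; technical replicates of the same
#' well id share the well effect, giving a tunable within-well (replicate)
#' correlation `rho = var_well / (var_well + var_noise)`.
#'
#' @param n_wells wells per plate.
#' @param n_features features per well.
#' @param plates character vector of plate ids (replicate plates).
#' @param within_cor target correlation between replicate wells' feature
#'   vectors (0 = independent).
#' @param effects optional numeric matrix (`n_wells` x `n_features`) of
#'   added per-well effects (same on all plates).
#' @param plate_offset sd of per-plate, per-feature offsets.
#' @param seed RNG seed.
#' @return data.frame: `plate`, `well`, `gene`, feature columns `f1..fk`.
#' @export
simulate_well_table <- function(n_wells = 300L, n_features = 50L,
                                plates = c("1A", "1B"), within_cor = 0,
                                effects = NULL, plate_offset = 0.5,
                                seed = 1L) {
  set.seed(seed)
  stopifnot(within_cor >= 0, within_cor < 1)
  v_well <- within_cor
  v_noise <- 1 - within_cor
  wells <- sprintf("w%03d", seq_len(n_wells))
  base <- matrix(rnorm(n_wells * n_features, sd = sqrt(v_well)),
                 n_wells, n_features)
  if (!is.null(effects)) base <- base + effects
  out <- list()
  for (p in plates) {
    off <- matrix(rnorm(n_features, sd = plate_offset), n_wells, n_features,
                  byrow = TRUE)
    noise <- matrix(rnorm(n_wells * n_features, sd = sqrt(v_noise)),
                    n_wells, n_features)
    m <- base + off + noise
    colnames(m) <- paste0("f", seq_len(n_features))
    out[[p]] <- data.frame(plate = p, well = wells, gene = wells, m,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
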
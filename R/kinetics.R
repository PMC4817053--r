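# Colorimetric pNPP assay analysis: Beer-Lambert conversion, initial
# velocities, Michaelis-Menten fitting, kcat, and treated-vs-control
# comparison.

#' Beer-Lambert configuration for plate-reader absorbance
#'
#' The p-nitrophenolate product is read at 405 nm with molar extinction
#' coefficient 17.8 per mM per cm; the vertical light path through a
#' well is fixed by the liquid volume and well radius rather than a
#' cuvette.
#'
#' @param epsilon molar extinction coefficient (mM^-1 cm^-1),
#'   default 17.8.
#' @param well_radius_mm average well radius (mm), default 4.
#' @param well_volume_ul reaction volume per well (ul), default 100.
#' @return a config list.
#' @export
beer_lambert_config <- function(epsilon = 17.8, well_radius_mm = 4,
                                well_volume_ul = 100) {
  stopifnot(epsilon > 0, well_radius_mm > 0, well_volume_ul > 0)
  list(epsilon = epsilon, well_radius_mm = well_radius_mm,
       well_volume_ul = well_volume_ul)
}

#' Light path length from well geometry
#'
#' Height of the liquid column: `volume / (pi r^2)`, returned in cm.
#' 100 ul in a 4 mm-radius well gives 0.199 cm.
#'
#' @param volume_ul liquid volume (ul).
#' @param radius_mm well radius (mm).
#' @return path length in cm.
#' @export
path_length <- function(volume_ul = 100, radius_mm = 4) {
  stopifnot(volume_ul > 0, radius_mm > 0)
  vol_cm3 <- volume_ul / 1000
  r_cm <- radius_mm / 10
  vol_cm3 / (pi * r_cm^2)
}

#' Convert absorbance to concentration
#'
#' `c = A / (epsilon * path)`. Negative absorbances (blank noise) are
#' clipped to zero with a warning.
#'
#' @param absorbance numeric A405 values.
#' @param beer a [beer_lambert_config()].
#' @return concentration in mM.
#' @export
absorbance_to_concentration <- function(absorbance,
                                        beer = beer_lambert_config()) {
  if (any(absorbance < 0)) {
    rlang::warn("Negative absorbance value(s) clipped to 0")
    absorbance <- pmax(absorbance, 0)
  }
  path <- path_length(beer$well_volume_ul, beer$well_radius_mm)
  absorbance / (beer$epsilon * path)
}

#' Initial velocity from a progress curve
#'
#' The slope of the most linear portion of the product-vs-time curve.
#' All contiguous windows of `min_points` to `max_points` samples are
#' scored by linear-fit R-squared; among windows whose R-squared lies
#' within `r2_slack` of the best (i.e. indistinguishable in linearity at
#' the noise level), the earliest-starting and then longest window is
#' used, matching the initial-rate convention: when several stretches
#' are equally linear, the one closest to t = 0 is least affected by
#' substrate depletion. The window cap bounds depletion bias on slow
#' curves. The estimator is invariant to a constant offset, matching
#' blank subtraction. Selected window and R-squared are reported.
#'
#' @param time_min sample times (min), >= 5 points.
#' @param concentration product concentrations (mM).
#' @param min_points minimum window length (default 5).
#' @param max_points maximum window length (default 11; at 3-minute
#'   plate reads that is a half-hour stretch).
#' @param r2_slack R-squared band counted as a tie (default 0.02).
#' @return one-row tibble `v0` (mM/min), `window_start`, `window_end`,
#'   `r_squared`, `n_points`. With fewer than `min_points` samples the
#'   full-curve slope is returned with a warning.
#' @export
initial_velocity <- function(time_min, concentration, min_points = 5,
                             max_points = 11, r2_slack = 0.02) {
  stopifnot(length(time_min) == length(concentration),
            min_points >= 3, max_points >= min_points, r2_slack >= 0)
  n <- length(time_min)
  slope_r2 <- function(t, y) {
    f <- stats::lm.fit(cbind(1, t), y)
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    c(unname(f$coefficients[2]),
      if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
  }
  if (n < min_points) {
    rlang::warn("Fewer samples than the window length; full-curve slope")
    sr <- slope_r2(time_min, concentration)
    return(tibble::tibble(v0 = sr[1], window_start = time_min[1],
                          window_end = time_min[n], r_squared = sr[2],
                          n_points = n))
  }
  cand <- list()
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, min(n, i + max_points - 1))) {
      sr <- slope_r2(time_min[i:j], concentration[i:j])
      cand[[length(cand) + 1]] <- c(i, j, sr)
    }
  }
  cand <- do.call(rbind, cand)
  eligible <- cand[cand[, 4] >= max(cand[, 4]) - r2_slack, , drop = FALSE]
  eligible <- eligible[eligible[, 1] == min(eligible[, 1]), , drop = FALSE]
  best <- eligible[which.max(eligible[, 2]), ]
  tibble::tibble(v0 = best[3], window_start = time_min[best[1]],
                 window_end = time_min[best[2]], r_squared = best[4],
                 n_points = best[2] - best[1] + 1)
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `v = Vmax S / (Km + S)` over initial
#' velocities at >= 3 substrate concentrations
#' (Levenberg-Marquardt via minpack.lm). 95% confidence intervals come
#' from the linearized fit covariance (delta method); the turnover
#' number is `kcat = Vmax / [E]` with units reconciled (Vmax in mM/min,
#' enzyme in uM, kcat in min^-1).
#'
#' @param v0 initial velocities (mM/min).
#' @param substrate_mM substrate concentrations (mM).
#' @param enzyme_uM total enzyme concentration (uM), default 2.1.
#' @return an `"mm_fit"` object; see [tidy.mm_fit()] and
#'   [glance.mm_fit()].
#' @examples
#' s <- c(0.8, 2, 5, 15, 40)
#' v <- 1 * s / (5 + s)
#' fit_michaelis_menten(v, s)
#' @export
fit_michaelis_menten <- function(v0, substrate_mM, enzyme_uM = 2.1) {
  stopifnot(length(v0) == length(substrate_mM),
            length(unique(substrate_mM)) >= 3, enzyme_uM > 0)
  if (all(v0 == 0)) {
    rlang::abort("All velocities are zero; Michaelis-Menten fit is degenerate")
  }
  if (stats::sd(v0) / mean(v0) < 1e-8) {
    # saturation limit: constant v carries no Km information
    rlang::warn("Velocities constant across the substrate grid; Vmax taken as their mean, Km unconstrained")
    n <- length(v0)
    return(structure(list(
      Vmax = mean(v0), Km = 0, Vmax_se = stats::sd(v0) / sqrt(n),
      Km_se = Inf, Vmax_ci = rep(mean(v0), 2), Km_ci = c(0, Inf),
      kcat = mean(v0) * 1000 / enzyme_uM, enzyme_uM = enzyme_uM,
      saturated = TRUE,
      data = tibble::tibble(substrate_mM = substrate_mM, v0 = v0,
                            fitted = mean(v0)),
      fit = NULL
    ), class = "mm_fit"))
  }
  start <- list(Vmax = max(v0) * 1.2,
                Km = max(substrate_mM[which(v0 <= max(v0) / 2)][1],
                         min(substrate_mM) / 2, na.rm = TRUE))
  df <- data.frame(S = substrate_mM, v = v0)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df, start = start,
                      lower = c(Vmax = 0, Km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      rlang::abort(paste0("Michaelis-Menten fit did not converge (start ",
                          "Vmax = ", signif(start$Vmax, 4), ", Km = ",
                          signif(start$Km, 4), "): ", conditionMessage(e)))
    }
  )
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zcrit <- stats::qt(0.975, df = max(1, length(v0) - 2))
  saturated <- est[["Km"]] < min(substrate_mM) / 10
  if (saturated) {
    rlang::warn("Km estimate far below the substrate range; poorly constrained")
  }
  structure(list(
    Vmax = est[["Vmax"]], Km = est[["Km"]],
    Vmax_se = se[["Vmax"]], Km_se = se[["Km"]],
    Vmax_ci = est[["Vmax"]] + c(-1, 1) * zcrit * se[["Vmax"]],
    Km_ci = est[["Km"]] + c(-1, 1) * zcrit * se[["Km"]],
    kcat = est[["Vmax"]] * 1000 / enzyme_uM,  # mM/min over uM -> min^-1
    enzyme_uM = enzyme_uM, saturated = saturated,
    data = tibble::tibble(substrate_mM = substrate_mM, v0 = v0,
                          fitted = stats::fitted(fit)),
    fit = fit
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> Michaelis-Menten fit\n")
  cat(sprintf("  Km   = %.4g mM (95%% CI %.4g - %.4g)\n",
              x$Km, x$Km_ci[1], x$Km_ci[2]))
  cat(sprintf("  Vmax = %.4g mM/min (95%% CI %.4g - %.4g)\n",
              x$Vmax, x$Vmax_ci[1], x$Vmax_ci[2]))
  cat(sprintf("  kcat = %.4g min^-1 at [E] = %.3g uM\n",
              x$kcat, x$enzyme_uM))
  invisible(x)
}

#' Full progress-curve workflow: absorbance table to kinetic fit
#'
#' Converts each substrate concentration's absorbance series to product
#' concentration, extracts initial velocities, and fits the
#' Michaelis-Menten equation.
#'
#' @param curves tibble `substrate_mM`, `time_min`, `absorbance` (e.g.
#'   from [simulate_pnpp_progress()] or a plate-reader CSV).
#' @param beer a [beer_lambert_config()].
#' @inheritParams fit_michaelis_menten
#' @inheritParams initial_velocity
#' @return an `"mm_fit"`; the per-concentration velocity table is in
#'   `$velocities`.
#' @export
fit_progress_curves <- function(curves, beer = beer_lambert_config(),
                                enzyme_uM = 2.1, min_points = 5) {
  stopifnot(all(c("substrate_mM", "time_min", "absorbance") %in%
                  names(curves)))
  vel <- curves |>
    dplyr::group_by(.data$substrate_mM) |>
    dplyr::group_modify(function(df, key) {
      conc <- absorbance_to_concentration(df$absorbance, beer)
      initial_velocity(df$time_min, conc, min_points)
    }) |>
    dplyr::ungroup()
  fit <- fit_michaelis_menten(vel$v0, vel$substrate_mM, enzyme_uM)
  fit$velocities <- vel
  fit
}

#' Compare two Michaelis-Menten fits
#'
#' Fold changes (first fit over second and its inverse) for Km, Vmax
#' and kcat, with 95% confidence intervals propagated on the log scale
#' (delta method) and a flag for whether the parameter CIs overlap.
#'
#' @param fit_a,fit_b `"mm_fit"` objects (e.g. oxidized vs control).
#' @return tibble `parameter`, `a`, `b`, `fold_a_over_b`,
#'   `fold_b_over_a`, `fold_ci_low`, `fold_ci_high`, `ci_overlap`.
#' @export
compare_kinetics <- function(fit_a, fit_b) {
  rows <- lapply(c("Km", "Vmax", "kcat"), function(par) {
    a <- fit_a[[par]]
    b <- fit_b[[par]]
    if (par == "kcat") {
      # kcat is Vmax rescaled by [E]; reuse Vmax relative errors
      se_a <- fit_a$Vmax_se / fit_a$Vmax * a
      se_b <- fit_b$Vmax_se / fit_b$Vmax * b
      ci_a <- a + c(-1, 1) * 1.96 * se_a
      ci_b <- b + c(-1, 1) * 1.96 * se_b
    } else {
      se_a <- fit_a[[paste0(par, "_se")]]
      se_b <- fit_b[[paste0(par, "_se")]]
      ci_a <- fit_a[[paste0(par, "_ci")]]
      ci_b <- fit_b[[paste0(par, "_ci")]]
    }
    fold <- a / b
    log_se <- sqrt((se_a / a)^2 + (se_b / b)^2)
    tibble::tibble(
      parameter = par, a = a, b = b,
      fold_a_over_b = fold, fold_b_over_a = 1 / fold,
      fold_ci_low = fold * exp(-1.96 * log_se),
      fold_ci_high = fold * exp(1.96 * log_se),
      ci_overlap = ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2]
    )
  })
  dplyr::bind_rows(rows)
}
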
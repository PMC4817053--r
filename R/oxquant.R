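# Site-specific oxidation quantitation from extracted ion chromatograms.

#' Extract an ion chromatogram
#'
#' Per scan, sums the intensities of all centroids whose m/z lies within
#' `tolerance_ppm` of any target m/z. The default workflow targets the
#' monoisotopic and A+1 peaks of a species (see [species_mz()]) at 5 ppm.
#'
#' @param run spectra table (`scan_time`, `mz`, `intensity`).
#' @param targets numeric vector of target m/z values.
#' @param tolerance_ppm half-width of the extraction window in ppm
#'   (default 5).
#' @return an `"xic"`: tibble with `scan_time` and `intensity`, one row
#'   per scan present in the run (scans with no matching centroid get
#'   intensity 0). Targets and tolerance are kept as attributes.
#' @export
extract_xic <- function(run, targets, tolerance_ppm = 5) {
  assert_spectra(run)
  stopifnot(tolerance_ppm > 0, length(targets) > 0)
  scan_times <- sort(unique(run$scan_time))
  if (length(scan_times) == 0) {
    out <- tibble::tibble(scan_time = numeric(), intensity = numeric())
  } else {
    hit <- rep(FALSE, nrow(run))
    for (tg in targets) {
      hit <- hit | abs(run$mz - tg) <= tg * tolerance_ppm * 1e-6
    }
    matched <- run[hit, ]
    sums <- tapply(matched$intensity, matched$scan_time, sum)
    out <- tibble::tibble(
      scan_time = scan_times,
      intensity = as.numeric(sums[as.character(scan_times)])
    )
    out$intensity[is.na(out$intensity)] <- 0
  }
  structure(out, targets = targets, tolerance_ppm = tolerance_ppm,
            class = c("xic", class(out)))
}

# apex +/- extent to 1% of apex, the default integration window
detect_peak_window <- function(xic) {
  if (nrow(xic) == 0 || all(xic$intensity <= 0)) {
    return(c(NA_real_, NA_real_))
  }
  apex <- which.max(xic$intensity)
  thr <- 0.01 * xic$intensity[apex]
  lo <- apex
  while (lo > 1 && xic$intensity[lo - 1] >= thr) lo <- lo - 1
  hi <- apex
  while (hi < nrow(xic) && xic$intensity[hi + 1] >= thr) hi <- hi + 1
  c(xic$scan_time[lo], xic$scan_time[hi])
}

#' Integrate the area under an XIC peak
#'
#' Trapezoidal integral over a time window. When no window is given the
#' peak bounds are auto-detected as the apex plus its contiguous extent
#' down to 1% of the apex intensity on each side.
#'
#' @param xic an `"xic"` from [extract_xic()] (or any table with
#'   `scan_time` and `intensity`).
#' @param window optional `c(t0, t1)` in minutes, `t0 < t1`.
#' @return the AUC (intensity x minutes); 0 for an all-zero XIC.
#' @export
integrate_auc <- function(xic, window = NULL) {
  if (nrow(xic) < 2) return(0)
  if (is.null(window)) {
    window <- detect_peak_window(xic)
    if (anyNA(window)) return(0)
  }
  stopifnot(length(window) == 2, window[1] <= window[2])
  keep <- xic$scan_time >= window[1] & xic$scan_time <= window[2]
  t <- xic$scan_time[keep]
  y <- xic$intensity[keep]
  if (length(t) < 2) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Oxidized : non-oxidized AUC ratio in one run
#'
#' Extracts XICs for the oxidized and non-oxidized species of the same
#' peptide backbone (monoisotopic and A+1 targets each), integrates
#' their auto-detected peaks, and returns the AUC ratio. A zero
#' non-oxidized AUC yields an `NA` ratio with a warning rather than an
#' error; callers exclude such replicates from group means.
#'
#' @param run spectra table for one replicate.
#' @param mz_oxidized,mz_nonoxidized target m/z vectors for the two
#'   species (typically from [species_mz()]).
#' @param tolerance_ppm extraction tolerance (default 5 ppm).
#' @param windows optional list with elements `oxidized` and
#'   `nonoxidized`, each `c(t0, t1)`; `NULL` auto-detects.
#' @return one-row tibble `auc_oxidized`, `auc_nonoxidized`, `ratio`.
#' @export
site_oxidation_ratio <- function(run, mz_oxidized, mz_nonoxidized,
                                 tolerance_ppm = 5, windows = NULL) {
  auc_ox <- integrate_auc(extract_xic(run, mz_oxidized, tolerance_ppm),
                          windows$oxidized)
  auc_non <- integrate_auc(extract_xic(run, mz_nonoxidized, tolerance_ppm),
                           windows$nonoxidized)
  ratio <- if (auc_non > 0) auc_ox / auc_non else {
    rlang::warn("Non-oxidized AUC is zero; ratio undefined (NA)")
    NA_real_
  }
  tibble::tibble(auc_oxidized = auc_ox, auc_nonoxidized = auc_non,
                 ratio = ratio)
}

#' Per-replicate oxidation ratios for a multi-run collection
#'
#' Maps [site_oxidation_ratio()] over every `group` x `replicate` in a
#' simulated or imported collection of runs.
#'
#' @param runs spectra table with `group` and `replicate` columns.
#' @inheritParams site_oxidation_ratio
#' @return tibble `group`, `replicate`, `auc_oxidized`,
#'   `auc_nonoxidized`, `ratio`.
#' @export
quantify_oxidation <- function(runs, mz_oxidized, mz_nonoxidized,
                               tolerance_ppm = 5, windows = NULL) {
  runs |>
    dplyr::group_by(.data$group, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      site_oxidation_ratio(df, mz_oxidized, mz_nonoxidized,
                           tolerance_ppm, windows)
    }) |>
    dplyr::ungroup()
}

#' Fold change in oxidation versus the control group
#'
#' Per-replicate ratios are averaged within each group; the fold change
#' is the group mean over the control mean, and the p-value comes from a
#' two-tailed homoscedastic (pooled-variance) two-sample Student t-test
#' on the per-replicate ratios.
#'
#' @param group_ratios numeric per-replicate ratios of the treatment
#'   group (`NA`s dropped with a warning).
#' @param control_ratios per-replicate ratios of the control group.
#' @return one-row tibble `fold`, `p_value`, `degenerate` (TRUE when
#'   the pooled variance is zero and the p-value is reported at the
#'   machine limit), `n_group`, `n_control`.
#' @export
fold_change_vs_control <- function(group_ratios, control_ratios) {
  drop_na <- function(x, label) {
    if (anyNA(x)) {
      rlang::warn(paste0("Dropping ", sum(is.na(x)), " undefined ratio(s) in ",
                         label, " group"))
      x <- x[!is.na(x)]
    }
    x
  }
  g <- drop_na(group_ratios, "treatment")
  ctl <- drop_na(control_ratios, "control")
  stopifnot(length(g) >= 1, length(ctl) >= 1)
  mean_ctl <- mean(ctl)
  fold <- if (mean_ctl > 0) mean(g) / mean_ctl else {
    rlang::warn("Control mean ratio is zero; fold change undefined (NA)")
    NA_real_
  }
  degenerate <- FALSE
  if (length(g) >= 2 && length(ctl) >= 2) {
    pooled_var <- (sum((g - mean(g))^2) + sum((ctl - mean(ctl))^2)) /
      (length(g) + length(ctl) - 2)
    if (pooled_var == 0) {
      degenerate <- TRUE
      p <- if (isTRUE(all.equal(mean(g), mean_ctl))) 1 else
        .Machine$double.eps
      if (p < 1) {
        rlang::warn("Zero within-group variance with unequal means; p-value at machine limit")
      }
    } else {
      p <- stats::t.test(g, ctl, var.equal = TRUE)$p.value
    }
  } else {
    p <- NA_real_
  }
  tibble::tibble(fold = fold, p_value = p, degenerate = degenerate,
                 n_group = length(g), n_control = length(ctl))
}

#' Global oxidized / non-oxidized intensity ratio
#'
#' Whole-protein oxidation summary: the summed intensity of all
#' oxidized peptides over the summed intensity of all non-oxidized
#' peptides in an identification table.
#'
#' @param intensity_table data frame with a logical `oxidized` column
#'   and a numeric `intensity` column (one row per identified peptide).
#' @return the ratio; `NA` with a warning when no non-oxidized
#'   intensity is present.
#' @export
global_oxidation_ratio <- function(intensity_table) {
  stopifnot(all(c("oxidized", "intensity") %in% names(intensity_table)))
  num <- sum(intensity_table$intensity[intensity_table$oxidized])
  den <- sum(intensity_table$intensity[!intensity_table$oxidized])
  if (den <= 0) {
    rlang::warn("No non-oxidized intensity; global ratio undefined (NA)")
    return(NA_real_)
  }
  num / den
}

#' Normalize per-site mod/base values to the largest value
#'
#' Rescales a set of per-residue modified/unmodified intensity ratios so
#' the most-oxidized site maps to 1.
#'
#' @param values data frame with columns `site` and `value`
#'   (values >= 0), or a named numeric vector.
#' @return tibble `site`, `value`, `normalized`; all-zero input returns
#'   zeros with a warning.
#' @export
normalize_modbase <- function(values) {
  if (is.numeric(values)) {
    values <- tibble::tibble(site = names(values), value = unname(values))
  }
  stopifnot(all(c("site", "value") %in% names(values)),
            nrow(values) > 0, all(values$value >= 0))
  mx <- max(values$value)
  out <- tibble::as_tibble(values)
  if (mx == 0) {
    rlang::warn("All mod/base values are zero; normalization undefined")
    out$normalized <- 0
  } else {
    out$normalized <- out$value / mx
  }
  out
}
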
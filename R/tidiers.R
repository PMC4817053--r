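# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Michaelis-Menten fit
#'
#' @param x an `"mm_fit"`.
#' @param ... unused.
#' @return one row per parameter (`Km`, `Vmax`, `kcat`) with `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Km", "Vmax", "kcat"),
    estimate = c(x$Km, x$Vmax, x$kcat),
    std.error = c(x$Km_se, x$Vmax_se, x$Vmax_se * 1000 / x$enzyme_uM),
    conf.low = c(x$Km_ci[1], x$Vmax_ci[1],
                 (x$Vmax - 1.96 * x$Vmax_se) * 1000 / x$enzyme_uM),
    conf.high = c(x$Km_ci[2], x$Vmax_ci[2],
                  (x$Vmax + 1.96 * x$Vmax_se) * 1000 / x$enzyme_uM)
  )
}

#' Glance at a Michaelis-Menten fit
#'
#' @param x an `"mm_fit"`.
#' @param ... unused.
#' @return one-row tibble with `Km`, `Vmax`, `kcat`, `enzyme_uM`,
#'   `sigma`, `n`, `saturated`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    Km = x$Km, Vmax = x$Vmax, kcat = x$kcat, enzyme_uM = x$enzyme_uM,
    sigma = if (is.null(x$fit)) NA_real_ else stats::sigma(x$fit),
    n = nrow(x$data),
    saturated = x$saturated
  )
}

#' Tidy a discriminability profile
#'
#' @param x a `"discriminability_profile"`.
#' @param ... unused.
#' @return the underlying tibble (`residue`, `eta`, `com_deviation`,
#'   `flagged`).
#' @method tidy discriminability_profile
#' @export
tidy.discriminability_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("residue", "eta", "com_deviation",
                                 "flagged")])
}

#' Glance at a discriminability profile
#'
#' @param x a `"discriminability_profile"`.
#' @param ... unused.
#' @return one-row tibble: `n_residues`, `eta_crit`, `n_flagged`,
#'   `max_eta`, `max_com_deviation`.
#' @method glance discriminability_profile
#' @export
glance.discriminability_profile <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x), eta_crit = attr(x, "eta_crit"),
    n_flagged = sum(x$flagged), max_eta = max(x$eta),
    max_com_deviation = max(x$com_deviation)
  )
}
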
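# Elemental mass tables and amino-acid compositions.
#
# Monoisotopic masses: CODATA/IUPAC values to >= 5 decimals.
# Average masses: IUPAC standard atomic weights (conventional values).
# All peptide masses in this package are computed from elemental
# composition, so monoisotopic and average masses always refer to the
# same molecule.

.elements_mono <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.9637064864
)

.elements_avg <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  S  = 32.06,
  P  = 30.973762,
  Na = 22.98976928,
  K  = 39.0983
)

.electron_mass <- 0.000548579909
.proton_mass <- 1.00727646688

# Spacing of the A+1 isotope peak above the monoisotopic peak (13C
# dominant); fine structure is not modelled.
.a1_spacing <- 1.00336

# Cation masses used for adduct m/z: neutral atom minus one electron.
.cation_mass <- c(
  H  = .elements_mono[["H"]] - .electron_mass,
  Na = .elements_mono[["Na"]] - .electron_mass,
  K  = .elements_mono[["K"]] - .electron_mass
)

# Residue (i.e. dehydrated amino-acid) elemental compositions.
.residue_comp <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1)
)

.water_comp <- c(H = 2, O = 1)

# ---- composition arithmetic --------------------------------------------

comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}

comp_mass <- function(comp, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  tab <- if (kind == "monoisotopic") .elements_mono else .elements_avg
  unknown <- setdiff(names(comp), names(tab))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  sum(tab[names(comp)] * comp)
}

parse_formula <- function(formula) {
  # "C4H4O3" -> named vector; element symbols with optional counts.
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    rlang::abort(paste0("Cannot parse formula: '", formula, "'"))
  }
  els <- sub("[0-9]*$", "", parts)
  n <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(n, els, sum)
  stats::setNames(as.numeric(out), names(out))
}
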
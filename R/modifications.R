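#' Residue modification table
#'
#' The built-in table of residue-level modifications. Each row gives the
#' label used in peptide spec strings (e.g. `"M(ox)"`), the elemental
#' composition of the mass shift, the monoisotopic and average deltas
#' (Da), and the residues the modification may sit on.
#'
#' Additional modifications can be appended by the caller: any tibble
#' with the same columns is accepted wherever a `mod_table` argument
#' appears. Compositions are given as chemical formulas (e.g. `"HO3P"`)
#' so that monoisotopic and average deltas always describe the same
#' chemistry.
#'
#' @param extra optional tibble of additional rows with columns
#'   `label`, `formula`, `targets` (character vector of one-letter
#'   residue codes, or `"*"` for any residue).
#' @return a tibble with columns `label`, `formula`, `mono_delta`,
#'   `avg_delta`, `targets` (list column).
#' @examples
#' modification_table()
#' @export
modification_table <- function(extra = NULL) {
  base <- tibble::tribble(
    ~label,   ~formula,  ~targets,
    "ph",     "HPO3",    c("H", "S", "T", "Y"),
    "ox",     "O",       c("M", "C", "Y", "W"),
    "diox",   "O2",      c("M", "C", "W"),
    "triox",  "O3",      c("C"),
    "cam",    "C2H3NO",  c("C")
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    base <- dplyr::bind_rows(base, extra[c("label", "formula", "targets")])
  }
  base$mono_delta <- vapply(base$formula,
    function(f) comp_mass(parse_formula(f), "monoisotopic"), numeric(1))
  base$avg_delta <- vapply(base$formula,
    function(f) comp_mass(parse_formula(f), "average"), numeric(1))
  base[c("label", "formula", "mono_delta", "avg_delta", "targets")]
}

# Terminal groups, expressed as composition deltas relative to the bare
# residue chain (i.e. the free-termini peptide already includes water;
# deltas here are relative to free N-terminal amine / C-terminal acid).
.n_term_groups <- list(
  free     = c(C = 0),
  succinyl = parse_formula("C4H4O3")
)

.c_term_groups <- list(
  free = c(C = 0),
  # condensation with p-nitroaniline (C6H6N2O2) releasing water
  pna  = comp_add(parse_formula("C6H6N2O2"), -.water_comp)
)

.n_term_aliases <- c(Suc = "succinyl", suc = "succinyl", H = "free")
.c_term_aliases <- c(pNA = "pna", pna = "pna", OH = "free")

mod_lookup <- function(label, mod_table) {
  i <- match(label, mod_table$label)
  if (is.na(i)) {
    rlang::abort(paste0("Unknown modification label: '", label, "'"))
  }
  mod_table[i, ]
}

#' @rdname modification_table
#' @format NULL
#' @section Built-in labels:
#' * `ph` phosphorylation, +79.96633 Da, His/Ser/Thr/Tyr
#' * `ox` mono-oxidation, +15.99491 Da, Met/Cys/Tyr/Trp
#' * `diox` di-oxidation, +31.98983 Da, Met/Cys/Trp
#' * `triox` tri-oxidation, +47.98474 Da, Cys
#' * `cam` carbamidomethylation, +57.02146 Da, Cys
#'
#' Terminal groups (handled separately from residue modifications):
#' N-terminal `succinyl` (+100.01604 Da) and C-terminal `pna`
#' (p-nitroanilide, +120.03236 Da relative to the free acid).
#' @name modification_table
NULL
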
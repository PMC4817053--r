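#' Construct a modified peptide
#'
#' A peptide is a one-letter amino-acid sequence plus a terminal-group
#' pair and a set of residue modifications. All mass computation in the
#' package goes through this object.
#'
#' @param sequence one-letter amino-acid string (may be empty).
#' @param n_term N-terminal group: `"free"` or `"succinyl"`.
#' @param c_term C-terminal group: `"free"` or `"pna"` (p-nitroanilide).
#' @param mods tibble/data frame with columns `position` (1-based
#'   residue index) and `label` (a row of [modification_table()]), or
#'   `NULL` for none.
#' @param mod_table modification table; defaults to the built-in one.
#' @return an object of class `"peptide"`.
#' @examples
#' peptide("AHPF", n_term = "succinyl", c_term = "pna")
#' parse_peptide("Suc-AHPF-pNA")
#' parse_peptide("VYEAGM(ox)K")
#' @export
peptide <- function(sequence, n_term = "free", c_term = "free",
                    mods = NULL, mod_table = modification_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  letters_seq <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(letters_seq, names(.residue_comp))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown residue letter(s): ",
                        paste(unique(unknown), collapse = ", ")))
  }
  if (!n_term %in% names(.n_term_groups)) {
    rlang::abort(paste0("Unknown N-terminal group: '", n_term, "'"))
  }
  if (!c_term %in% names(.c_term_groups)) {
    rlang::abort(paste0("Unknown C-terminal group: '", c_term, "'"))
  }
  if (is.null(mods)) {
    mods <- tibble::tibble(position = integer(), label = character())
  } else {
    mods <- tibble::as_tibble(mods)[c("position", "label")]
    mods$position <- as.integer(mods$position)
  }
  p <- structure(
    list(sequence = sequence, n_term = n_term, c_term = c_term,
         mods = mods),
    class = "peptide"
  )
  validate_peptide(p, mod_table)
  p
}

validate_peptide <- function(p, mod_table = modification_table()) {
  n <- nchar(p$sequence)
  if (nrow(p$mods) == 0) return(invisible(p))
  if (any(p$mods$position < 1 | p$mods$position > n)) {
    rlang::abort("Modification position outside 1..nchar(sequence)")
  }
  ox_labels <- c("ox", "diox", "triox")
  for (i in seq_len(nrow(p$mods))) {
    row <- mod_lookup(p$mods$label[i], mod_table)
    res <- substr(p$sequence, p$mods$position[i], p$mods$position[i])
    tgt <- row$targets[[1]]
    if (!identical(tgt, "*") && !res %in% tgt) {
      rlang::abort(paste0("Modification '", row$label,
                          "' not allowed on residue ", res,
                          " at position ", p$mods$position[i]))
    }
  }
  # a residue carries at most one oxidation-state label
  ox <- p$mods[p$mods$label %in% ox_labels, ]
  if (anyDuplicated(ox$position) > 0) {
    rlang::abort("A residue may carry at most one oxidation-state label")
  }
  if (anyDuplicated(paste(p$mods$position, p$mods$label)) > 0) {
    rlang::abort("Duplicate modification at the same position")
  }
  invisible(p)
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", format_peptide(x), "\n", sep = "")
  cat("  monoisotopic ", format(round(monoisotopic_mass(x), 4), nsmall = 4),
      " Da; average ", format(round(average_mass(x), 2), nsmall = 2),
      " Da\n", sep = "")
  invisible(x)
}

format_peptide <- function(p) {
  seq_chars <- strsplit(p$sequence, "")[[1]]
  if (nrow(p$mods) > 0) {
    for (i in seq_len(nrow(p$mods))) {
      pos <- p$mods$position[i]
      seq_chars[pos] <- paste0(seq_chars[pos], "(", p$mods$label[i], ")")
    }
  }
  body <- paste(seq_chars, collapse = "")
  nt <- if (p$n_term == "succinyl") "Suc-" else ""
  ct <- if (p$c_term == "pna") "-pNA" else ""
  paste0(nt, body, ct)
}

#' Parse a peptide spec string
#'
#' Accepts strings of the form `"Suc-AHPF-pNA"` (dash-separated terminal
#' group labels) with optional inline residue modifications such as
#' `"VYEAGM(ox)K"` or `"Suc-AH(ph)PF-pNA"`. Recognized terminal labels:
#' `Suc`/`H` (N-terminal), `pNA`/`OH` (C-terminal); absent labels mean
#' free termini.
#'
#' @param spec the peptide string.
#' @inheritParams peptide
#' @return a `"peptide"` object.
#' @export
parse_peptide <- function(spec, mod_table = modification_table()) {
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  n_term <- "free"
  c_term <- "free"
  if (length(parts) > 1 && parts[1] %in% names(.n_term_aliases)) {
    n_term <- .n_term_aliases[[parts[1]]]
    parts <- parts[-1]
  }
  if (length(parts) > 1 &&
      parts[length(parts)] %in% names(.c_term_aliases)) {
    c_term <- .c_term_aliases[[parts[length(parts)]]]
    parts <- parts[-length(parts)]
  }
  if (length(parts) != 1) {
    rlang::abort(paste0("Cannot parse peptide spec: '", spec, "'"))
  }
  body <- parts[1]
  # peel off inline mods: residue letter optionally followed by (label)
  seq_chars <- character()
  mods <- list()
  i <- 1
  while (i <= nchar(body)) {
    ch <- substr(body, i, i)
    seq_chars <- c(seq_chars, ch)
    i <- i + 1
    if (i <= nchar(body) && substr(body, i, i) == "(") {
      close <- regexpr(")", substr(body, i, nchar(body)), fixed = TRUE)
      if (close < 0) rlang::abort("Unclosed '(' in peptide spec")
      label <- substr(body, i + 1, i + close - 2)
      mods[[length(mods) + 1]] <-
        list(position = length(seq_chars), label = label)
      i <- i + close
    }
  }
  mods <- if (length(mods) > 0) {
    tibble::tibble(
      position = vapply(mods, `[[`, integer(1), "position"),
      label = vapply(mods, `[[`, character(1), "label")
    )
  } else NULL
  peptide(paste(seq_chars, collapse = ""), n_term = n_term,
          c_term = c_term, mods = mods, mod_table = mod_table)
}

# elemental composition of the whole (neutral) peptide
peptide_composition <- function(p, mod_table = modification_table()) {
  comp <- .water_comp
  for (ch in strsplit(p$sequence, "")[[1]]) {
    comp <- comp_add(comp, .residue_comp[[ch]])
  }
  comp <- comp_add(comp, .n_term_groups[[p$n_term]])
  comp <- comp_add(comp, .c_term_groups[[p$c_term]])
  if (nrow(p$mods) > 0) {
    for (label in p$mods$label) {
      comp <- comp_add(comp, parse_formula(mod_lookup(label, mod_table)$formula))
    }
  }
  comp
}

#' Peptide masses
#'
#' `monoisotopic_mass()` sums residue monoisotopic masses plus water and
#' any terminal-group and modification deltas; `average_mass()` uses
#' isotope-abundance-weighted standard atomic weights on the same
#' elemental composition.
#'
#' @param p a `"peptide"`.
#' @inheritParams peptide
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_peptide("Suc-AHPF-pNA"))  # 690.2762
#' average_mass(parse_peptide("Suc-AHPF-pNA"))       # 690.70
#' @export
monoisotopic_mass <- function(p, mod_table = modification_table()) {
  comp_mass(peptide_composition(p, mod_table), "monoisotopic")
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(p, mod_table = modification_table()) {
  comp_mass(peptide_composition(p, mod_table), "average")
}

#' Add or remove a residue modification
#'
#' Mass additivity holds exactly: the modified peptide's mass equals the
#' input mass plus the modification delta.
#'
#' @param p a `"peptide"`.
#' @param label modification label from the modification table.
#' @param position 1-based residue index.
#' @inheritParams peptide
#' @return a new `"peptide"`.
#' @examples
#' ph <- apply_modification(parse_peptide("Suc-AHPF-pNA"), "ph", 2)
#' adduct_mz(ph, "H")  # 771.2498
#' @export
apply_modification <- function(p, label, position,
                               mod_table = modification_table()) {
  mods <- dplyr::bind_rows(
    p$mods,
    tibble::tibble(position = as.integer(position), label = label)
  )
  peptide(p$sequence, p$n_term, p$c_term, mods, mod_table)
}

#' @rdname apply_modification
#' @export
remove_modification <- function(p, label, position,
                                mod_table = modification_table()) {
  keep <- !(p$mods$position == position & p$mods$label == label)
  if (all(keep)) {
    rlang::abort(paste0("No modification '", label, "' at position ",
                        position, " to remove"))
  }
  peptide(p$sequence, p$n_term, p$c_term, p$mods[keep, ], mod_table)
}

#' Adduct m/z of a peptide ion
#'
#' m/z of `[M + n cation]^n+` for H+, Na+ or K+ adducts, optionally
#' shifted to a heavy-isotope peak. The cation mass is the neutral atom
#' minus one electron; the A+k peak sits `k * 1.00336 / z` above the
#' monoisotopic peak.
#'
#' @param p a `"peptide"`.
#' @param adduct `"H"`, `"Na"` or `"K"`.
#' @param charge positive integer number of adduct cations.
#' @param isotope_index 0 for monoisotopic, 1 for A+1, etc.
#' @inheritParams peptide
#' @return m/z value.
#' @export
adduct_mz <- function(p, adduct = "H", charge = 1L, isotope_index = 0L,
                      mod_table = modification_table()) {
  if (!adduct %in% names(.cation_mass)) {
    rlang::abort(paste0("Unknown adduct: '", adduct, "'"))
  }
  stopifnot(charge >= 1, isotope_index >= 0)
  m <- monoisotopic_mass(p, mod_table)
  (m + charge * .cation_mass[[adduct]]) / charge +
    isotope_index * .a1_spacing / charge
}

#' Nominal (integer-rounded) m/z
#'
#' @inheritParams adduct_mz
#' @return integer m/z as printed on unit-resolution peak labels.
#' @export
nominal_mz <- function(p, adduct = "H", charge = 1L,
                       mod_table = modification_table()) {
  round(adduct_mz(p, adduct, charge, 0L, mod_table))
}

#' Target m/z list for XIC extraction
#'
#' Convenience wrapper returning the monoisotopic and heavy-isotope m/z
#' of one ion species, the default target set for XIC reconstruction.
#'
#' @inheritParams adduct_mz
#' @param isotopes integer vector of isotope indices (default 0:1,
#'   monoisotopic and A+1).
#' @return numeric vector of m/z values.
#' @export
species_mz <- function(p, adduct = "H", charge = 1L, isotopes = 0:1,
                       mod_table = modification_table()) {
  vapply(isotopes, function(k) adduct_mz(p, adduct, charge, k, mod_table),
         numeric(1))
}
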
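# b/y fragment ions with neutral losses, and in-silico tryptic digestion.

.loss_formulas <- c(
  "CH4SO"     = "CH4SO",    # methanesulfenic acid, from oxidized Met
  "HPO3"      = "HPO3",     # metaphosphate, from phospho residues
  "H3PO4"     = "H3PO4",    # phosphoric acid
  "H3PO4+H2O" = "H5PO5"     # phosphoric acid plus water
)

.loss_requires <- list(
  "CH4SO"     = function(labels) "ox" %in% labels,
  "HPO3"      = function(labels) "ph" %in% labels,
  "H3PO4"     = function(labels) "ph" %in% labels,
  "H3PO4+H2O" = function(labels) "ph" %in% labels
)

#' Fragment ions of a peptide
#'
#' Singly charged b- and y-type ions for every amide-bond cleavage, plus
#' the protonated precursor. When neutral-loss labels are requested,
#' each ion that carries the triggering modification gains a companion
#' peak: `"CH4SO"` (-63.99829 Da, methanesulfenic acid from oxidized
#' methionine, the diagnostic -64 loss) for ions containing an
#' oxidized Met, and `"HPO3"` (-79.96633), `"H3PO4"` (-97.97690) and
#' `"H3PO4+H2O"` (-115.98746) for ions containing a phospho residue
#' (acid-labile phosphohistidine fragments readily via these losses).
#'
#' @param p a `"peptide"`.
#' @param series ion series to generate, subset of `c("b", "y")`.
#' @param losses character vector of neutral-loss labels (may be empty):
#'   `"CH4SO"`, `"HPO3"`, `"H3PO4"`, `"H3PO4+H2O"`.
#' @param include_precursor also report the `[M+H]+` precursor (and its
#'   loss companions) as series `"M"`.
#' @inheritParams peptide
#' @return tibble with columns `ion` (e.g. `"b2"`, `"y3-H3PO4"`),
#'   `series`, `index`, `loss` (`NA` for the intact ion) and `mz`.
#' @examples
#' fragment_ions(parse_peptide("VYEAGM(ox)K"), losses = "CH4SO")
#' @export
fragment_ions <- function(p, series = c("b", "y"), losses = character(),
                          include_precursor = TRUE,
                          mod_table = modification_table()) {
  n <- nchar(p$sequence)
  if (n == 0) rlang::abort("Cannot fragment an empty peptide")
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  bad <- setdiff(losses, names(.loss_formulas))
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown neutral-loss label(s): ",
                        paste(bad, collapse = ", ")))
  }
  chars <- strsplit(p$sequence, "")[[1]]
  res_mono <- vapply(chars, function(ch) {
    comp_mass(.residue_comp[[ch]], "monoisotopic")
  }, numeric(1))
  mod_delta <- numeric(n)
  mod_labels <- vector("list", n)
  if (nrow(p$mods) > 0) {
    for (i in seq_len(nrow(p$mods))) {
      pos <- p$mods$position[i]
      lab <- p$mods$label[i]
      mod_delta[pos] <- mod_delta[pos] +
        mod_lookup(lab, mod_table)$mono_delta
      mod_labels[[pos]] <- c(mod_labels[[pos]], lab)
    }
  }
  res_mass <- unname(res_mono + mod_delta)
  nterm <- comp_mass(.n_term_groups[[p$n_term]], "monoisotopic")
  cterm <- comp_mass(.c_term_groups[[p$c_term]], "monoisotopic")
  water <- comp_mass(.water_comp, "monoisotopic")

  rows <- list()
  emit <- function(series, index, mz, labels_in_ion) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      ion = paste0(series, if (series != "M") index else ""),
      series = series, index = index, loss = NA_character_, mz = mz)
    for (loss in losses) {
      if (.loss_requires[[loss]](labels_in_ion)) {
        rows[[length(rows) + 1]] <<- tibble::tibble(
          ion = paste0(series, if (series != "M") index else "", "-", loss),
          series = series, index = index, loss = loss,
          mz = mz - comp_mass(parse_formula(.loss_formulas[[loss]]),
                              "monoisotopic"))
      }
    }
  }

  if ("b" %in% series) {
    cum <- cumsum(res_mass)
    for (i in seq_len(n - 1)) {
      emit("b", i, cum[i] + nterm + .proton_mass,
           unlist(mod_labels[seq_len(i)]))
    }
  }
  if ("y" %in% series) {
    cum_rev <- rev(cumsum(rev(res_mass)))
    for (j in seq_len(n - 1)) {
      first <- n - j + 1
      emit("y", j, cum_rev[first] + water + cterm + .proton_mass,
           unlist(mod_labels[first:n]))
    }
  }
  if (include_precursor) {
    emit("M", n, sum(res_mass) + water + nterm + cterm + .proton_mass,
         unlist(mod_labels))
  }
  dplyr::bind_rows(rows)
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine or arginine except when the next residue is
#' proline, the standard trypsin convention. Peptides with up to
#' `max_missed` missed cleavages are reported with their 1-based span in
#' the protein.
#'
#' @param sequence protein sequence (one-letter string).
#' @param max_missed maximum number of missed cleavages (>= 0).
#' @return tibble with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`, ordered by `start` then `missed_cleavages`.
#' @examples
#' tryptic_digest("AKRGPCK", max_missed = 1)
#' @export
tryptic_digest <- function(sequence, max_missed = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1, max_missed >= 0)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0) {
    return(tibble::tibble(peptide = character(), start = integer(),
                          end = integer(), missed_cleavages = integer()))
  }
  chars <- strsplit(sequence, "")[[1]]
  # cut after position i if chars[i] is K/R and chars[i+1] is not P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts == n | chars[pmin(cuts + 1, n)] != "P"]
  bounds <- c(0L, cuts, if (n %in% cuts) NULL else n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  out <- list()
  n_pep <- length(starts)
  for (m in 0:max_missed) {
    idx <- seq_len(n_pep - m)
    if (length(idx) == 0 || n_pep - m < 1) break
    out[[m + 1]] <- tibble::tibble(
      peptide = substring(sequence, starts[idx], ends[idx + m]),
      start = as.integer(starts[idx]),
      end = as.integer(ends[idx + m]),
      missed_cleavages = as.integer(m)
    )
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$start, .data$missed_cleavages)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readAAStringSet()` returning a tidy
#' table suitable for piping into [tryptic_digest()].
#'
#' @param path FASTA file path.
#' @return tibble with columns `name` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("read_protein_fasta() requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(name = names(aa), sequence = as.character(aa))
}
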
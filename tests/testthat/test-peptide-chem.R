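# Deterministic peptide chemistry: masses, modifications, adducts,
# fragments, digestion.

test_that("monoisotopic and average masses match atomic-composition references", {
  suc <- parse_peptide("Suc-AHPF-pNA")
  expect_equal(monoisotopic_mass(suc), 690.27617, tolerance = 1e-7)
  expect_equal(round(average_mass(suc), 1), 690.7)

  # free-termini peptide, frozen from an elemental-composition oracle
  expect_equal(monoisotopic_mass(peptide("AHPF")), 470.22777,
               tolerance = 1e-7)
  # zero-residue limit: water
  expect_equal(monoisotopic_mass(peptide("")), 18.010565, tolerance = 1e-6)
  expect_equal(average_mass(peptide("")), 18.0153, tolerance = 1e-4)
  # glycine free acid from average atomic masses (C2H5NO2)
  expect_equal(round(average_mass(peptide("G")), 2), 75.07)
})

test_that("unknown residues, mods and adducts raise informative errors", {
  expect_error(peptide("AXZ"), "X")
  expect_error(apply_modification(peptide("AHPF"), "nosuchmod", 1),
               "nosuchmod")
  expect_error(apply_modification(peptide("AHPF"), "ph", 1), "not allowed")
  expect_error(apply_modification(peptide("AHPF"), "ph", 9),
               "position")
  expect_error(adduct_mz(peptide("AHPF"), "Li"), "adduct")
})

test_that("modification deltas are additive and invertible", {
  tab <- modification_table()
  base <- parse_peptide("Suc-AHPF-pNA")
  m0 <- monoisotopic_mass(base)
  ph <- apply_modification(base, "ph", 2)
  expect_equal(monoisotopic_mass(ph), m0 + 79.96633, tolerance = 1e-5)
  back <- remove_modification(ph, "ph", 2)
  expect_equal(monoisotopic_mass(back), m0, tolerance = 1e-10)

  met <- peptide("AMK")
  expect_equal(monoisotopic_mass(apply_modification(met, "ox", 2)) -
                 monoisotopic_mass(met), 15.99491, tolerance = 1e-5)

  # additivity over several mods at once
  multi <- parse_peptide("Suc-AH(ph)PF-pNA")
  expect_equal(monoisotopic_mass(multi), m0 + 79.96633, tolerance = 1e-5)

  # one oxidation state per residue
  expect_error(apply_modification(apply_modification(met, "ox", 2),
                                  "diox", 2), "oxidation")
})

test_that("adduct m/z reproduces the six-peak set and isotope spacing", {
  non <- parse_peptide("Suc-AHPF-pNA")
  ph <- apply_modification(non, "ph", 2)
  expect_equal(round(adduct_mz(ph, "H"), 1), 771.2)
  expect_equal(vapply(c("H", "Na", "K"), function(a) nominal_mz(ph, a),
                      numeric(1)),
               c(H = 771, Na = 793, K = 809))
  expect_equal(vapply(c("H", "Na", "K"), function(a) nominal_mz(non, a),
                      numeric(1)),
               c(H = 691, Na = 713, K = 729))
  # A+1 spacing at z = 1 and z = 2
  expect_equal(adduct_mz(ph, "H", 1, 1) - adduct_mz(ph, "H", 1, 0), 1.00336)
  expect_equal(adduct_mz(ph, "H", 2, 1) - adduct_mz(ph, "H", 2, 0),
               1.00336 / 2)
})

test_that("adduct ordering follows cation masses", {
  for (spec in c("AHPF", "VYEAGMK", "Suc-AHPF-pNA")) {
    p <- parse_peptide(spec)
    mzs <- vapply(c("H", "Na", "K"), function(a) adduct_mz(p, a), numeric(1))
    expect_true(mzs[["K"]] > mzs[["Na"]] && mzs[["Na"]] > mzs[["H"]])
    expect_equal(mzs[["Na"]] - mzs[["H"]], 22.98922070 - 1.00727647,
                 tolerance = 1e-4)
    expect_equal(mzs[["K"]] - mzs[["Na"]], 38.96315791 - 22.98922070,
                 tolerance = 1e-4)
  }
})

test_that("monoisotopic mass never exceeds average mass for CHNOS peptides", {
  for (spec in c("G", "AHPF", "VYEAGMK", "WCTNQ", "Suc-AHPF-pNA")) {
    p <- parse_peptide(spec)
    expect_lt(monoisotopic_mass(p), average_mass(p))
  }
})

test_that("b/y complementarity holds at every cleavage position", {
  peps <- list(parse_peptide("VYEAGMK"),
               parse_peptide("Suc-AH(ph)PF-pNA"),
               parse_peptide("VYEAGM(ox)K"))
  for (p in peps) {
    fr <- fragment_ions(p, include_precursor = FALSE)
    intact <- fr[is.na(fr$loss), ]
    n <- nchar(p$sequence)
    prec <- monoisotopic_mass(p)
    for (i in seq_len(n - 1)) {
      b <- intact$mz[intact$series == "b" & intact$index == i]
      y <- intact$mz[intact$series == "y" & intact$index == n - i]
      expect_equal(b + y - 1.00727647, prec + 1.00727647, tolerance = 1e-5)
    }
  }
})

test_that("neutral-loss companions appear only on ions carrying the mod", {
  p <- parse_peptide("VYEAGM(ox)K")  # ox-Met at position 6 of 7
  fr <- fragment_ions(p, losses = "CH4SO", include_precursor = TRUE)
  with_loss <- fr[!is.na(fr$loss), ]
  # b1..b5 lack the Met; y2..y6 and b6 contain it
  expect_false(any(with_loss$series == "b" & with_loss$index < 6))
  expect_true(all(c("b6-CH4SO", "y2-CH4SO", "M-CH4SO") %in% with_loss$ion))
  # loss magnitude rounds to the diagnostic -64 Da
  b6 <- fr$mz[fr$ion == "b6"]
  expect_equal(b6 - fr$mz[fr$ion == "b6-CH4SO"], 63.99829, tolerance = 1e-5)

  ph <- parse_peptide("Suc-AH(ph)PF-pNA")
  frp <- fragment_ions(ph, losses = c("HPO3", "H3PO4", "H3PO4+H2O"))
  m <- frp[frp$series == "M", ]
  mh <- m$mz[is.na(m$loss)]
  expect_equal(round(mh - m$mz[!is.na(m$loss)]),
               c(80, 98, 116), ignore_attr = TRUE)
})

test_that("tryptic digestion matches a brute-force rule oracle", {
  cases <- list(
    list(seq = "AKRGPC", m = 0),
    list(seq = "AKRGPC", m = 2),
    list(seq = "MKWVTFISLLLLFSSAYSRGVFRRDTHK", m = 1),
    list(seq = "KRPKPK", m = 2)
  )
  for (cs in cases) {
    got <- as.data.frame(tryptic_digest(cs$seq, cs$m))
    want <- oracle_digest(cs$seq, cs$m)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # no cleavage sites: whole sequence back
  expect_equal(tryptic_digest("AGHPF", 0)$peptide, "AGHPF")
  # 0-missed-cleavage peptides partition the protein
  for (seqs in c("AKRGPC", "MKWVTFISLLLLFSSAYSRGVFRRDTHK")) {
    d0 <- tryptic_digest(seqs, 0)
    expect_equal(paste(d0$peptide, collapse = ""), seqs)
    expect_equal(d0$start[-1], utils::head(d0$end, -1) + 1)
  }
})

test_that("peptide spec strings round-trip through the parser", {
  p <- parse_peptide("Suc-AH(ph)PF-pNA")
  expect_equal(p$n_term, "succinyl")
  expect_equal(p$c_term, "pna")
  expect_equal(p$mods$position, 2L)
  expect_equal(oxiquant:::format_peptide(p), "Suc-AH(ph)PF-pNA")
  expect_error(parse_peptide("Suc-AH(phPF-pNA"), "Unclosed")
})
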
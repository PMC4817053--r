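# Synthetic-data generators.
#
# Every generator takes a config list built by a *_sim_config()
# constructor plus a seed, and returns both the simulated dataset and a
# ground-truth table sufficient to compute the expected value of every
# downstream statistic. Identical seeds give bit-identical output.

#' Configuration for the LC-MS oxidation-pair simulator
#'
#' Describes paired oxidized / non-oxidized ion species of one tryptic
#' peptide eluting as Gaussian chromatographic peaks. The defaults model
#' a doubly protonated Met-containing tryptic peptide observed on a
#' high-resolution instrument: narrow peaks, ppm-level mass error, mild
#' multiplicative intensity noise and a low background of spurious
#' centroids.
#'
#' @param peptide peptide spec string for the non-oxidized form; must
#'   contain the residue named by `ox_position`.
#' @param ox_position 1-based position of the methionine that carries
#'   the mono-oxidation in the oxidized form.
#' @param charge charge state (H+ adducts) of both species.
#' @param base_abundance apex intensity of the non-oxidized species.
#' @param elution_center_nonox,elution_center_ox peak apexes (min); the
#'   sulfoxide elutes earlier on reversed phase, hence the offset.
#' @param elution_width Gaussian peak sigma (min).
#' @param a1_fraction intensity of the A+1 peak relative to the
#'   monoisotopic peak; `NULL` estimates it from the carbon count
#'   (about 1.08% per carbon).
#' @param ppm_error_sd per-centroid m/z jitter (ppm).
#' @param noise_cv multiplicative intensity noise (coefficient of
#'   variation).
#' @param noise_floor mean intensity of background centroids; 0 disables
#'   the background.
#' @param n_background background centroids per scan.
#' @param scan_interval time between scans (s).
#' @param run_length run duration (min).
#' @param replicates replicate runs per group.
#' @return a config list for [simulate_lcms_oxidation()].
#' @export
lcms_sim_config <- function(peptide = "VYEAGMK", ox_position = 6L,
                            charge = 2L, base_abundance = 1e6,
                            elution_center_nonox = 2.4,
                            elution_center_ox = 1.6,
                            elution_width = 0.12,
                            a1_fraction = NULL,
                            ppm_error_sd = 1.5, noise_cv = 0.05,
                            noise_floor = 50, n_background = 5L,
                            scan_interval = 1, run_length = 4,
                            replicates = 3L) {
  stopifnot(elution_width > 0, replicates >= 1, ppm_error_sd >= 0,
            scan_interval > 0, run_length > 0)
  nonox <- parse_peptide(peptide)
  ox <- apply_modification(nonox, "ox", ox_position)
  if (is.null(a1_fraction)) {
    n_c <- peptide_composition(nonox)[["C"]]
    a1_fraction <- n_c * 0.0108
  }
  list(
    nonox = nonox, ox = ox, charge = charge,
    base_abundance = base_abundance,
    elution_center_nonox = elution_center_nonox,
    elution_center_ox = elution_center_ox,
    elution_width = elution_width,
    a1_fraction = a1_fraction,
    ppm_error_sd = ppm_error_sd, noise_cv = noise_cv,
    noise_floor = noise_floor, n_background = n_background,
    scan_interval = scan_interval, run_length = run_length,
    replicates = replicates
  )
}

#' Simulate paired oxidized/non-oxidized LC-MS runs
#'
#' For each treatment group, generates `config$replicates` runs in which
#' the oxidized and non-oxidized species of one peptide elute as
#' Gaussian peaks. The oxidized : non-oxidized abundance odds of each
#' group are set by `ox_odds`, so the ground-truth XIC AUC ratio of
#' every replicate is exactly its group's odds (noise aside). Both
#' species contribute their monoisotopic and A+1 centroids with m/z
#' jittered by `N(0, ppm_error_sd)`.
#'
#' @param ox_odds named numeric vector, group label -> oxidized :
#'   non-oxidized abundance odds (>= 0). The first element is
#'   conventionally the control group.
#' @param config from [lcms_sim_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with elements
#'   * `runs`: tibble `group`, `replicate`, `scan_time`, `mz`,
#'     `intensity`;
#'   * `truth`: tibble `group`, `replicate`, `odds` (the exact injected
#'     AUC ratio), plus `overlap_warning` if any oxidized target m/z
#'     falls within 3x the 5 ppm tolerance of a non-oxidized target;
#'   * `species`: tibble of target m/z values per species.
#' @export
simulate_lcms_oxidation <- function(ox_odds, config = lcms_sim_config(),
                                    seed = 1L) {
  stopifnot(all(ox_odds >= 0), !is.null(names(ox_odds)))
  withr::with_seed(seed, {
    mz_nonox <- species_mz(config$nonox, "H", config$charge)
    mz_ox <- species_mz(config$ox, "H", config$charge)
    sep_ppm <- min(abs(outer(mz_ox, mz_nonox, "-"))) /
      mean(c(mz_ox, mz_nonox)) * 1e6
    overlap <- sep_ppm < 3 * 5
    times <- seq(0, config$run_length, by = config$scan_interval / 60)
    iso_w <- c(1, config$a1_fraction)
    mz_range <- range(c(mz_ox, mz_nonox)) + c(-2, 2)

    one_run <- function(group, replicate, odds) {
      shape_nonox <- exp(-(times - config$elution_center_nonox)^2 /
                           (2 * config$elution_width^2))
      shape_ox <- exp(-(times - config$elution_center_ox)^2 /
                        (2 * config$elution_width^2))
      species <- list(
        list(mz = mz_nonox, amp = config$base_abundance, shape = shape_nonox),
        list(mz = mz_ox, amp = config$base_abundance * odds, shape = shape_ox)
      )
      rows <- lapply(species, function(sp) {
        grid <- expand.grid(t = seq_along(times), k = seq_along(sp$mz))
        inten <- sp$amp * sp$shape[grid$t] * iso_w[grid$k]
        inten <- inten * pmax(0, 1 + stats::rnorm(length(inten),
                                                  sd = config$noise_cv))
        mz <- sp$mz[grid$k] *
          (1 + stats::rnorm(length(inten), sd = config$ppm_error_sd * 1e-6))
        keep <- inten > config$noise_floor
        tibble::tibble(scan_time = times[grid$t][keep], mz = mz[keep],
                       intensity = inten[keep])
      })
      if (config$noise_floor > 0 && config$n_background > 0) {
        nbg <- config$n_background * length(times)
        rows <- c(rows, list(tibble::tibble(
          scan_time = rep(times, each = config$n_background),
          mz = stats::runif(nbg, mz_range[1], mz_range[2]),
          intensity = abs(stats::rnorm(nbg, sd = config$noise_floor))
        )))
      }
      out <- dplyr::bind_rows(rows)
      out$group <- group
      out$replicate <- replicate
      out[c("group", "replicate", "scan_time", "mz", "intensity")]
    }

    runs <- list()
    truth <- list()
    for (g in names(ox_odds)) {
      for (r in seq_len(config$replicates)) {
        runs[[length(runs) + 1]] <- one_run(g, r, ox_odds[[g]])
        truth[[length(truth) + 1]] <- tibble::tibble(
          group = g, replicate = r, odds = ox_odds[[g]],
          overlap_warning = overlap)
      }
    }
    list(
      runs = dplyr::bind_rows(runs),
      truth = dplyr::bind_rows(truth),
      species = tibble::tibble(
        species = rep(c("nonoxidized", "oxidized"), each = 2),
        isotope = rep(0:1, 2),
        mz = c(mz_nonox, mz_ox))
    )
  })
}

#' Configuration for the direct-infusion dephosphorylation simulator
#'
#' Models the six-peak direct-infusion assay: the phosphopeptide and its
#' dephosphorylated product each observed as H+, Na+ and K+ adducts
#' (nominal m/z 771/793/809 and 691/713/729 for the
#' succinyl-Ala-His-Pro-Phe-p-nitroanilide substrate). With substrate in
#' vast excess over enzyme the conversion is pseudo-first-order, so the
#' phosphorylated fraction decays as `f(t) = f0 * exp(-k * t)`;
#' dephosphorylation converts phospho intensity into non-phospho
#' intensity, never destroys it. An optional in-source phosphate loss
#' transfers a fixed fraction of phospho signal to the product peaks in
#' every scan, and optional per-adduct rate multipliers let the sodium
#' and potassium adducts convert more slowly than the protonated form.
#'
#' @param initial_phospho_fraction phosphorylated fraction at t = 0
#'   (default 0.375, the midpoint of the 35-40% yield of aqueous
#'   phosphoramidate synthesis).
#' @param k_dephos first-order dephosphorylation rate (per minute).
#' @param adduct_fractions named fractions for H, Na, K summing to 1.
#' @param adduct_rate_multiplier named per-adduct multipliers on
#'   `k_dephos` (all 1 = equal conversion).
#' @param source_loss_fraction fraction of phospho-peak intensity moved
#'   to the product peaks by in-source phosphate loss (0..1).
#' @param total_intensity summed six-peak intensity per scan.
#' @param duration infusion length (min).
#' @param scan_interval time between scans (s).
#' @param noise_cv multiplicative intensity noise (0 = noise free).
#' @param peptide substrate spec string; phospho form is built by
#'   phosphorylating `phospho_position`.
#' @param phospho_position 1-based index of the phosphohistidine.
#' @return a config list for [simulate_infusion_timecourse()].
#' @export
infusion_sim_config <- function(initial_phospho_fraction = 0.375,
                                k_dephos = log(100) / 10,
                                adduct_fractions = c(H = 0.5, Na = 0.3, K = 0.2),
                                adduct_rate_multiplier = c(H = 1, Na = 1, K = 1),
                                source_loss_fraction = 0,
                                total_intensity = 1e6,
                                duration = 30, scan_interval = 10,
                                noise_cv = 0,
                                peptide = "Suc-AHPF-pNA",
                                phospho_position = 2L) {
  stopifnot(initial_phospho_fraction >= 0, initial_phospho_fraction <= 1,
            k_dephos >= 0, source_loss_fraction >= 0,
            source_loss_fraction <= 1,
            abs(sum(adduct_fractions) - 1) < 1e-9,
            all(sort(names(adduct_fractions)) == c("H", "K", "Na")))
  nonphos <- parse_peptide(peptide)
  phos <- apply_modification(nonphos, "ph", phospho_position)
  list(
    f0 = initial_phospho_fraction, k = k_dephos,
    adduct_fractions = adduct_fractions,
    adduct_rate_multiplier = adduct_rate_multiplier,
    source_loss = source_loss_fraction,
    total_intensity = total_intensity,
    duration = duration, scan_interval = scan_interval,
    noise_cv = noise_cv, nonphos = nonphos, phos = phos
  )
}

#' Simulate a direct-infusion dephosphorylation time course
#'
#' @param config from [infusion_sim_config()].
#' @param seed integer seed (only consumed when `noise_cv > 0`).
#' @return list with elements
#'   * `spectra`: tibble `scan_time`, `mz`, `intensity` with six peaks
#'     per scan;
#'   * `truth`: tibble `scan_time`, `phospho_fraction` (the true
#'     chemical fraction) and `measured_fraction_expected` (expectation
#'     of the intensity-based estimate, biased low by the in-source
#'     loss);
#'   * `species`: tibble mapping each peak m/z to adduct and phospho
#'     state.
#' @export
simulate_infusion_timecourse <- function(config = infusion_sim_config(),
                                         seed = 1L) {
  withr::with_seed(seed, {
    adducts <- c("H", "Na", "K")
    mz_phos <- vapply(adducts, function(a) adduct_mz(config$phos, a),
                      numeric(1))
    mz_non <- vapply(adducts, function(a) adduct_mz(config$nonphos, a),
                     numeric(1))
    times <- seq(0, config$duration, by = config$scan_interval / 60)
    rows <- vector("list", length(times))
    truth_f <- numeric(length(times))
    truth_meas <- numeric(length(times))
    for (i in seq_along(times)) {
      t <- times[i]
      f_a <- config$f0 *
        exp(-config$k * config$adduct_rate_multiplier[adducts] * t)
      int_phos_chem <- config$total_intensity *
        config$adduct_fractions[adducts] * f_a
      int_non_chem <- config$total_intensity *
        config$adduct_fractions[adducts] * (1 - f_a)
      # in-source phosphate loss: intensity moves phospho -> product
      int_phos <- int_phos_chem * (1 - config$source_loss)
      int_non <- int_non_chem + int_phos_chem * config$source_loss
      inten <- c(int_phos, int_non)
      if (config$noise_cv > 0) {
        inten <- inten * pmax(0, 1 + stats::rnorm(length(inten),
                                                  sd = config$noise_cv))
      }
      rows[[i]] <- tibble::tibble(
        scan_time = t, mz = unname(c(mz_phos, mz_non)),
        intensity = unname(inten))
      truth_f[i] <- sum(config$adduct_fractions[adducts] * f_a)
      truth_meas[i] <- sum(int_phos) / (sum(int_phos) + sum(int_non))
    }
    list(
      spectra = dplyr::bind_rows(rows),
      truth = tibble::tibble(scan_time = times,
                             phospho_fraction = truth_f,
                             measured_fraction_expected = truth_meas),
      species = tibble::tibble(
        mz = unname(c(mz_phos, mz_non)),
        adduct = rep(adducts, 2),
        phospho = rep(c(TRUE, FALSE), each = 3))
    )
  })
}

#' Helical reference coordinates for synthetic ensembles
#'
#' Deterministic per-residue reference positions laid out on a coarse
#' helix (radius 8 angstrom, rise 1.5 angstrom per residue), a compact
#' protein-like arrangement for superposition tests.
#'
#' @param n_residues number of residues.
#' @return an `n_residues` x 3 matrix (angstrom).
#' @export
reference_coordinates <- function(n_residues = 125L) {
  i <- seq_len(n_residues)
  cbind(x = 8 * cos(i / 2), y = 8 * sin(i / 2), z = 1.5 * i)
}

#' Configuration for the conformational-ensemble simulator
#'
#' Two ensembles of per-residue coordinates drawn from isotropic
#' Gaussian clouds around a reference structure; ensemble B's residue
#' means are displaced by a configured shift. This stands in for MD
#' ensembles: frames are independent draws, not dynamics.
#'
#' @param n_residues residues per frame (default 125, a PHPT1-sized
#'   chain).
#' @param n_frames frames per ensemble (default 3001, a 150 ns
#'   trajectory sampled every 50 ps, endpoints inclusive).
#' @param reference `n_residues` x 3 matrix of reference coordinates.
#' @param shift `n_residues` x 3 matrix of mean displacements applied to
#'   ensemble B (angstrom); default all zero.
#' @param sd per-residue isotropic coordinate SD (scalar or length
#'   `n_residues`), default 1 angstrom.
#' @param frame_interval_ps time between frames (ps).
#' @return a config list for [simulate_ensembles()].
#' @export
ensemble_sim_config <- function(n_residues = 125L, n_frames = 3001L,
                                reference = reference_coordinates(n_residues),
                                shift = NULL, sd = 1,
                                frame_interval_ps = 50) {
  stopifnot(n_frames >= 2, all(sd > 0),
            nrow(reference) == n_residues, ncol(reference) == 3)
  if (is.null(shift)) shift <- matrix(0, n_residues, 3)
  stopifnot(nrow(shift) == n_residues, ncol(shift) == 3)
  sd <- rep_len(sd, n_residues)
  list(n_residues = n_residues, n_frames = n_frames,
       reference = reference, shift = shift, sd = sd,
       frame_interval_ps = frame_interval_ps)
}

#' Simulate a pair of conformational ensembles
#'
#' @param config from [ensemble_sim_config()].
#' @param seed integer seed.
#' @return list with `a` and `b` (class `"ensemble"`) and `truth`, a
#'   tibble of the exact per-residue center-of-mass separation between
#'   the two generating distributions.
#' @export
simulate_ensembles <- function(config = ensemble_sim_config(), seed = 1L) {
  withr::with_seed(seed, {
    draw <- function(means) {
      coords <- array(0, c(config$n_frames, config$n_residues, 3))
      for (r in seq_len(config$n_residues)) {
        coords[, r, ] <- matrix(
          stats::rnorm(config$n_frames * 3, sd = config$sd[r]),
          config$n_frames, 3)
        coords[, r, ] <- sweep(coords[, r, ], 2, means[r, ], "+")
      }
      coords
    }
    a <- new_ensemble(draw(config$reference),
                      frame_interval_ps = config$frame_interval_ps)
    b <- new_ensemble(draw(config$reference + config$shift),
                      frame_interval_ps = config$frame_interval_ps)
    list(a = a, b = b,
         truth = tibble::tibble(
           residue = seq_len(config$n_residues),
           com_separation = sqrt(rowSums(config$shift^2))))
  })
}

#' Configuration for the colorimetric pNPP progress-curve simulator
#'
#' Michaelis-Menten product formation with substrate depletion,
#' converted to 405 nm absorbance through the Beer-Lambert contract of
#' the kinetics module (p-nitrophenolate, epsilon = 17.8 per mM per cm;
#' path length from well geometry).
#'
#' @param Km Michaelis constant (mM).
#' @param Vmax maximal velocity (mM/min).
#' @param E0 enzyme concentration (micromolar), default 2.1.
#' @param substrate_mM substrate concentration series (mM), default five
#'   levels spanning 0.8-40 mM pNPP.
#' @param duration assay length (min), default 120 (2 h).
#' @param sample_interval read interval (min), default 3.
#' @param noise_sd Gaussian absorbance noise SD (AU).
#' @param beer [beer_lambert_config()] used for the conversion.
#' @param dt integration step (min).
#' @return a config list for [simulate_pnpp_progress()].
#' @export
pnpp_sim_config <- function(Km = 5, Vmax = 0.01, E0 = 2.1,
                            substrate_mM = c(0.8, 2, 5, 15, 40),
                            duration = 120, sample_interval = 3,
                            noise_sd = 0.005,
                            beer = beer_lambert_config(), dt = 0.01) {
  stopifnot(Km > 0, Vmax >= 0, E0 > 0, length(substrate_mM) > 0)
  list(Km = Km, Vmax = Vmax, E0 = E0, substrate_mM = substrate_mM,
       duration = duration, sample_interval = sample_interval,
       noise_sd = noise_sd, beer = beer, dt = dt)
}

#' Simulate pNPP absorbance progress curves
#'
#' @param config from [pnpp_sim_config()].
#' @param seed integer seed.
#' @return list with `curves` (tibble `substrate_mM`, `time_min`,
#'   `absorbance`) and `truth` (list `Km`, `Vmax`, `E0`, `path_cm`).
#' @export
simulate_pnpp_progress <- function(config = pnpp_sim_config(), seed = 1L) {
  withr::with_seed(seed, {
    path <- path_length(config$beer$well_volume_ul,
                        config$beer$well_radius_mm)
    times <- seq(0, config$duration, by = config$sample_interval)
    curves <- lapply(config$substrate_mM, function(s0) {
      # small-step integration of dP/dt = Vmax (S0 - P) / (Km + S0 - P)
      grid <- seq(0, config$duration, by = config$dt)
      p <- numeric(length(grid))
      for (i in seq_along(grid)[-1]) {
        s <- max(0, s0 - p[i - 1])
        p[i] <- p[i - 1] + config$Vmax * s / (config$Km + s) * config$dt
      }
      prod <- stats::approx(grid, p, xout = times)$y
      a <- config$beer$epsilon * path * prod +
        stats::rnorm(length(times), sd = config$noise_sd)
      tibble::tibble(substrate_mM = s0, time_min = times, absorbance = a)
    })
    list(curves = dplyr::bind_rows(curves),
         truth = list(Km = config$Km, Vmax = config$Vmax, E0 = config$E0,
                      path_cm = path))
  })
}
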
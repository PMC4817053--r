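# Frame extraction, superposition, discriminability, CoM deviation.

test_that("inclusive interval extraction reproduces frame counts", {
  ens <- new_ensemble(array(rnorm(15001 * 1 * 3), c(15001, 1, 3)),
                      frame_interval_ps = 10)  # 150 ns span at 10 ps
  out <- extract_frames(ens, 50)
  expect_equal(dim(out$coords)[1], 3001)
  expect_equal(out$frame_interval_ps, 50)
  # 100 ps span at 50 ps: 3 frames
  short <- new_ensemble(array(rnorm(3 * 1 * 3), c(3, 1, 3)),
                        frame_interval_ps = 50)
  expect_equal(dim(extract_frames(short, 50)$coords)[1], 3)
  # interval beyond the span: single frame with a warning
  expect_warning(one <- extract_frames(short, 200), "single frame")
  expect_equal(dim(one$coords)[1], 1)
  expect_error(extract_frames(short, 75), "multiple")
})

test_that("superposition recovers exact rigid transforms", {
  ref <- reference_coordinates(20)
  coords <- array(0, c(2, 20, 3))
  coords[1, , ] <- ref
  coords[2, , ] <- rigid_rotate_z90(ref)
  ens <- superpose(new_ensemble(coords), ref)
  expect_equal(frame_rmsd(ens, ref), c(0, 0), tolerance = 1e-10)
})

test_that("fitted RMSD matches an independent quaternion oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      P <- matrix(rnorm(30), 10, 3)
      Q <- matrix(rnorm(30), 10, 3)
      ens <- superpose(new_ensemble(array(P, c(1, 10, 3))), Q)
      got <- frame_rmsd(ens, Q)
      expect_equal(got, oracle_rigid_rmsd(P, Q), tolerance = 1e-8)
    }
  })
})

test_that("superposition decreases RMSD and yields proper orthonormal rotations", {
  withr::with_seed(7, {
    ref <- reference_coordinates(30)
    cfg <- ensemble_sim_config(n_residues = 30, n_frames = 25,
                               reference = ref, sd = 0.8)
    sim <- simulate_ensembles(cfg, seed = 7)
    fitted <- superpose(sim$a, ref)
    expect_true(all(frame_rmsd(fitted, ref) <=
                      frame_rmsd(sim$a, ref) + 1e-10))
    for (rep in 1:5) {
      P <- matrix(rnorm(30), 10, 3)
      Q <- matrix(rnorm(30), 10, 3)
      fit <- oxiquant:::kabsch(P, Q)
      R <- fit$rotation
      expect_equal(det(R), 1, tolerance = 1e-10)
      expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
    }
  })
  expect_error(superpose(new_ensemble(array(0, c(1, 2, 3)) + 1,
                                      frame_interval_ps = 50),
                         matrix(1, 2, 3)), "at least 3")
})

test_that("CoM deviation matches geometry", {
  ref <- reference_coordinates(5)
  a <- new_ensemble(array(rep(ref, each = 4), c(4, 5, 3)))
  shifted <- ref
  shifted[2, ] <- shifted[2, ] + c(0.6, 0.8, 0)
  b <- new_ensemble(array(rep(shifted, each = 4), c(4, 5, 3)))
  expect_equal(com_deviation(a, b, 1), 0)
  expect_equal(com_deviation(a, b, 2), 1.0)  # 3-4-5 triangle
})

test_that("eta sits at chance for identical distributions and saturates when disjoint", {
  cfg <- ensemble_sim_config(n_residues = 3, n_frames = 400, sd = 1)
  sim <- simulate_ensembles(cfg, seed = 10)
  eta_null <- residue_discriminability(sim$a, sim$b, 2, repeats = 5,
                                       seed = 1)
  se <- sqrt(0.25 / (2 * 400))
  expect_lt(abs(eta_null - 0.5), 5 * se)
  # disjoint clouds 100 sigma apart
  shift <- matrix(0, 3, 3)
  shift[2, 1] <- 100
  simd <- simulate_ensembles(
    ensemble_sim_config(n_residues = 3, n_frames = 400, shift = shift),
    seed = 11)
  expect_equal(residue_discriminability(simd$a, simd$b, 2, repeats = 3,
                                        seed = 1), 1.0)
  # eta is symmetric in argument order up to resampling error
  eta_ab <- residue_discriminability(sim$a, sim$b, 1, repeats = 5, seed = 2)
  eta_ba <- residue_discriminability(sim$b, sim$a, 1, repeats = 5, seed = 2)
  expect_lt(abs(eta_ab - eta_ba), 0.02)
})

test_that("eta agrees with the Bayes oracle at d = 2 sigma and is monotone", {
  seps <- c(0, 1, 2, 4)
  n_fr <- 1500
  etas <- numeric(length(seps))
  for (i in seq_along(seps)) {
    shift <- matrix(0, 2, 3)
    shift[1, 1] <- seps[i]
    sim <- simulate_ensembles(
      ensemble_sim_config(n_residues = 2, n_frames = n_fr, shift = shift,
                          sd = 1), seed = 20 + i)
    etas[i] <- residue_discriminability(sim$a, sim$b, 1, repeats = 5,
                                        seed = 5)
    if (seps[i] == 2) {
      Xa <- matrix(sim$a$coords[, 1, ], ncol = 3)
      Xb <- matrix(sim$b$coords[, 1, ], ncol = 3)
      bayes <- oracle_bayes_accuracy(Xa, Xb, c(0, 0, 0) + reference_coordinates(2)[1, ],
                                     reference_coordinates(2)[1, ] + shift[1, ])
      expect_equal(etas[i], bayes, tolerance = 0.02)
      expect_equal(etas[i], pnorm(1), tolerance = 0.02)
    }
  }
  expect_true(all(diff(etas) > 0))
})

test_that("eta agreement with an established LDA implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(33, {
    Xa <- matrix(rnorm(600), 200, 3)
    Xb <- sweep(matrix(rnorm(600), 200, 3), 2, c(1.5, 0, 0), "+")
    X <- rbind(Xa, Xb)
    y <- rep(c(0, 1), each = 200)
    model <- oxiquant:::lda_train(X, y)
    mine <- oxiquant:::lda_predict(model, X)
    mass_fit <- MASS::lda(X, grouping = y)
    theirs <- as.integer(predict(mass_fit, X)$class) - 1L
    expect_gt(mean(mine == theirs), 0.99)
  })
})

test_that("profile flags configured shifts", {
  # generator frames are already in the reference frame; no fitting step
  # so the localized shift stays put
  shift <- matrix(0, 12, 3)
  shift[5:7, 1] <- 2
  cfg <- ensemble_sim_config(n_residues = 12, n_frames = 300, shift = shift,
                             sd = 0.5)
  sim <- simulate_ensembles(cfg, seed = 14)
  prof <- discriminability_profile(sim$a, sim$b, folds = 5, repeats = 3,
                                   seed = 3)
  expect_true(all(prof$flagged[5:7]))
  expect_false(any(prof$flagged[-(5:7)]))
  expect_equal(prof$com_deviation[5:7], rep(2, 3), tolerance = 0.15)
  gl <- glance(prof)
  expect_equal(gl$n_flagged, 3)
  expect_s3_class(autoplot(prof), "ggplot")
  expect_error(discriminability_profile(
    sim$a, new_ensemble(array(0, c(300, 5, 3))), seed = 1),
    "residue counts")
})

test_that("profile is invariant to a global rigid transform of both ensembles", {
  cfg <- ensemble_sim_config(n_residues = 12, n_frames = 200, sd = 0.5)
  sim <- simulate_ensembles(cfg, seed = 15)
  move <- function(e) {
    out <- e$coords
    for (f in seq_len(dim(out)[1])) out[f, , ] <- rigid_rotate_z90(out[f, , ])
    new_ensemble(out, e$residues, e$frame_interval_ps)
  }
  prof <- discriminability_profile(superpose(sim$a, cfg$reference),
                                   superpose(sim$b, cfg$reference),
                                   folds = 5, repeats = 3, seed = 3)
  prof2 <- discriminability_profile(superpose(move(sim$a), cfg$reference),
                                    superpose(move(sim$b), cfg$reference),
                                    folds = 5, repeats = 3, seed = 3)
  expect_equal(prof2$eta, prof$eta, tolerance = 1e-9)
  expect_equal(prof2$com_deviation, prof$com_deviation, tolerance = 1e-9)
})

test_that("degenerate zero-variance coordinates fall back to majority rule", {
  flat <- new_ensemble(array(1, c(30, 1, 3)))
  expect_warning(
    eta <- residue_discriminability(flat, flat, 1, repeats = 1, seed = 1),
    "majority")
  expect_equal(eta, 0.5)
})

test_that("ensembles round-trip through multi-model PDB", {
  skip_if_not_installed("bio3d")
  sim <- simulate_ensembles(
    ensemble_sim_config(n_residues = 4, n_frames = 6), seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(sim$a, path)
  back <- read_ensemble_pdb(path)
  expect_equal(back$coords, sim$a$coords, tolerance = 1e-3)
})
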
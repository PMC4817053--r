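# XIC extraction, AUC integration, ratios, fold changes, summaries.

make_run <- function(times, peaks) {
  # peaks: list of list(mz, intensity vector over times)
  dplyr::bind_rows(lapply(peaks, function(p) {
    tibble::tibble(scan_time = times, mz = p$mz, intensity = p$intensity)
  }))
}

test_that("XIC extraction honors the ppm window", {
  times <- seq(0, 2, by = 0.02)
  target <- 500.25
  shape <- exp(-(times - 1)^2 / (2 * 0.1^2)) * 1e5
  run <- make_run(times, list(
    list(mz = target, intensity = shape),
    list(mz = target * (1 + 50e-6), intensity = shape)  # 50 ppm away
  ))
  xic <- extract_xic(run, target, tolerance_ppm = 5)
  expect_equal(xic$scan_time[which.max(xic$intensity)], 1)
  expect_equal(max(xic$intensity), 1e5)  # far peak excluded
  # both captured at a wide tolerance
  wide <- extract_xic(run, target, tolerance_ppm = 100)
  expect_equal(max(wide$intensity), 2e5)
  # near-zero window on jittered data recovers nothing
  jit <- run
  jit$mz <- jit$mz * (1 + rnorm(nrow(jit), sd = 2e-6))
  none <- extract_xic(jit, target, tolerance_ppm = 1e-9)
  expect_lt(sum(none$intensity), 1e5 * 0.05)
  # empty run: empty XIC, not an error
  empty <- extract_xic(run[0, ], target, 5)
  expect_equal(nrow(empty), 0)
})

test_that("XICs scale linearly with global intensity", {
  times <- seq(0, 2, by = 0.02)
  run <- make_run(times, list(
    list(mz = 400.2, intensity = exp(-(times - 1)^2 / 0.02) * 1e4)))
  x1 <- extract_xic(run, 400.2, 5)
  run2 <- run
  run2$intensity <- run2$intensity * 3
  x2 <- extract_xic(run2, 400.2, 5)
  expect_equal(x2$intensity, 3 * x1$intensity)
})

test_that("AUC integration matches closed forms and is scan-rate invariant", {
  # unit-height rectangular pulse of width 0.5
  times <- seq(0, 3, by = 0.01)
  rect <- tibble::tibble(scan_time = times,
                         intensity = as.numeric(times >= 1 & times <= 1.5))
  expect_equal(integrate_auc(rect, c(0.9, 1.6)), 0.5, tolerance = 0.03)
  # Gaussian pulse: amplitude * sigma * sqrt(2 pi)
  amp <- 2e5; sigma <- 0.08
  gauss <- tibble::tibble(
    scan_time = times,
    intensity = amp * exp(-(times - 1.5)^2 / (2 * sigma^2)))
  expect_equal(integrate_auc(gauss, c(0, 3)), amp * sigma * sqrt(2 * pi),
               tolerance = 0.01)
  # auto-detected window captures the peak to within 1%
  expect_equal(integrate_auc(gauss), amp * sigma * sqrt(2 * pi),
               tolerance = 0.01)
  # doubling the scan rate leaves the integral unchanged
  fine <- seq(0, 3, by = 0.005)
  gauss2 <- tibble::tibble(
    scan_time = fine,
    intensity = amp * exp(-(fine - 1.5)^2 / (2 * sigma^2)))
  expect_equal(integrate_auc(gauss2, c(0, 3)), integrate_auc(gauss, c(0, 3)),
               tolerance = 1e-4)
  # all-zero XIC
  expect_equal(integrate_auc(tibble::tibble(scan_time = times,
                                            intensity = 0 * times)), 0)
})

test_that("AUC is proportional to injected abundance over a 100x ladder", {
  scales <- c(0.01, 0.03, 0.1, 0.3, 1)
  aucs <- vapply(seq_along(scales), function(i) {
    sim <- simulate_lcms_oxidation(
      c(g = 1), lcms_sim_config(base_abundance = 1e6 * scales[i],
                                replicates = 1), seed = 100 + i)
    run <- sim$runs
    mz_non <- sim$species$mz[sim$species$species == "nonoxidized"]
    integrate_auc(extract_xic(run, mz_non, 5))
  }, numeric(1))
  r2 <- summary(lm(aucs ~ scales))$r.squared
  expect_gt(r2, 0.99)
})

test_that("oxidation ratios recover injected odds and invert on swap", {
  sim <- simulate_lcms_oxidation(c(g = 0.5), lcms_sim_config(replicates = 1),
                                 seed = 21)
  run <- sim$runs
  mz_non <- sim$species$mz[sim$species$species == "nonoxidized"]
  mz_ox <- sim$species$mz[sim$species$species == "oxidized"]
  res <- site_oxidation_ratio(run, mz_ox, mz_non)
  expect_equal(res$ratio, 0.5, tolerance = 0.05)
  swapped <- site_oxidation_ratio(run, mz_non, mz_ox)
  expect_equal(swapped$ratio, 1 / res$ratio, tolerance = 1e-10)
  # zero denominator: NA with a warning, not an error
  blank <- run
  blank$intensity <- 0
  expect_warning(r0 <- site_oxidation_ratio(blank, mz_ox, mz_non), "zero")
  expect_true(is.na(r0$ratio))
})

test_that("fold change and t-test match textbook arithmetic", {
  g <- c(0.42, 0.39, 0.45)
  ctl <- c(0.010, 0.012, 0.008)
  fc <- fold_change_vs_control(g, ctl)
  expect_equal(fc$fold, mean(g) / mean(ctl), tolerance = 1e-12)
  expect_equal(fc$p_value, oracle_t_test(g, ctl), tolerance = 1e-10)
  # identical groups with variance: fold 1, p = 1
  same <- fold_change_vs_control(ctl, ctl)
  expect_equal(same$fold, 1)
  expect_equal(same$p_value, 1)
  # zero within-group variance, different means: p at the machine limit
  expect_warning(deg <- fold_change_vs_control(c(2, 2, 2), c(1, 1, 1)),
                 "machine")
  expect_true(deg$degenerate)
  expect_lte(deg$p_value, .Machine$double.eps)
  # undefined ratios are dropped with a warning
  expect_warning(fold_change_vs_control(c(0.4, NA), c(0.01, 0.02)),
                 "Dropping")
})

test_that("global oxidation ratio and mod/base normalization behave", {
  tab <- tibble::tibble(oxidized = c(TRUE, TRUE, FALSE, FALSE),
                        intensity = c(10, 30, 20, 20))
  expect_equal(global_oxidation_ratio(tab), 1.0)
  tab2 <- tab
  tab2$intensity <- tab2$intensity * 7
  expect_equal(global_oxidation_ratio(tab2), 1.0)
  half <- tibble::tibble(oxidized = c(TRUE, FALSE), intensity = c(5, 5))
  expect_equal(global_oxidation_ratio(half), 1.0)
  expect_warning(
    gna <- global_oxidation_ratio(
      tibble::tibble(oxidized = TRUE, intensity = 3)), "undefined")
  expect_true(is.na(gna))

  nb <- normalize_modbase(c(M95 = 0.8, M64 = 0.2))
  expect_equal(nb$normalized[nb$site == "M95"], 1.0)
  expect_equal(nb$normalized[nb$site == "M64"], 0.25)
  expect_equal(normalize_modbase(c(only = 0.3))$normalized, 1.0)
  # permutation invariance
  nb2 <- normalize_modbase(c(M64 = 0.2, M95 = 0.8))
  expect_equal(nb2$normalized[nb2$site == "M64"], 0.25)
  expect_warning(z <- normalize_modbase(c(a = 0, b = 0)), "zero")
  expect_equal(z$normalized, c(0, 0))
})

test_that("fold-change recovery is unbiased across an odds and fold grid", {
  for (fold in c(5, 41)) {
    base_odds <- 0.01
    sim <- run_oxidation_scenario(
      ox_odds = c(control = base_odds, treated = base_odds * fold),
      seed = 40 + fold)
    rep_row <- sim$report[sim$report$group == "treated", ]
    expect_equal(rep_row$recovered_fold, fold, tolerance = 0.05)
  }
})
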
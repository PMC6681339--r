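# One-site ITC: displacement bookkeeping against the finite-mixing oracle,
# isotherm limits and heat conservation, and parameter recovery by the
# Levenberg-Marquardt fit.

test_that("displacement model matches stepwise finite mixing", {
  sched <- cocun_itc_schedule("forward")
  half <- injection_schedule(V0 = 200e-6, volumes = 100e-6,
                             syringe_conc = 1e-3, cell_conc = 1e-4)
  expect_equal(unname(concentrations_after_injection(half, 1)),
               c(1e-4 / 2, 1e-3 / 2))

  fine <- oracle_itc_concentrations(sched$V0, sched$volumes,
                                    sched$syringe_conc, sched$cell_conc)
  for (i in c(1, 10, 38)) {
    got <- concentrations_after_injection(sched, i)
    expect_equal(got[["M"]], fine$M[i], tolerance = 1e-3)
    # titrant concentration carries the second-order displacement
    # difference between per-injection and per-step bookkeeping
    expect_equal(got[["X"]], fine$X[i], tolerance = 3.5e-3)
  }

  over <- injection_schedule(V0 = 10e-6, volumes = rep(2e-6, 6),
                             syringe_conc = 1e-3, cell_conc = 1e-4)
  expect_error(concentrations_after_injection(over, 1), "exceeds")
})

test_that("isotherm limits behave: zero enthalpy, tight binding, conservation", {
  sched <- cocun_itc_schedule("forward")
  expect_equal(simulate_isotherm(1, 49.7e-6, 0, 0, sched)$heats,
               rep(0, 38))

  # stoichiometric limit: constant heat per mole before the equivalence
  # point, ~zero after, with the transition at molar ratio n
  tight <- simulate_isotherm(1, 1e-12, -12600, 0, sched)
  moles <- sched$volumes * sched$syringe_conc
  per_mole <- tight$heats / moles
  conc <- t(vapply(1:38, function(i)
    concentrations_after_injection(sched, i), numeric(2)))
  ratio <- conc[, 2] / conc[, 1]
  pre <- ratio < 0.9; post <- ratio > 1.1
  expect_true(all(abs(per_mole[pre] - (-12600)) / 12600 < 0.02))
  expect_true(all(abs(per_mole[post]) / 12600 < 0.02))

  # heat conservation at the published parameters
  ex <- simulate_isotherm(1, 49.7e-6, -12600, 0, sched)
  i <- 38
  Qfinal <- 1 * conc[i, 1] * sched$V0 * (-12600) *
    fraction_bound(conc[i, 1], conc[i, 2], 49.7e-6)
  expect_equal(sum(ex$heats), unname(Qfinal), tolerance = 0.02)
})

test_that("noiseless fits recover the generating parameters", {
  for (dir in c("forward", "reverse")) {
    sched <- cocun_itc_schedule(dir)
    truth <- if (dir == "forward") c(1, 49.7e-6, -12600)
             else c(1, 61.8e-6, -13000)
    ex <- simulate_isotherm(truth[1], truth[2], truth[3], 0, sched)
    f <- fit_one_site(ex)
    expect_true(f$converged)
    expect_equal(f$n, truth[1], tolerance = 1e-4)
    expect_equal(f$K_D, truth[2], tolerance = 1e-4)
    expect_equal(f$dH, truth[3], tolerance = 1e-4)
  }
})

test_that("reverse-direction synthesis recovers a consistent dissociation constant", {
  # swap titrant and titrand but keep the forward ground truth: the fit
  # must find the same K_D from either direction
  sched_rev <- cocun_itc_schedule("reverse")
  ex <- make_itc_experiment(1, 49.7e-6, -12600, sched_rev,
                            noise_sd = 0.02, seed = 5)
  f <- fit_one_site(ex)
  expect_true(f$converged)
  expect_true(abs(f$K_D - 49.7e-6) < 3 * max(f$se[["K_D"]], 0.1 * 49.7e-6))
})

test_that("recovery error shrinks with noise and bias vanishes at low noise", {
  sched <- cocun_itc_schedule("forward")
  levels <- c(0.04, 0.02, 0.005)
  bias <- rmse <- numeric(length(levels))
  for (l in seq_along(levels)) {
    kd <- vapply(1:20, function(s) {
      ex <- make_itc_experiment(1, 49.7e-6, -12600, sched,
                                noise_sd = levels[l], seed = 1000 * l + s)
      fit_one_site(ex)$K_D
    }, numeric(1))
    rmse[l] <- sqrt(mean((kd - 49.7e-6)^2))
    bias[l] <- abs(stats::median(kd) - 49.7e-6) / 49.7e-6
  }
  expect_true(all(diff(rmse) < 0))
  # the estimator is consistent: with 20 replicates the apparent bias at
  # high noise is dominated by sampling error, so assert only where the
  # median is well resolved
  expect_lt(bias[2], 0.05)
  expect_lt(bias[3], 0.02)
})

test_that("degenerate all-zero data flags an unidentifiable K_D", {
  sched <- cocun_itc_schedule("forward")
  ex <- itc_experiment(sched, rep(0, 38))
  f <- fit_one_site(ex)
  expect_true(f$converged)
  expect_equal(f$dH, 0)
  expect_true(f$se[["K_D"]] >= f$K_D)
})

test_that("fit refuses too-short series and warns on extreme c-values", {
  sched <- injection_schedule(volumes = rep(1e-6, 5),
                              syringe_conc = 3.3e-3, cell_conc = 246e-6)
  ex <- simulate_isotherm(1, 49.7e-6, -12600, 0, sched)
  expect_error(fit_one_site(ex), "at least 6")

  tight <- simulate_isotherm(1, 1e-7, -12600, 0, cocun_itc_schedule())
  f <- fit_one_site(tight)
  expect_true(f$converged)
  expect_true(any(grepl("c-value", f$warnings)))
})

test_that("ITC data round-trips through the TSV dialect", {
  sched <- cocun_itc_schedule("forward")
  ex <- make_itc_experiment(1, 49.7e-6, -12600, sched, noise_sd = 0.02,
                            seed = 3)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_itc_experiment(ex, tmp)
  back <- read_itc_experiment(tmp, syringe_conc = 3.3e-3,
                              cell_conc = 246e-6)
  expect_equal(back$heats, ex$heats)
  expect_equal(back$schedule$volumes, sched$volumes)
})
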
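# CD spectroscopy: unit conversion arithmetic, difference-spectrum algebra,
# interpolation accuracy on closed-form spectra, and the 222 nm helix
# estimator.

grid02 <- seq(195, 260, by = 0.2)

test_that("mean-residue-ellipticity conversion is exact and invertible", {
  s <- cd_spectrum(grid02, rep(-10, length(grid02)), "mdeg",
                   conc = 50e-6, path_cm = 0.1, n_residues = 50)
  m <- to_mean_residue_ellipticity(s)
  expect_equal(m$signal, rep(-4000, length(grid02)))
  expect_identical(m$unit, "mre")
  back <- to_millidegrees(m)
  expect_equal(back$signal, s$signal, tolerance = 1e-12)

  z <- cd_spectrum(grid02, rep(0, length(grid02)), "mdeg", conc = 1e-5,
                   path_cm = 0.1, n_residues = 10)
  expect_equal(to_mean_residue_ellipticity(z)$signal, z$signal)

  nometa <- cd_spectrum(grid02, rep(-10, length(grid02)), "mdeg")
  expect_error(to_mean_residue_ellipticity(nometa), "requires")
})

test_that("difference spectra subtract point by point on the overlap", {
  s <- cd_spectrum(grid02, sin(grid02 / 10) * 1000, "mre")
  expect_equal(cd_difference(s, s)$signal, rep(0, length(grid02)))

  a <- cd_spectrum(grid02, cos(grid02 / 15) * 800, "mre")
  expect_equal(cd_sum(s, a)$signal - a$signal, s$signal)
  expect_equal(cd_difference(cd_sum(s, a), a)$signal, s$signal)

  other_unit <- cd_spectrum(grid02, s$signal, "mdeg")
  expect_error(cd_difference(s, other_unit), "unit mismatch")
  disjoint <- cd_spectrum(seq(300, 320, 0.2), rep(1, 101), "mre")
  expect_error(cd_difference(s, disjoint), "overlap")
})

test_that("offset grids interpolate within the linear-interpolation error", {
  f <- function(wl) -4000 * exp(-(wl - 208)^2 / (2 * 36)) # smooth band
  g <- function(wl) 1500 * exp(-(wl - 220)^2 / (2 * 49))
  a <- cd_spectrum(grid02, f(grid02), "mre")
  b <- cd_spectrum(grid02 + 0.1, g(grid02 + 0.1), "mre")
  d <- cd_difference(a, b)
  want <- f(d$wavelength) - g(d$wavelength)
  expect_lt(max(abs(d$signal - want)), 1e-3 * max(abs(want)))
})

test_that("difference algebra composes and scaling keeps zero crossings", {
  s <- cd_spectrum(grid02, sin(grid02 / 7) * 900, "mre")
  a <- cd_spectrum(grid02, cos(grid02 / 9) * 400, "mre")
  b <- cd_spectrum(grid02, sin(grid02 / 13) * 250, "mre")
  lhs <- cd_difference(cd_difference(s, a), b)
  rhs <- cd_difference(s, cd_sum(a, b))
  expect_equal(lhs$signal, rhs$signal, tolerance = 1e-12)

  # conversion commutes with subtraction
  meta <- list(conc = 3e-5, path_cm = 0.1, n_residues = 50)
  am <- cd_spectrum(grid02, a$signal, "mdeg", meta$conc, meta$path_cm,
                    meta$n_residues)
  bm <- cd_spectrum(grid02, b$signal, "mdeg", meta$conc, meta$path_cm,
                    meta$n_residues)
  d1 <- to_mean_residue_ellipticity(
    cd_spectrum(grid02, cd_difference(am, bm)$signal, "mdeg", meta$conc,
                meta$path_cm, meta$n_residues))
  d2 <- cd_difference(to_mean_residue_ellipticity(am),
                      to_mean_residue_ellipticity(bm))
  expect_equal(d1$signal, d2$signal, tolerance = 1e-12)

  amp <- cd_scale(lhs, 25)
  sgn <- sign(lhs$signal)
  expect_identical(sign(amp$signal), sgn)
})

test_that("the 222 nm estimator hits its own limits and inverts exactly", {
  N <- 50; T <- 25
  thH <- -39500 * (1 - 2.57 / N)
  thC <- 2220 - 53 * T
  coil <- cd_spectrum(grid02, rep(thC, length(grid02)), "mre",
                      n_residues = N)
  helix <- cd_spectrum(grid02, rep(thH, length(grid02)), "mre",
                       n_residues = N)
  expect_equal(helix_fraction_theta222(coil, T), 0)
  expect_equal(helix_fraction_theta222(helix, T), 1)

  d <- make_cd_dataset(0.46, n_residues_a = N)
  expect_equal(helix_fraction_theta222(d$a_alone, T), 0.46,
               tolerance = 1e-10)

  wrongunit <- cd_spectrum(grid02, rep(-10, length(grid02)), "mdeg")
  expect_error(helix_fraction_theta222(wrongunit), "mean residue")
  narrow <- cd_spectrum(seq(240, 260, 0.2), rep(-1, 101), "mre",
                        n_residues = N)
  expect_error(helix_fraction_theta222(narrow), "outside")
})

test_that("non-interacting mixtures difference to zero; perturbations return", {
  d <- make_cd_dataset(0.46)
  ch <- complex_induced_changes(d$mixture, d$a_alone, d$b_alone)
  expect_lt(max(abs(ch$delta_a$signal)), 1e-8)
  expect_equal(ch$delta_a$signal, ch$delta_b$signal)

  pert <- cd_spectrum(grid02, 300 * sin((grid02 - 195) / 8), "mre")
  dp <- make_cd_dataset(0.46, perturbation = pert)
  chp <- complex_induced_changes(dp$mixture, dp$a_alone, dp$b_alone)
  expect_equal(chp$delta_a$signal, pert$signal, tolerance = 1e-9)

  # null experiment with noise: the residual trace stays at the noise floor
  sigma <- 20
  dn <- make_cd_dataset(0.46, noise_sd = sigma, seed = 31)
  chn <- complex_induced_changes(dn$mixture, dn$a_alone, dn$b_alone)
  expect_lt(sqrt(mean(chn$delta_a$signal^2)), 3 * sigma)
})
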
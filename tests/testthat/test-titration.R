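# Fast-exchange titration machinery: the binding quadratic against a
# grid-search oracle, population-averaged shifts, CSP arithmetic and
# thresholding, and the active/passive partition by direct rule application.

test_that("fraction bound solves one-site mass action", {
  expect_equal(fraction_bound(100e-6, 0, 50e-6), 0)
  # stoichiometric limit: no dissociation, excess ligand
  expect_equal(fraction_bound(100e-6, 100e-6, 0), 1)
  expect_equal(fraction_bound(100e-6, 250e-6, 0), 1)
  expect_error(fraction_bound(-1, 1, 1))

  # published concentration regime vs the grid-search oracle
  fb <- fraction_bound(246e-6, 246e-6, 49.7e-6)
  expect_equal(fb, oracle_fraction_bound(246e-6, 246e-6, 49.7e-6),
               tolerance = 1e-5)

  # monotone in ligand, antitone in K_D
  set.seed(4)
  for (k in 1:25) {
    P <- runif(1, 1e-6, 1e-3)
    L <- sort(runif(6, 0, 2e-3))
    K <- sort(runif(4, 1e-7, 1e-3))
    expect_true(all(diff(fraction_bound(P, L, K[1])) >= 0))
    expect_true(all(diff(fraction_bound(P, L[3], K)) <= 0))
  }

  # hyperbolic limit as the protein becomes trace
  L <- 80e-6; K <- 49.7e-6
  expect_equal(fraction_bound(1e-12, L, K), L / (K + L), tolerance = 1e-6)
})

test_that("observed peaks interpolate linearly between free and bound", {
  free <- c(8.0, 120.0); bound <- c(8.2, 118.0)
  expect_equal(observed_shift(free, bound, 0), free)
  expect_equal(observed_shift(free, bound, 1), bound)
  expect_equal(observed_shift(free, bound, 0.5), c(8.1, 119.0))
  expect_error(observed_shift(free, bound, 1.2))
  # collinearity for arbitrary endpoints and fractions
  set.seed(9)
  for (k in 1:20) {
    f <- runif(2, 6, 130); b <- runif(2, 6, 130); fb <- runif(1)
    obs <- observed_shift(f, b, fb)
    lambda <- (obs - f) / (b - f)
    expect_equal(lambda[1], lambda[2], tolerance = 1e-12)
  }
})

test_that("CSP combines the two dimensions with the nitrogen scaling", {
  ref <- peak_list(1:3, c(8.0, 8.1, 8.2), c(120, 121, 122), "1:0")
  expect_equal(csp(ref, ref)$csp, c(0, 0, 0))
  expect_equal(attr(csp(ref, ref), "sigma"), 0)

  per <- peak_list(1:3, c(8.10, 8.1, 8.23), c(120, 121, 122.5))
  pr <- csp(ref, per)
  expect_equal(pr$csp[1], 0.10)                         # proton-only move
  expect_equal(pr$csp[3], sqrt(0.03^2 + (0.14 * 0.5)^2)) # 0.07616
  expect_equal(pr$csp[3], 0.07616, tolerance = 1e-4)

  # symmetric under swapping, invariant to a global proton offset
  expect_equal(csp(per, ref)$csp, pr$csp)
  ref2 <- ref; per2 <- per
  ref2$dH <- ref2$dH + 0.37; per2$dH <- per2$dH + 0.37
  expect_equal(csp(ref2, per2)$csp, pr$csp)

  expect_error(csp(ref, peak_list(7:9, rep(8, 3), rep(120, 3))),
               "no residue")
})

test_that("threshold rules match direct enumeration", {
  ref <- peak_list(1:3, rep(8, 3), rep(120, 3))
  per <- peak_list(1:3, c(8.01, 8.01, 8.10), rep(120, 3))
  pr <- csp(ref, per)
  vals <- pr$csp
  sg <- sqrt(mean((vals - mean(vals))^2))
  expect_identical(residues_above_threshold(pr, "sigma"),
                   sort(pr$residue[vals > sg]))
  expect_identical(residues_above_threshold(pr, "mean_plus_sigma"),
                   sort(pr$residue[vals > mean(vals) + sg]))
  zero <- csp(ref, ref)
  expect_length(residues_above_threshold(zero), 0)
})

test_that("active/passive partition applies the exposure and adjacency rules", {
  ref <- peak_list(1:3, rep(8, 3), rep(120, 3))
  per <- peak_list(1:3, c(8.00, 8.05, 8.30), rep(120, 3))
  pr <- csp(ref, per)
  expo <- c("1" = 0.8, "2" = 0.1, "3" = 0.9)
  nb <- list("1" = c(2, 3), "2" = c(1, 3), "3" = c(1, 2))
  sel <- select_active_passive(pr, expo, nb, exposure_cutoff = 0.4)
  # direct rule: above the mean AND exposed -> only residue 3
  expect_identical(sel$active, 3L)
  # neighbours of 3 are 1 and 2; only 1 is exposed
  expect_identical(sel$passive, 1L)

  # uniform profile: nothing strictly above the mean
  uni <- csp(ref, peak_list(1:3, rep(8.1, 3), rep(120, 3)))
  expect_length(select_active_passive(uni, expo, nb)$active, 0)

  # zero cutoff + complete adjacency: passive = profiled \ active
  sel0 <- select_active_passive(pr, expo, nb, exposure_cutoff = 0)
  expect_identical(sort(c(sel0$active, sel0$passive)), 1:3)

  expect_error(select_active_passive(pr, expo[1:2], nb), "missing exposure")
})

test_that("peak lists round-trip through the TSV dialect", {
  pl <- peak_list(c(3, 1, 7), c(8.1, 8.0, 7.9), c(120.5, 121, 119),
                  label = "1:0.5")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_peak_list(pl, tmp)
  back <- read_peak_list(tmp)
  expect_equal(as.data.frame(back), as.data.frame(pl))
  expect_identical(attr(back, "label"), "1:0.5")
})
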
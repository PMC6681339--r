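# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: shift tables with prescribed helical tracts,
# fast-exchange titration peak movements under a one-site model, noisy
# one-site thermograms, and additive CD mixtures with a small interaction
# perturbation. Every generator is a right-inverse of its analysis stage at
# zero noise, and identical seeds give bit-identical output.

#' Synthetic chemical-shift table with prescribed helical tracts
#'
#' Observed shifts are random-coil values plus a constant helical secondary
#' shift inside the given tracts plus optional Gaussian noise. Prolines get
#' no amide (N/HN) entries; positions marked `'X'` get no record at all. At
#' zero noise, [csi_index()] followed by [segments_from_index()] recovers
#' the tracts exactly (for tracts of at least `min_run` residues).
#'
#' @param sequence one-letter amino-acid string (may contain X).
#' @param helical_tracts data frame with `start`, `end` columns
#'   (non-overlapping) or a list of `c(start, end)` pairs.
#' @param helix_offsets named secondary shifts in ppm applied inside
#'   tracts; the defaults (HA -0.30, N -1.8) are typical helical
#'   magnitudes with the upfield sign convention used by [csi_index()].
#' @param noise_sd Gaussian noise sd in ppm (applied per nucleus).
#' @param seed integer seed; identical seeds give identical tables.
#' @param rc_set random-coil reference set.
#' @return a `shift_table`.
#' @export
make_shift_table <- function(sequence, helical_tracts,
                             helix_offsets = c(HA = -0.30, N = -1.8),
                             noise_sd = 0, seed = NULL,
                             rc_set = "wishart1995") {
  tr <- .as_tracts(helical_tracts)
  n <- nchar(sequence)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (nrow(tr) && (any(tr$start < 1) || any(tr$end > n)))
    stop("tract outside the sequence")
  in_tract <- rep(FALSE, n)
  for (k in seq_len(nrow(tr))) {
    span <- tr$start[k]:tr$end[k]
    if (any(in_tract[span])) stop("overlapping helical tracts")
    in_tract[span] <- TRUE
  }
  with_seed(seed, {
    rec <- data.frame(residue = integer(), aa = character())
    for (nu in .NUCLEI) rec[[nu]] <- numeric()
    for (i in seq_len(n)) {
      if (aa[i] == "X") next
      off_ha <- if (in_tract[i]) helix_offsets[["HA"]] else 0
      off_n <- if (in_tract[i]) helix_offsets[["N"]] else 0
      row <- list(residue = i, aa = aa[i],
                  N = NA_real_, HN = NA_real_,
                  HA = random_coil_shift(aa[i], "HA", rc_set) + off_ha +
                    stats::rnorm(1, 0, noise_sd),
                  HB = NA_real_, HG = NA_real_, HD = NA_real_)
      if (aa[i] != "P") {
        row$N <- random_coil_shift(aa[i], "N", rc_set) + off_n +
          stats::rnorm(1, 0, noise_sd)
        row$HN <- 8.30 + stats::rnorm(1, 0, noise_sd)
      }
      rec[nrow(rec) + 1L, ] <- row
    }
    new_shift_table(rec,
                    data.frame(residue = integer(), nucleus = character(),
                               note = character()),
                    sequence_length = n)
  })
}

.as_tracts <- function(x) {
  if (is.data.frame(x)) return(x[, c("start", "end"), drop = FALSE])
  if (!length(x)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, lapply(x, function(p)
    data.frame(start = p[1], end = p[2])))
}

#' Synthetic fast-exchange HSQC titration series
#'
#' Builds one peak list per molar ratio from the amide positions of a shift
#' table. Interface residues move toward their bound-state position by the
#' fraction bound from one-site mass action at each ratio; all peaks then
#' receive optional Gaussian noise. At zero noise and saturating ratio, the
#' 1-sigma rule of [residues_above_threshold()] recovers the interface set
#' exactly.
#'
#' @param table a `shift_table` providing the free-state amide positions
#'   (residues with both N and HN assigned).
#' @param interface integer residue set that senses binding.
#' @param delta_max bound-state offsets: either `c(dH = , dN = )` applied
#'   to every interface residue, or a data frame with `residue`, `dH`,
#'   `dN`.
#' @param K_D dissociation constant (molar).
#' @param P_t labelled-protein concentration (molar).
#' @param ratios molar ratios ligand:protein (>= 0); ratio 0 is the
#'   reference.
#' @param noise_sd Gaussian noise sd in ppm added to both dimensions.
#' @param seed integer seed.
#' @return named list of `peak_list`s, labels `"1:<ratio>"`.
#' @export
make_titration_series <- function(table, interface, delta_max, K_D, P_t,
                                  ratios = c(0, 0.5, 1), noise_sd = 0,
                                  seed = NULL) {
  stopifnot(inherits(table, "shift_table"), all(ratios >= 0))
  rec <- table$records
  rec <- rec[!is.na(rec$N) & !is.na(rec$HN), ]
  if (!all(interface %in% rec$residue))
    stop("interface residues absent from the amide-assigned set: ",
         paste(setdiff(interface, rec$residue), collapse = ", "))
  if (is.data.frame(delta_max)) {
    dmax <- delta_max
  } else {
    dmax <- data.frame(residue = interface,
                       dH = delta_max[["dH"]], dN = delta_max[["dN"]])
  }
  with_seed(seed, {
    out <- list()
    for (r in ratios) {
      fb <- if (r == 0) 0 else fraction_bound(P_t, r * P_t, K_D)
      dH <- rec$HN
      dN <- rec$N
      hit <- match(dmax$residue, rec$residue)
      dH[hit] <- observed_shift(dH[hit], dH[hit] + dmax$dH, fb)
      dN[hit] <- observed_shift(dN[hit], dN[hit] + dmax$dN, fb)
      dH <- dH + stats::rnorm(length(dH), 0, noise_sd)
      dN <- dN + stats::rnorm(length(dN), 0, noise_sd)
      lab <- paste0("1:", format(r))
      out[[lab]] <- peak_list(rec$residue, dH, dN, label = lab)
    }
    out
  })
}

#' Synthetic one-site ITC thermogram
#'
#' [simulate_isotherm()] plus seeded Gaussian noise whose standard
#' deviation is a fraction of the largest absolute per-injection heat
#' (default 2%).
#'
#' @param n,K_D,dH,q_offset one-site parameters, see [simulate_isotherm()].
#' @param schedule an `injection_schedule`.
#' @param noise_sd relative noise level (fraction of `max(abs(q))`).
#' @param seed integer seed.
#' @return an `itc_experiment`.
#' @export
make_itc_experiment <- function(n, K_D, dH, schedule, q_offset = 0,
                                noise_sd = 0.02, seed = NULL) {
  clean <- simulate_isotherm(n, K_D, dH, q_offset, schedule)
  if (noise_sd == 0) return(clean)
  sigma <- noise_sd * max(abs(clean$heats))
  with_seed(seed, {
    itc_experiment(schedule,
                   clean$heats + stats::rnorm(length(clean$heats), 0, sigma))
  })
}

# Closed-form template spectra on a wavelength grid, anchored exactly at
# 222 nm to the limiting mean residue ellipticities used by
# helix_fraction_theta222(), so generated spectra invert that estimator
# exactly. These are synthetic shapes for testing, not measured basis sets.
.cd_helix_template <- function(wl, n_residues) {
  shape <- exp(-(wl - 222)^2 / (2 * 6^2)) + exp(-(wl - 208)^2 / (2 * 6^2)) -
    1.1 * exp(-(wl - 193)^2 / (2 * 5^2))
  at222 <- 1 + exp(-(222 - 208)^2 / (2 * 6^2)) -
    1.1 * exp(-(222 - 193)^2 / (2 * 5^2))
  .theta_helix_222(n_residues) * shape / at222
}
.cd_coil_template <- function(wl, temperature) {
  g <- exp(-(wl - 198)^2 / (2 * 7^2))
  .theta_coil_222(temperature) - 42000 * (g - exp(-(222 - 198)^2 / (2 * 7^2)))
}

#' Synthetic beta-rich CD spectrum
#'
#' A smooth template resembling a beta-sheet protein (single negative band
#' near 217 nm, positive band near 196 nm); used as the default binding
#' partner in [make_cd_dataset()]. Synthetic shape, not a measured
#' reference.
#'
#' @param wavelength nm grid.
#' @param n_residues residue count stored in the metadata.
#' @return a `cd_spectrum` in mean residue ellipticity.
#' @export
cd_beta_template <- function(wavelength = seq(195, 260, by = 0.2),
                             n_residues = 76) {
  sig <- -11000 * exp(-(wavelength - 217)^2 / (2 * 8^2)) +
    14000 * exp(-(wavelength - 196)^2 / (2 * 4^2))
  cd_spectrum(wavelength, sig, "mre", n_residues = n_residues)
}

#' Synthetic CD interaction dataset
#'
#' Emulates the difference-spectrum experiment: component A is a
#' helix/coil mixture with helix fraction `frac_helix_a` (constructed so
#' [helix_fraction_theta222()] recovers that fraction exactly), component B
#' is a supplied spectrum, and the mixture is `A + B + perturbation +
#' noise`. A zero perturbation emulates a non-interacting pair (the NEDD8
#' null experiment); at zero noise, [complex_induced_changes()] then
#' returns an exactly zero trace, and a non-zero perturbation is recovered
#' exactly.
#'
#' @param frac_helix_a helix fraction of component A in `[0, 1]`.
#' @param n_residues_a residue count of component A.
#' @param spectrum_b `cd_spectrum` of component B on the same grid
#'   (default: [cd_beta_template()] on `grid`).
#' @param perturbation `cd_spectrum` added to the mixture, or `NULL` for a
#'   non-interacting pair.
#' @param noise_sd Gaussian noise sd (signal units) added to the mixture.
#' @param seed integer seed.
#' @param grid wavelength grid, nm.
#' @param temperature degrees Celsius for the coil limit.
#' @return list of `cd_spectrum`s: `a_alone`, `b_alone`, `mixture`.
#' @export
make_cd_dataset <- function(frac_helix_a, n_residues_a = 50,
                            spectrum_b = NULL, perturbation = NULL,
                            noise_sd = 0, seed = NULL,
                            grid = seq(195, 260, by = 0.2),
                            temperature = 25) {
  stopifnot(frac_helix_a >= 0, frac_helix_a <= 1)
  if (is.null(spectrum_b)) spectrum_b <- cd_beta_template(grid)
  if (!isTRUE(all.equal(spectrum_b$wavelength, grid)))
    stop("spectrum_b must be on the requested wavelength grid")
  a_sig <- frac_helix_a * .cd_helix_template(grid, n_residues_a) +
    (1 - frac_helix_a) * .cd_coil_template(grid, temperature)
  a <- cd_spectrum(grid, a_sig, "mre", n_residues = n_residues_a)
  mix_sig <- a_sig + spectrum_b$signal
  if (!is.null(perturbation)) {
    if (!isTRUE(all.equal(perturbation$wavelength, grid)))
      stop("perturbation must be on the requested wavelength grid")
    mix_sig <- mix_sig + perturbation$signal
  }
  mix_sig <- with_seed(seed,
                       mix_sig + stats::rnorm(length(grid), 0, noise_sd))
  list(a_alone = a, b_alone = spectrum_b,
       mixture = cd_spectrum(grid, mix_sig, "mre"))
}
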
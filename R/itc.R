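# One-site isothermal titration calorimetry: perfusion-cell concentration
# bookkeeping, the forward isotherm model, and Levenberg-Marquardt fitting
# of (n, K_D, dH, offset) to per-injection heats.

#' Injection schedule of an ITC experiment
#'
#' @param V0 active cell volume in litres (default 200 uL, the nominal
#'   volume of the instrument family used; configurable).
#' @param volumes per-injection volumes in litres.
#' @param syringe_conc titrant concentration in the syringe (molar).
#' @param cell_conc titrand concentration in the cell before the first
#'   injection (molar).
#' @param temperature kelvin (metadata).
#' @param spacing seconds between injections (metadata).
#' @return an `injection_schedule`.
#' @export
injection_schedule <- function(V0 = 200e-6, volumes = rep(1e-6, 38),
                               syringe_conc, cell_conc,
                               temperature = 298.15, spacing = 150) {
  stopifnot(V0 > 0, all(volumes > 0), syringe_conc > 0, cell_conc > 0)
  structure(list(V0 = V0, volumes = volumes, syringe_conc = syringe_conc,
                 cell_conc = cell_conc, temperature = temperature,
                 spacing = spacing),
            class = "injection_schedule")
}

#' Published titration schedules for the CoCUN/ubiquitin ITC experiments
#'
#' Forward: 38 x 1 uL of 3.3 mM ubiquitin into 246 uM CoCUN; reverse:
#' 38 x 1 uL of 2.78 mM CoCUN into 200 uM ubiquitin; 150 s spacing, room
#' temperature, 200 uL cell.
#'
#' @param direction `"forward"` or `"reverse"`.
#' @return an `injection_schedule`.
#' @export
cocun_itc_schedule <- function(direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (direction == "forward")
    injection_schedule(syringe_conc = 3.3e-3, cell_conc = 246e-6)
  else
    injection_schedule(syringe_conc = 2.78e-3, cell_conc = 200e-6)
}

# Concentrations in the cell after every injection, under the perfusion
# (constant-volume displacement) model: each injection of volume v dilutes
# the existing contents by (1 - v/V0).
.itc_concentrations <- function(schedule) {
  v <- schedule$volumes
  if (sum(v) > schedule$V0)
    stop("cumulative injected volume exceeds the cell volume")
  d <- cumprod(1 - v / schedule$V0)
  data.frame(injection = seq_along(v),
             M = schedule$cell_conc * d,
             X = schedule$syringe_conc * (1 - d))
}

#' Cell concentrations after an injection
#'
#' Perfusion-cell displacement model: with the dilution factor
#' `d_i = prod_j (1 - v_j/V0)` over injections `j <= i`, the titrand
#' concentration is `M_i = M_0 d_i` and the titrant concentration
#' `X_i = X_syr (1 - d_i)`.
#'
#' @param schedule an `injection_schedule`.
#' @param i injection index (1-based).
#' @return named vector `c(M = , X = )` in molar.
#' @export
concentrations_after_injection <- function(schedule, i) {
  conc <- .itc_concentrations(schedule)
  if (i < 1 || i > nrow(conc)) stop("injection index out of range")
  c(M = conc$M[i], X = conc$X[i])
}

#' Simulate a one-site binding isotherm
#'
#' Forward model of the one-site fit. The cumulative heat after injection
#' `i` is `Q_i = n M_i V0 dH Theta_i`, where `Theta_i` is the fraction of
#' binding sites occupied, obtained from [fraction_bound()] with site
#' concentration `n M_i` and ligand `X_i`. The per-injection heat corrects
#' for the displaced volume and adds a dilution-heat baseline proportional
#' to the moles injected:
#' `q_i = Q_i - Q_{i-1} + (v_i/V0) (Q_i + Q_{i-1})/2 + q_offset v_i X_syr`.
#'
#' @param n stoichiometry (> 0, sites per titrand molecule).
#' @param K_D dissociation constant in molar (> 0).
#' @param dH binding enthalpy in J/mol of titrant bound.
#' @param q_offset dilution-heat baseline in J per mole injected.
#' @param schedule an `injection_schedule`.
#' @return an `itc_experiment`: list with `schedule`, `heats` (J per
#'   injection) and `unit = "J"`.
#' @export
simulate_isotherm <- function(n, K_D, dH, q_offset = 0, schedule) {
  stopifnot(n > 0, K_D > 0)
  conc <- .itc_concentrations(schedule)
  theta <- fraction_bound(n * conc$M, conc$X, K_D)
  Q <- n * conc$M * schedule$V0 * dH * theta
  Qprev <- c(0, Q[-length(Q)])
  v <- schedule$volumes
  q <- Q - Qprev + (v / schedule$V0) * (Q + Qprev) / 2 +
    q_offset * v * schedule$syringe_conc
  itc_experiment(schedule, q)
}

#' Construct an ITC experiment
#'
#' @param schedule an `injection_schedule`.
#' @param heats per-injection heats, same length as the schedule.
#' @param unit energy unit tag; joules internally.
#' @return an `itc_experiment`.
#' @export
itc_experiment <- function(schedule, heats, unit = "J") {
  stopifnot(inherits(schedule, "injection_schedule"),
            length(heats) == length(schedule$volumes),
            all(is.finite(heats)))
  structure(list(schedule = schedule, heats = heats, unit = unit),
            class = "itc_experiment")
}

#' Read / write per-injection ITC data
#'
#' Tab-separated `injection  volume_uL  heat_uJ`; the schedule metadata
#' (cell volume, concentrations, temperature) travel separately.
#'
#' @param file path.
#' @param syringe_conc,cell_conc,V0,temperature schedule metadata used to
#'   rebuild the `injection_schedule` on read.
#' @return [read_itc_experiment()] returns an `itc_experiment`.
#' @export
read_itc_experiment <- function(file, syringe_conc, cell_conc, V0 = 200e-6,
                                temperature = 298.15) {
  d <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  sched <- injection_schedule(V0 = V0, volumes = d$volume_uL * 1e-6,
                              syringe_conc = syringe_conc,
                              cell_conc = cell_conc,
                              temperature = temperature)
  itc_experiment(sched, d$heat_uJ * 1e-6)
}

#' @rdname read_itc_experiment
#' @param data an `itc_experiment`.
#' @export
write_itc_experiment <- function(data, file) {
  d <- data.frame(injection = seq_along(data$heats),
                  volume_uL = data$schedule$volumes * 1e6,
                  heat_uJ = data$heats * 1e6)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Automatic starting values: stoichiometry from the molar ratio at which
# half the total heat has evolved, enthalpy from the early per-mole heats
# (where nearly all injected titrant binds), K_D at a fifth of the cell
# concentration, offset from the final per-mole heats.
.itc_init <- function(data, use) {
  sched <- data$schedule
  conc <- .itc_concentrations(sched)
  q <- data$heats[use]
  ratio <- (conc$X / conc$M)[use]
  moles <- (sched$volumes * sched$syringe_conc)[use]
  cum <- cumsum(q)
  half <- cum[length(cum)] / 2
  k <- which(abs(cum - half) == min(abs(cum - half)))[1]
  n0 <- max(0.2, min(5, ratio[k]))
  dh0 <- stats::median(utils::head(q / moles, 3))
  off0 <- stats::median(utils::tail(q / moles, 3))
  list(n = n0, K_D = sched$cell_conc / 5, dH = dh0 - off0, q_offset = off0)
}

#' Fit a one-site binding model to ITC data
#'
#' Least-squares fit of [simulate_isotherm()] to per-injection heats over
#' the four parameters (stoichiometry `n`, dissociation constant `K_D`,
#' enthalpy `dH`, per-mole dilution offset `q_offset`), by
#' Levenberg-Marquardt (via \pkg{minpack.lm}). Starting values are derived
#' automatically from the half-saturation molar ratio unless supplied. The
#' first `skip_first` injections are excluded (the customary discard of the
#' equilibration injection). The result carries asymptotic standard errors,
#' the association constant `K_A = 1/K_D`, a convergence flag, and a
#' warning when the Wiseman c-value `n * M_0 / K_D` leaves the
#' identifiable range `[0.1, 1000]`.
#'
#' @param data an `itc_experiment`.
#' @param init optional named list/vector with starting `n`, `K_D`, `dH`,
#'   `q_offset`.
#' @param skip_first number of leading injections to exclude (default 1).
#' @return a `one_site_fit`: list with elements `n`, `K_D`, `dH`,
#'   `q_offset`, `se` (named vector), `K_A`, `c_value`, `converged`,
#'   `warnings`, `fitted`, `residuals`.
#' @export
fit_one_site <- function(data, init = NULL, skip_first = 1L) {
  stopifnot(inherits(data, "itc_experiment"))
  nq <- length(data$heats)
  use <- seq_len(nq) > skip_first
  if (sum(use) < 6) stop("need at least 6 usable injections")
  sched <- data$schedule
  q_obs <- data$heats[use]
  scale <- max(abs(q_obs))

  if (scale == 0 || !is.finite(scale)) {
    # Degenerate: no heat at all. dH = 0 reproduces the data for any K_D,
    # which is therefore unidentifiable (infinite standard error).
    se <- c(n = Inf, K_D = Inf, dH = 0, q_offset = 0)
    return(structure(list(n = 1, K_D = sched$cell_conc, dH = 0,
                          q_offset = 0, se = se,
                          K_A = 1 / sched$cell_conc,
                          c_value = NA_real_, converged = TRUE,
                          warnings = "zero heats: K_D unidentifiable",
                          fitted = rep(0, sum(use)),
                          residuals = q_obs),
                     class = "one_site_fit"))
  }

  if (is.null(init)) init <- .itc_init(data, use)
  # Fit on a rescaled parameterization (log K_D, kJ/mol enthalpies, uJ
  # heats) so the gradient columns are commensurate; the raw-unit
  # parameterization leaves the problem numerically rank-deficient for
  # steep (high-c) isotherms.
  model_uJ <- function(p)
    1e6 * simulate_isotherm(p[["n"]], exp(p[["lnK"]]), 1e3 * p[["dH_kJ"]],
                            1e3 * p[["off_kJ"]], sched)$heats[use]
  q_uJ <- q_obs * 1e6
  start <- c(n = init$n, lnK = log(init$K_D),
             dH_kJ = init$dH / 1e3, off_kJ = init$q_offset / 1e3)

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(p) q_uJ - model_uJ(p),
      lower = c(n = 1e-3, lnK = log(1e-12), dH_kJ = -Inf, off_kJ = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    cf <- unlist(init)
    return(structure(list(n = cf[["n"]], K_D = cf[["K_D"]], dH = cf[["dH"]],
                          q_offset = cf[["q_offset"]],
                          se = c(n = NA, K_D = NA, dH = NA, q_offset = NA),
                          K_A = 1 / cf[["K_D"]],
                          c_value = cf[["n"]] * sched$cell_conc / cf[["K_D"]],
                          converged = FALSE,
                          warnings = conditionMessage(fit),
                          fitted = NULL, residuals = NULL),
                     class = "one_site_fit"))
  }

  raw <- fit$par
  cf <- c(n = raw[["n"]], K_D = exp(raw[["lnK"]]),
          dH = raw[["dH_kJ"]] * 1e3, q_offset = raw[["off_kJ"]] * 1e3)
  raw_se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) stats::setNames(rep(NA_real_, 4),
                                                         names(raw)))
  se <- c(n = raw_se[["n"]],
          K_D = cf[["K_D"]] * raw_se[["lnK"]],  # delta method on log K_D
          dH = raw_se[["dH_kJ"]] * 1e3,
          q_offset = raw_se[["off_kJ"]] * 1e3)
  cval <- cf[["n"]] * sched$cell_conc / cf[["K_D"]]
  warn <- character()
  if (cval < 0.1 || cval > 1000)
    warn <- sprintf("c-value %.3g outside the identifiable range [0.1, 1000]",
                    cval)
  if (any(is.na(se)))
    warn <- c(warn, "standard errors unavailable (singular information matrix)")
  structure(list(n = cf[["n"]], K_D = cf[["K_D"]], dH = cf[["dH"]],
                 q_offset = cf[["q_offset"]], se = se,
                 K_A = 1 / cf[["K_D"]], c_value = cval,
                 converged = fit$info %in% 1:4,
                 warnings = warn,
                 fitted = model_uJ(fit$par) * 1e-6,
                 residuals = (q_uJ - model_uJ(fit$par)) * 1e-6),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("One-site ITC fit", if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  n        = %.4g +/- %.2g\n", x$n, x$se[["n"]]))
  cat(sprintf("  K_D      = %.4g uM +/- %.2g (K_A = %.4g /M)\n",
              x$K_D * 1e6, x$se[["K_D"]] * 1e6, x$K_A))
  cat(sprintf("  dH       = %.4g kJ/mol +/- %.2g\n",
              x$dH / 1000, x$se[["dH"]] / 1000))
  cat(sprintf("  q_offset = %.4g J/mol, c-value = %.3g\n",
              x$q_offset, x$c_value))
  if (length(x$warnings) && nzchar(x$warnings[1]))
    cat("  warning:", x$warnings, "\n")
  invisible(x)
}
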
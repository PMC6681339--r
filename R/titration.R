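# HSQC titrations under two-state fast exchange: fraction bound, observed
# peak positions, chemical-shift perturbations (CSP), interface selection by
# the 1-sigma rule and active/passive partitioning for ambiguous
# interaction restraints (AIR).

#' Fraction of protein bound under one-site mass action
#'
#' Closed-form solution of the 1:1 binding quadratic for total protein
#' `P_t`, total ligand `L_t` and dissociation constant `K_D` (common units):
#' `f_b = ((P_t+L_t+K_D) - sqrt((P_t+L_t+K_D)^2 - 4 P_t L_t)) / (2 P_t)`,
#' clipped to `[0, 1]` against floating-point rounding.
#'
#' @param P_t total protein concentration (> 0); vectorized.
#' @param L_t total ligand concentration (>= 0); vectorized.
#' @param K_D dissociation constant (>= 0).
#' @return fraction(s) bound in `[0, 1]`.
#' @export
fraction_bound <- function(P_t, L_t, K_D) {
  if (any(P_t <= 0) || any(L_t < 0) || any(K_D < 0))
    stop("concentrations must be non-negative and P_t > 0")
  s <- P_t + L_t + K_D
  disc <- s^2 - 4 * P_t * L_t
  fb <- (s - sqrt(pmax(disc, 0))) / (2 * P_t)
  pmin(pmax(fb, 0), 1)
}

#' Population-averaged peak position under fast exchange
#'
#' In the fast-exchange regime the observed peak sits at the
#' population-weighted average of the free and bound positions:
#' `delta_obs = delta_free + f_b * (delta_bound - delta_free)`, per nucleus.
#'
#' @param free,bound numeric vectors (e.g. `c(dH, dN)`) of equal length.
#' @param f_b fraction bound in `[0, 1]`.
#' @return vector of observed positions.
#' @export
observed_shift <- function(free, bound, f_b) {
  if (any(f_b < 0 | f_b > 1)) stop("f_b must lie in [0, 1]")
  free + f_b * (bound - free)
}

#' Construct an HSQC peak list
#'
#' @param residue integer residue numbers (unique).
#' @param dH,dN proton and nitrogen shifts (ppm), finite.
#' @param label molar-ratio tag, e.g. `"1:0.5"`.
#' @return a `peak_list` data frame with attribute `label`.
#' @export
peak_list <- function(residue, dH, dN, label = "") {
  stopifnot(!anyDuplicated(residue), all(is.finite(dH)), all(is.finite(dN)))
  pl <- data.frame(residue = as.integer(residue), dH = dH, dN = dN)
  pl <- pl[order(pl$residue), ]
  rownames(pl) <- NULL
  attr(pl, "label") <- label
  class(pl) <- c("peak_list", "data.frame")
  pl
}

#' Read / write peak lists
#'
#' Tab-separated `residue  dH  dN` with an optional `#ratio=` comment line
#' carrying the molar-ratio tag.
#'
#' @param file path.
#' @return [read_peak_list()] returns a `peak_list`.
#' @export
read_peak_list <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lab <- sub("^#ratio=", "", grep("^#ratio=", lines, value = TRUE)[1])
  if (is.na(lab)) lab <- ""
  d <- utils::read.delim(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  peak_list(d$residue, d$dH, d$dN, label = lab)
}

#' @rdname read_peak_list
#' @param peaks a `peak_list`.
#' @export
write_peak_list <- function(peaks, file) {
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nzchar(attr(peaks, "label") %||% ""))
    writeLines(paste0("#ratio=", attr(peaks, "label")), con)
  utils::write.table(as.data.frame(peaks), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chemical-shift perturbation between two peak lists
#'
#' Combined amide displacement per residue present in both lists:
#' `CSP = sqrt(dDeltaH^2 + (alpha * dDeltaN)^2)` with the conventional
#' nitrogen scaling `alpha` (default 0.14, Williamson). The profile carries
#' the mean and the population standard deviation over the compared
#' residues, the basis of the 1-sigma interface threshold.
#'
#' @param reference,perturbed `peak_list`s (e.g. apo and ligand-added).
#' @param alpha 15N scaling factor (> 0).
#' @return a `csp_profile` data frame (`residue`, `dH`, `dN`, `csp`) with
#'   attributes `mean`, `sigma`, `alpha`.
#' @export
csp <- function(reference, perturbed, alpha = 0.14) {
  stopifnot(alpha > 0)
  m <- merge(as.data.frame(reference), as.data.frame(perturbed),
             by = "residue", suffixes = c("_ref", "_per"))
  if (!nrow(m)) stop("no residue is present in both peak lists")
  out <- data.frame(residue = m$residue,
                    dH = m$dH_per - m$dH_ref,
                    dN = m$dN_per - m$dN_ref)
  out$csp <- sqrt(out$dH^2 + (alpha * out$dN)^2)
  attr(out, "mean") <- mean(out$csp)
  attr(out, "sigma") <- sqrt(mean((out$csp - mean(out$csp))^2))
  attr(out, "alpha") <- alpha
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Residues above the perturbation threshold
#'
#' The interface-selection rule: residues whose combined shift perturbation
#' exceeds one standard deviation of the profile (`mode = "sigma"`, the
#' default, i.e. `CSP > sigma`), or the mean plus one standard deviation
#' (`mode = "mean_plus_sigma"`).
#'
#' @param profile a `csp_profile`.
#' @param mode threshold convention.
#' @return sorted integer vector of residue numbers.
#' @export
residues_above_threshold <- function(profile,
                                     mode = c("sigma", "mean_plus_sigma")) {
  mode <- match.arg(mode)
  if (!nrow(profile)) stop("empty CSP profile")
  thr <- switch(mode,
                sigma = attr(profile, "sigma"),
                mean_plus_sigma = attr(profile, "mean") + attr(profile, "sigma"))
  sort(profile$residue[profile$csp > thr])
}

#' Active/passive residue partition for docking restraints
#'
#' Active residues are those perturbed above the profile mean and exposed to
#' solvent (relative accessibility at or above `exposure_cutoff`); passive
#' residues are the exposed surface neighbours of the active set that are
#' not themselves active, as used to build ambiguous interaction restraints.
#'
#' @param profile a `csp_profile`.
#' @param exposure named numeric vector of per-residue relative solvent
#'   accessibilities (fractions), names = residue numbers; must cover every
#'   profiled residue. Computed externally (no structure engine here).
#' @param neighbors named list mapping residue number to the residue numbers
#'   of its spatial neighbours (symmetric adjacency).
#' @param exposure_cutoff minimum relative accessibility (default 0.4).
#' @return list with sorted integer vectors `active` and `passive`.
#' @export
select_active_passive <- function(profile, exposure, neighbors,
                                  exposure_cutoff = 0.4) {
  res <- profile$residue
  if (any(!as.character(res) %in% names(exposure)))
    stop("missing exposure entry for residue(s): ",
         paste(setdiff(res, as.integer(names(exposure))), collapse = ", "))
  expo <- exposure[as.character(res)]
  active <- res[profile$csp > attr(profile, "mean") &
                  expo >= exposure_cutoff]
  nb <- unique(unlist(neighbors[as.character(active)], use.names = FALSE))
  nb <- setdiff(as.integer(nb), active)
  nb_expo <- exposure[as.character(nb)]
  passive <- nb[!is.na(nb_expo) & nb_expo >= exposure_cutoff]
  list(active = sort(as.integer(active)), passive = sort(as.integer(passive)))
}

#' @export
print.csp_profile <- function(x, ...) {
  cat("CSP profile over", nrow(x), "residues: mean",
      signif(attr(x, "mean"), 4), "ppm, sigma",
      signif(attr(x, "sigma"), 4), "ppm (alpha =", attr(x, "alpha"), ")\n")
  invisible(x)
}
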
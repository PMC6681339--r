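# Chemical-shift-index (CSI) style secondary-structure assignment.
#
# Secondary shifts delta_obs - delta_rc of Halpha (and, as fallback, the
# amide 15N) are digitized against a dead band: upfield deviations beyond
# the threshold mark helix (-1), downfield beyond it strand-like (+1),
# otherwise coil (0). Maximal helical runs become segments.

# Random-coil reference shifts (ppm).
#
# "wishart1995": the GGXGG random-coil compilation of Wishart, Bigam, Holm,
# Hodges & Sykes (J Biomol NMR 5, 67-81, 1995), the modern standard for
# secondary-shift computation. "csi": the Halpha reference values of the
# original chemical-shift-index digitization (Wishart, Sykes & Richards,
# Biochemistry 31, 1647-1651, 1992); its 15N entries are taken from the 1995
# compilation since the original index was Halpha-canonical.
.RC_HA_1995 <- c(
  A = 4.32, C = 4.55, D = 4.64, E = 4.35, F = 4.62, G = 3.96, H = 4.73,
  I = 4.17, K = 4.32, L = 4.34, M = 4.48, N = 4.74, P = 4.42, Q = 4.34,
  R = 4.34, S = 4.47, T = 4.35, V = 4.12, W = 4.66, Y = 4.55)
.RC_N_1995 <- c(
  A = 123.8, C = 118.8, D = 120.4, E = 120.2, F = 120.3, G = 108.8,
  H = 118.2, I = 119.9, K = 120.4, L = 121.8, M = 119.6, N = 118.7,
  P = 128.1, Q = 119.8, R = 120.5, S = 115.7, T = 113.6, V = 119.2,
  W = 121.3, Y = 120.3)
.RC_HA_CSI <- c(
  A = 4.35, C = 4.65, D = 4.76, E = 4.29, F = 4.66, G = 3.97, H = 4.63,
  I = 3.95, K = 4.36, L = 4.17, M = 4.52, N = 4.75, P = 4.44, Q = 4.37,
  R = 4.38, S = 4.50, T = 4.35, V = 3.95, W = 4.70, Y = 4.60)

#' Random-coil chemical shift
#'
#' Deterministic lookup of the random-coil reference shift for one of the 20
#' canonical amino acids.
#'
#' @param amino_acid one-letter code (vectorized).
#' @param nucleus `"HA"` or `"N"`.
#' @param rc_set `"wishart1995"` (default) or `"csi"` (the original
#'   chemical-shift-index Halpha table).
#' @return reference shift(s) in ppm.
#' @export
random_coil_shift <- function(amino_acid, nucleus = c("HA", "N"),
                              rc_set = c("wishart1995", "csi")) {
  nucleus <- match.arg(nucleus)
  rc_set <- match.arg(rc_set)
  tab <- switch(paste(rc_set, nucleus, sep = "."),
                wishart1995.HA = .RC_HA_1995,
                wishart1995.N  = .RC_N_1995,
                csi.HA = .RC_HA_CSI,
                csi.N  = .RC_N_1995)
  amino_acid <- toupper(amino_acid)
  if (any(!amino_acid %in% names(tab)))
    stop("no random-coil value for amino acid(s): ",
         paste(unique(amino_acid[!amino_acid %in% names(tab)]),
               collapse = ", "))
  unname(tab[amino_acid])
}

#' Chemical-shift index profile
#'
#' Computes per-residue secondary shifts `delta_obs - delta_rc` and digitizes
#' them: index -1 (helix-like) below `-threshold`, +1 (strand-like) above
#' `+threshold`, 0 otherwise. The governing nucleus is the first in
#' `nucleus` that is assigned for the residue (default: Halpha primary, 15N
#' fallback); residues with neither nucleus assigned, or of unknown identity
#' (`'X'`), stay unassigned (`NA`).
#'
#' @param table a `shift_table`.
#' @param nucleus character vector giving nucleus priority, subset of
#'   `c("HA", "N")`.
#' @param threshold named dead-band half-widths in ppm, per nucleus.
#' @param rc_set random-coil reference set, see [random_coil_shift()].
#' @return a `csi_profile`: data frame with one row per sequence position
#'   (`residue`, `aa`, `nucleus`, `delta`, `index`).
#' @export
csi_index <- function(table, nucleus = c("HA", "N"),
                      threshold = c(HA = 0.10, N = 1.5),
                      rc_set = c("wishart1995", "csi")) {
  stopifnot(inherits(table, "shift_table"))
  nucleus <- match.arg(nucleus, c("HA", "N"), several.ok = TRUE)
  rc_set <- match.arg(rc_set)
  if (any(threshold[nucleus] <= 0) || any(is.na(threshold[nucleus])))
    stop("threshold must be > 0 for every governing nucleus")
  n <- table$sequence_length
  prof <- data.frame(residue = seq_len(n), aa = "X",
                     nucleus = NA_character_, delta = NA_real_,
                     index = NA_integer_)
  rec <- table$records
  prof$aa[rec$residue] <- rec$aa
  for (k in seq_len(nrow(rec))) {
    aa <- rec$aa[k]
    if (aa == "X" || !aa %in% names(.RC_HA_1995)) next
    for (nu in nucleus) {
      obs <- rec[[nu]][k]
      if (is.na(obs)) next
      d <- obs - random_coil_shift(aa, nu, rc_set)
      thr <- threshold[[nu]]
      i <- rec$residue[k]
      prof$nucleus[i] <- nu
      prof$delta[i] <- d
      prof$index[i] <- if (d < -thr) -1L else if (d > thr) 1L else 0L
      break
    }
  }
  class(prof) <- c("csi_profile", "data.frame")
  prof
}

#' Helical segments from a chemical-shift-index profile
#'
#' Extracts maximal runs of index -1. Interior gaps of index 0 or unassigned
#' residues are tolerated as long as each gap is at most
#' `max_interior_zeros` residues long; a +1 index always breaks a run.
#' Segment ends are always index -1, and runs shorter than `min_run` are
#' discarded.
#'
#' @param profile a `csi_profile` (or any data frame with `residue` and
#'   `index` columns).
#' @param min_run minimum segment length (default 4, the shortest span a
#'   helix can plausibly occupy).
#' @param max_interior_zeros maximum length of each interior non-helical gap
#'   (default 1).
#' @return data frame with columns `start`, `end`, `length`.
#' @export
segments_from_index <- function(profile, min_run = 4L,
                                max_interior_zeros = 1L) {
  stopifnot(min_run >= 1L, max_interior_zeros >= 0L)
  anchors <- profile$residue[!is.na(profile$index) & profile$index == -1L]
  idx <- rep(NA_integer_, max(profile$residue, 0L))
  idx[profile$residue] <- profile$index
  segs <- list()
  s <- e <- NA_integer_
  for (a in anchors) {
    if (is.na(s)) { s <- e <- a; next }
    gap <- (e + 1L):(a - 1L)
    gap <- gap[gap <= a - 1L & gap >= e + 1L]
    ok <- (a - e - 1L) <= max_interior_zeros &&
      !any(!is.na(idx[gap]) & idx[gap] == 1L)
    if (length(gap) == 0L || ok) e <- a
    else { segs[[length(segs) + 1L]] <- c(s, e); s <- e <- a }
  }
  if (!is.na(s)) segs[[length(segs) + 1L]] <- c(s, e)
  out <- data.frame(start = integer(), end = integer(), length = integer())
  for (sg in segs)
    if (sg[2] - sg[1] + 1L >= min_run)
      out[nrow(out) + 1L, ] <- c(sg[1], sg[2], sg[2] - sg[1] + 1L)
  out
}

#' Helix content from segments
#'
#' Fraction of the chain covered by helical segments.
#'
#' @param segments data frame with `start` and `end` columns (1-based,
#'   inclusive, non-overlapping).
#' @param n_residues denominator: the declared chain length, or the number
#'   of assigned residues (both conventions are in use; report which).
#' @return fraction in `[0, 1]`.
#' @export
helix_content <- function(segments, n_residues) {
  if (!nrow(segments)) return(0)
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end < segments$start))
    stop("segment with end < start")
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)]))
    stop("overlapping helical segments")
  covered <- sum(segments$end - segments$start + 1L)
  if (n_residues < covered)
    stop("n_residues smaller than the number of covered residues")
  covered / n_residues
}
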
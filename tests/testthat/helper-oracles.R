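# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: brute-force enumeration, stepwise
# bookkeeping, and direct rule application.

# --- helical-segment oracle -------------------------------------------------
# All maximal windows [s, e] with index -1 at both ends, no +1 inside, every
# maximal interior run of 0/NA at most max_z long, and length >= min_run.
# Direct window enumeration, independent of the package's chain-merging.
oracle_segments <- function(idx, min_run = 4L, max_z = 1L) {
  n <- length(idx)
  valid <- function(s, e) {
    w <- idx[s:e]
    if (is.na(w[1]) || w[1] != -1L) return(FALSE)
    if (is.na(w[length(w)]) || w[length(w)] != -1L) return(FALSE)
    if (any(!is.na(w) & w == 1L)) return(FALSE)
    gaps <- rle(is.na(w) | w != -1L)
    if (any(gaps$lengths[gaps$values] > max_z)) return(FALSE)
    TRUE
  }
  wins <- list()
  for (s in seq_len(n)) for (e in s:n)
    if (valid(s, e)) wins[[length(wins) + 1L]] <- c(s, e)
  keep <- list()
  for (w in wins) {
    contained <- any(vapply(wins, function(v)
      (v[1] < w[1] && v[2] >= w[2]) || (v[1] <= w[1] && v[2] > w[2]),
      logical(1)))
    if (!contained && (w[2] - w[1] + 1L) >= min_run)
      keep[[length(keep) + 1L]] <- w
  }
  if (!length(keep))
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  out <- do.call(rbind, keep)
  data.frame(start = out[, 1], end = out[, 2],
             length = out[, 2] - out[, 1] + 1L)
}

# --- mass-action grid-search oracle -----------------------------------------
# Fraction bound by direct minimisation of the mass-action residual
# (P - PL)(L - PL) - K PL over a fine grid of the complex concentration.
oracle_fraction_bound <- function(P, L, K, n_grid = 2e6) {
  pl <- seq(0, min(P, L), length.out = n_grid)
  resid <- abs((P - pl) * (L - pl) - K * pl)
  pl[which.min(resid)] / P
}

# --- stepwise finite-mixing oracle for the ITC cell -------------------------
# Explicit volume bookkeeping: each injection is delivered in small steps;
# each step adds titrant, mixes, and expels the overflow.
oracle_itc_concentrations <- function(V0, volumes, X_syr, M0,
                                      step = 0.01e-6) {
  M <- M0; X <- 0
  out <- data.frame(M = numeric(length(volumes)),
                    X = numeric(length(volumes)))
  for (i in seq_along(volumes)) {
    nstep <- round(volumes[i] / step)
    for (k in seq_len(nstep)) {
      M <- M * V0 / (V0 + step)
      X <- (X * V0 + X_syr * step) / (V0 + step)
    }
    out$M[i] <- M; out$X[i] <- X
  }
  out
}

# --- exhaustive global-alignment oracle -------------------------------------
# Enumerates every gapped global alignment of an (m, n) pair as a path of
# diagonal / up / left moves; affine gap cost: each maximal run of k
# identical gap moves costs open + k * extend. Returns per-shape path
# structures reusable across sequence pairs.
oracle_alignment_paths <- function(m, n) {
  paths <- list()
  walk <- function(i, j, moves) {
    if (i == m && j == n) {
      paths[[length(paths) + 1L]] <<- moves
      return(invisible())
    }
    if (i < m && j < n) walk(i + 1L, j + 1L, c(moves, "D"))
    if (i < m) walk(i + 1L, j, c(moves, "U"))
    if (j < n) walk(i, j + 1L, c(moves, "L"))
  }
  walk(0L, 0L, character())
  # usage matrix over aligned cells (i, j) and fixed gap cost per path
  U <- matrix(0L, nrow = length(paths), ncol = m * n)
  gap_runs <- vector("list", length(paths))
  for (p in seq_along(paths)) {
    mv <- paths[[p]]
    i <- 0L; j <- 0L
    for (s in mv) {
      if (s == "D") { i <- i + 1L; j <- j + 1L; U[p, (j - 1L) * m + i] <- 1L }
      else if (s == "U") i <- i + 1L
      else j <- j + 1L
    }
    r <- rle(mv)
    gap_runs[[p]] <- r$lengths[r$values != "D"]
  }
  list(U = U, gap_runs = gap_runs, m = m, n = n)
}

oracle_align_score <- function(a, b, paths, submat, open, extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  S <- outer(seq_along(ca), seq_along(cb),
             function(i, j) submat[cbind(ca[i], cb[j])])
  gapcost <- vapply(paths$gap_runs, function(g)
    if (length(g)) sum(open + g * extend) else 0, numeric(1))
  max(as.vector(paths$U %*% as.vector(S)) - gapcost)
}

# All sequences of lengths 1..max_len over an alphabet.
all_sequences <- function(alphabet, max_len) {
  unlist(lapply(seq_len(max_len), function(L) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    apply(g, 1, paste, collapse = "")
  }))
}
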
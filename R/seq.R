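# Pairwise global alignment with identity/similarity percentages and
# scanning for the short hydrophobic motifs that define CUE-like
# ubiquitin-binding domains (FP, FW, phi-xx-(I/L/V)-L, LSxx(L/V)L).

# Clustal consensus groups (strong ':' and weak '.').
.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")
.WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")

.get_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Global pairwise alignment with identity and similarity
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length `k`
#' costs `gap_open + k * gap_extend`), computed via
#' [Biostrings::pairwiseAlignment()]. Identity is the percentage of
#' alignment columns with identical residues; similarity additionally
#' counts columns whose substitution score is positive. A Clustal-style
#' consensus line marks identities (`*`), strong groups (`:`) and weak
#' groups (`.`).
#'
#' @param a,b amino-acid sequences (non-empty strings, canonical alphabet
#'   plus X).
#' @param matrix substitution matrix name (default `"BLOSUM62"`) or an
#'   actual matrix.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @return an `alignment_result`: list with `aligned_a`, `aligned_b`,
#'   `score`, `identity_pct`, `similarity_pct`, `consensus`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  mat <- .get_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb
  pos <- logical(len)
  pos[both] <- mat[cbind(ca[both], cb[both])] > 0
  pos <- pos & !ident
  cons <- vapply(seq_len(len), function(i) {
    if (!both[i]) return(" ")
    if (ident[i]) return("*")
    pair <- c(ca[i], cb[i])
    if (any(vapply(.STRONG_GROUPS,
                   function(g) all(pair %in% strsplit(g, "")[[1]]),
                   logical(1)))) return(":")
    if (any(vapply(.WEAK_GROUPS,
                   function(g) all(pair %in% strsplit(g, "")[[1]]),
                   logical(1)))) return(".")
    " "
  }, character(1))
  structure(list(aligned_a = ga, aligned_b = gb,
                 score = Biostrings::score(pa),
                 identity_pct = 100 * sum(ident) / len,
                 similarity_pct = 100 * (sum(ident) + sum(pos)) / len,
                 consensus = paste(cons, collapse = "")),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("Global alignment: score", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$consensus, "\n ", x$aligned_b, "\n")
  cat(sprintf("  identity %.1f%%, similarity %.1f%% over %d columns\n",
              x$identity_pct, x$similarity_pct, nchar(x$aligned_a)))
  invisible(x)
}

# Motif definitions: name -> c(regex, length). phi is a large hydrophobic
# residue (F, W, Y, L, I, M or V).
.MOTIFS <- list(
  FP = c("FP", 2L),
  FW = c("FW", 2L),
  phi_xx_IL_V_L = c("[FWYLIMV]..[ILV]L", 5L),
  LSxxLVL = c("LS..[LV]L", 6L))

#' Scan a sequence for ubiquitin-binding-domain motifs
#'
#' Finds every starting position (overlaps allowed) of the FP and FW pairs,
#' the C-terminal hydrophobic motif phi-xx-(I/L/V)-L (phi a large
#' hydrophobic residue) and its CoCUN/CUBAN variant LSxx(L/V)L.
#'
#' @param s an amino-acid sequence.
#' @return data frame with columns `motif`, `start` (1-based), `matched`.
#' @export
find_motifs <- function(s) {
  s <- toupper(s)
  hits <- list()
  for (name in names(.MOTIFS)) {
    rx <- .MOTIFS[[name]][1]
    len <- as.integer(.MOTIFS[[name]][2])
    m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    for (st in starts)
      hits[[length(hits) + 1L]] <- data.frame(
        motif = name, start = st, matched = substr(s, st, st + len - 1L))
  }
  if (!length(hits))
    return(data.frame(motif = character(), start = integer(),
                      matched = character()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write FASTA
#'
#' Thin wrappers over \pkg{Biostrings}: sequences are returned as a named
#' character vector, normalised to upper case; writing wraps at 60 columns
#' and round-trips exactly.
#'
#' @param file path.
#' @return [read_fasta()] returns a named character vector.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readAAStringSet(file)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, file) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every record needs a header name")
  set <- Biostrings::AAStringSet(toupper(sequences))
  Biostrings::writeXStringSet(set, file, width = 60L)
  invisible(file)
}
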
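# Per-residue backbone/side-chain chemical-shift tables.
#
# A shift_table holds one row per assigned residue with ppm values for up to
# six nucleus columns (N, HN, HA, HB, HG, HD), free-text qualifiers preserved
# from the source (e.g. "(Hg2)"), a declared sequence length (which may
# exceed the number of assigned rows) and the offset mapping local numbering
# onto the full-length protein (846 for CoCUN: local 1 <-> residue 847).

.NUCLEI <- c("N", "HN", "HA", "HB", "HG", "HD")

# Column-name aliases tolerated on input (BMRB-style and typographic
# variants); keys are lower-case.
.NUCLEUS_ALIASES <- c(
  "n" = "N", "15n" = "N",
  "hn" = "HN", "h" = "HN",
  "ha" = "HA", "hα" = "HA", "halpha" = "HA",
  "hb" = "HB", "hβ1,2" = "HB", "hβ" = "HB", "hbeta" = "HB",
  "hg" = "HG", "hγ" = "HG", "hgamma" = "HG",
  "hd" = "HD", "hδ" = "HD", "hdelta" = "HD"
)

new_shift_table <- function(records, annotations, sequence_length,
                            numbering_offset = 0L) {
  records <- records[order(records$residue), , drop = FALSE]
  rownames(records) <- NULL
  if (anyDuplicated(records$residue))
    stop("duplicate residue index in shift table: ",
         paste(records$residue[duplicated(records$residue)], collapse = ", "))
  if (nrow(records) && any(records$residue < 1L))
    stop("residue indices must be >= 1")
  if (nrow(records) && max(records$residue) > sequence_length)
    stop("residue index ", max(records$residue),
         " exceeds declared sequence length ", sequence_length)
  num <- as.matrix(records[, .NUCLEI, drop = FALSE])
  if (any(!is.finite(num) & !is.na(num)))
    stop("non-finite chemical shift value")
  structure(
    list(records = records, annotations = annotations,
         sequence_length = as.integer(sequence_length),
         numbering_offset = as.integer(numbering_offset)),
    class = "shift_table")
}

# Parse one table cell: "_" or blank -> NA; "0.08 (Hg2)" -> 0.08 with the
# qualifier preserved; Unicode minus accepted as a negative sign.
.parse_cell <- function(cell, row_label) {
  cell <- trimws(chartr("−", "-", cell))
  if (cell == "" || cell == "_") return(list(value = NA_real_, note = NA_character_))
  note <- NA_character_
  m <- regmatches(cell, regexec("^([^()]*?)\\s*\\(([^)]*)\\)\\s*$", cell))[[1]]
  if (length(m) == 3) {
    note <- m[3]
    cell <- trimws(m[2])
  }
  value <- suppressWarnings(as.numeric(cell))
  if (is.na(value))
    stop("row '", row_label, "': cell '", cell, "' is not numeric, '_' or blank")
  list(value = value, note = note)
}

#' Read a per-residue chemical-shift table
#'
#' Parses a tab-separated table whose header names a residue column plus one
#' or more nucleus columns (N, HN, HA, HB, HG, HD; BMRB-style aliases such as
#' "H" or Greek-letter headers are accepted). Rows start with the one-letter
#' amino-acid code followed by the residue index (e.g. `A1`), then numeric
#' cells. Missing values are written `_` or left blank and are stored as
#' absent (never 0); parenthesised qualifiers such as `0.08 (Hg2)` are
#' stripped into per-cell annotations; the Unicode minus sign is accepted.
#'
#' @param file path to a TSV file, or a character vector of lines.
#' @param sequence_length declared domain length including unassigned
#'   positions; defaults to the largest residue index present.
#' @param numbering_offset offset mapping local numbering to the full-length
#'   protein (846 for CoCUN).
#' @return a `shift_table`: list with `records` (data frame: `residue`,
#'   `aa`, one numeric column per nucleus), `annotations` (data frame:
#'   `residue`, `nucleus`, `note`), `sequence_length`, `numbering_offset`.
#' @seealso [cocun_shift_table()] for the packaged CoCUN assignment table,
#'   [write_shift_table()], [renumber()], [sequence_from_table()]
#' @export
read_shift_table <- function(file, sequence_length = NULL,
                             numbering_offset = 0L) {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               (file.exists(file) || grepl("[/\\\\]", file)))
    readLines(file, encoding = "UTF-8", warn = FALSE)
  else unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty input: no header row")

  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (!grepl("residue", header[1], ignore.case = TRUE) && header[1] != "")
    stop("header must name the residue column first, got '", header[1], "'")
  nuc_cols <- .NUCLEUS_ALIASES[tolower(header[-1])]
  if (any(is.na(nuc_cols)))
    stop("unknown nucleus column(s): ",
         paste(header[-1][is.na(nuc_cols)], collapse = ", "))
  if (!length(nuc_cols)) stop("header names no nucleus column")

  body <- lines[-1]
  n <- length(body)
  rec <- data.frame(residue = integer(n), aa = character(n))
  for (nu in .NUCLEI) rec[[nu]] <- rep(NA_real_, n)
  ann <- list()
  for (k in seq_len(n)) {
    cells <- strsplit(body[[k]], "\t", fixed = TRUE)[[1]]
    lab <- trimws(cells[1])
    m <- regmatches(lab, regexec("^([A-Za-z])([0-9]+)$", lab))[[1]]
    if (length(m) != 3)
      stop("row '", lab, "': residue label must be '<AA-letter><index>'")
    rec$aa[k] <- toupper(m[2])
    rec$residue[k] <- as.integer(m[3])
    vals <- cells[-1]
    for (j in seq_along(nuc_cols)) {
      if (j > length(vals)) break
      p <- .parse_cell(vals[j], lab)
      rec[[nuc_cols[j]]][k] <- p$value
      if (!is.na(p$note))
        ann[[length(ann) + 1L]] <- data.frame(
          residue = rec$residue[k], nucleus = unname(nuc_cols[j]),
          note = p$note)
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann)
  else data.frame(residue = integer(), nucleus = character(),
                  note = character())
  if (is.null(sequence_length))
    sequence_length <- if (n) max(rec$residue) else 0L
  new_shift_table(rec, annotations, sequence_length, numbering_offset)
}

#' Write a chemical-shift table
#'
#' Inverse of [read_shift_table()]: tab-separated, header
#' `residue N HN HA HB HG HD`, missing values written as `_`, annotations
#' re-attached as parenthesised qualifiers, ASCII hyphen-minus for negative
#' values. A parse -> write -> parse round trip reproduces the table exactly.
#'
#' @param table a `shift_table`.
#' @param file path to write to, or `NULL` to return the lines.
#' @return the written lines, invisibly when `file` is given.
#' @export
write_shift_table <- function(table, file = NULL) {
  stopifnot(inherits(table, "shift_table"))
  fmt <- function(x) ifelse(is.na(x), "_", vapply(x, format, "",
                                                  scientific = FALSE))
  rec <- table$records
  rows <- character(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    cells <- fmt(unlist(rec[k, .NUCLEI]))
    for (nu in .NUCLEI) {
      hit <- table$annotations$residue == rec$residue[k] &
        table$annotations$nucleus == nu
      if (any(hit))
        cells[nu] <- paste0(cells[nu], " (", table$annotations$note[hit][1], ")")
    }
    rows[k] <- paste(c(paste0(rec$aa[k], rec$residue[k]), cells),
                     collapse = "\t")
  }
  out <- c(paste(c("residue", .NUCLEI), collapse = "\t"), rows)
  if (is.null(file)) return(out)
  writeLines(out, file, useBytes = FALSE)
  invisible(out)
}

#' Packaged CoCUN chemical-shift assignment table
#'
#' The published backbone and side-chain proton/nitrogen assignments of the
#' CoCUN domain (44 assigned amide rows over a declared length of 50;
#' positions 20, 34, 36 and 48-50 carry no amide assignment), in local
#' numbering with `numbering_offset = 846`.
#'
#' @return a `shift_table`.
#' @export
cocun_shift_table <- function() {
  read_shift_table(
    system.file("extdata", "cocun_shifts.tsv", package = "cocun",
                mustWork = TRUE),
    sequence_length = 50L, numbering_offset = 846L)
}

#' Sequence patches for unassigned CoCUN positions
#'
#' Identities of positions absent from the packaged shift table but attested
#' by the domain's motifs and cloning construct: P20 (the Phe-Pro pair
#' F865-P866 in full-length numbering), V48 and L49 (the C-terminal
#' LSxx(L/V)L motif). Positions 34, 36 and 50 stay unknown.
#'
#' @return data frame with columns `position`, `aa`.
#' @export
cocun_sequence_patches <- function() {
  p <- utils::read.delim(
    system.file("extdata", "cocun_sequence_patches.tsv", package = "cocun",
                mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE)
  p$position <- as.integer(p$position)
  p
}

#' Amino-acid sequence recorded in a shift table
#'
#' Builds the one-letter sequence of length `sequence_length`; positions with
#' no assigned record are filled with `'X'` unless a patch supplies their
#' identity.
#'
#' @param table a `shift_table`.
#' @param patches optional data frame with columns `position`, `aa`
#'   (e.g. [cocun_sequence_patches()]).
#' @return a single character string.
#' @export
sequence_from_table <- function(table, patches = NULL) {
  stopifnot(inherits(table, "shift_table"))
  seq <- rep("X", table$sequence_length)
  seq[table$records$residue] <- table$records$aa
  if (!is.null(patches)) {
    stopifnot(all(c("position", "aa") %in% names(patches)))
    if (any(patches$position < 1 | patches$position > table$sequence_length))
      stop("patch position outside the sequence")
    seq[patches$position] <- toupper(patches$aa)
  }
  paste(seq, collapse = "")
}

#' Shift the residue numbering of a table
#'
#' Adds `offset` to every residue index (and to the declared sequence
#' length), adjusting the stored local-to-full-length offset so the mapping
#' stays invertible: `renumber(renumber(t, k), -k)` equals `t`.
#'
#' @param table a `shift_table`.
#' @param offset integer, may be negative.
#' @return the renumbered `shift_table`.
#' @export
renumber <- function(table, offset) {
  stopifnot(inherits(table, "shift_table"), length(offset) == 1L)
  offset <- as.integer(offset)
  rec <- table$records
  rec$residue <- rec$residue + offset
  if (nrow(rec) && any(rec$residue < 1L))
    stop("renumbering would produce residue index < 1")
  ann <- table$annotations
  ann$residue <- ann$residue + offset
  new_shift_table(rec, ann, table$sequence_length + offset,
                  table$numbering_offset - offset)
}

#' @export
print.shift_table <- function(x, ...) {
  cat("Chemical-shift table: ", nrow(x$records), " assigned residues / ",
      x$sequence_length, " positions (numbering offset ",
      x$numbering_offset, ")\n", sep = "")
  nuc <- colSums(!is.na(x$records[, .NUCLEI, drop = FALSE]))
  cat("  assigned per nucleus:",
      paste(names(nuc), nuc, sep = "=", collapse = " "), "\n")
  invisible(x)
}
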
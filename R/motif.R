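AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a dash-separated sequence motif
#'
#' Patterns like the diagnostic CAH motif `"S-G-G-X-E-X-Q-G-P-X-G-G-G-P"` are
#' parsed into an ordered list of allowed-residue sets; `X` is a wildcard
#' matching any of the 20 standard amino acids. Bracketed tokens such as
#' `"[ST]"` allow small residue sets.
#'
#' @param text dash-separated token string; tokens are single standard
#'   residues, `X`, or a bracketed residue set.
#' @return object of class `motif_pattern`: list with `positions` (list of
#'   character vectors) and `wildcard` (logical).
#' @export
#' @examples
#' p <- parse_pattern("S-G-G-X-E-X-Q-G-P-X-G-G-G-P")
#' length(p$positions)   # 14
#' format(p)
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 1L) stop("pattern must have at least one position")
  positions <- vector("list", length(tokens))
  wildcard <- logical(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok == "X") {
      positions[[i]] <- AA20
      wildcard[i] <- TRUE
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      set <- strsplit(substr(tok, 2, nchar(tok) - 1), "")[[1]]
      if (!all(set %in% AA20))
        stop("invalid residue set token: '", tok, "'", call. = FALSE)
      positions[[i]] <- sort(unique(set))
    } else if (tok %in% AA20) {
      positions[[i]] <- tok
    } else {
      stop("invalid motif token: '", tok, "'", call. = FALSE)
    }
  }
  structure(list(positions = positions, wildcard = wildcard),
            class = "motif_pattern")
}

#' @export
format.motif_pattern <- function(x, ...) {
  tok <- vapply(seq_along(x$positions), function(i) {
    if (x$wildcard[i]) "X"
    else if (length(x$positions[[i]]) == 1L) x$positions[[i]]
    else paste0("[", paste(x$positions[[i]], collapse = ""), "]")
  }, character(1))
  paste(tok, collapse = "-")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Motif pattern (", length(x$positions), " positions): ",
      format(x), "\n", sep = "")
  invisible(x)
}

sanitize_residues <- function(residues, lenient = FALSE, what = "sequence") {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(residues)
  if (!nzchar(res)) stop("empty ", what, call. = FALSE)
  chars <- strsplit(res, "")[[1]]
  if (any(chars %in% c("-", ".", "*")))
    stop("gap_or_stop_in_sequence: ", what,
         " contains gap or stop characters", call. = FALSE)
  bad <- !chars %in% AA20
  if (any(bad)) {
    if (!lenient)
      stop("nonstandard_residue: ", what, " contains non-standard residues: ",
           paste(unique(chars[bad]), collapse = ","), call. = FALSE)
    chars <- chars[!bad]
    if (!length(chars)) stop("empty ", what, " after sanitization", call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Scan a protein sequence for motif matches
#'
#' Reports every window matching the pattern (overlaps allowed), in ascending
#' start order, with 1-based inclusive coordinates. `relative_position` is
#' start divided by sequence length, so hits in the C-terminal quarter have
#' values >= 0.75.
#'
#' @param residues amino-acid string (sanitized; see `lenient`).
#' @param pattern a [parse_pattern()] object or pattern string.
#' @param seq_id identifier carried into the result.
#' @param lenient drop non-standard residues instead of erroring.
#' @return data.frame with columns `seq_id`, `start`, `end`, `matched`,
#'   `relative_position`.
#' @export
#' @examples
#' scan_motif("SGGAEAQGPAGGGP", "S-G-G-X-E-X-Q-G-P-X-G-G-G-P")
scan_motif <- function(residues, pattern, seq_id = "seq", lenient = FALSE) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  res <- sanitize_residues(residues, lenient = lenient)
  chars <- strsplit(res, "")[[1]]
  n <- length(chars)
  L <- length(pattern$positions)
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      matched = character(), relative_position = numeric(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    if (pattern$wildcard[j]) next
    ok <- ok & (chars[j:(j + n - L)] %in% pattern$positions[[j]])
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  data.frame(
    seq_id = seq_id, start = starts, end = starts + L - 1L,
    matched = vapply(starts, function(s) substr(res, s, s + L - 1L),
                     character(1)),
    relative_position = starts / n,
    stringsAsFactors = FALSE
  )
}

#' Position frequency matrix from an alignment
#'
#' Column residue frequencies from an equal-length set of aligned sequences;
#' gap characters (`-` or `.`) are excluded from column counts. Information
#' content per column is `log2(20)` minus the column's Shannon entropy, the
#' quantity drawn as letter heights in a sequence logo.
#'
#' @param aligned character vector (>= 2) of equal-length aligned sequences.
#' @return object of class `pfm`: list with `freq` (20 x L matrix, columns sum
#'   to 1), `info_bits` (length-L numeric) and `n_seq`.
#' @export
#' @examples
#' pfm_from_alignment(c("SGGA", "SGGC", "SGGA"))
pfm_from_alignment <- function(aligned) {
  stopifnot(is.character(aligned))
  if (length(aligned) < 2L) stop("need at least 2 sequences", call. = FALSE)
  aligned <- toupper(aligned)
  L <- unique(nchar(aligned))
  if (length(L) != 1L)
    stop("alignment_length_mismatch: sequences differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(aligned, ""))
  freq <- matrix(0, nrow = length(AA20), ncol = L,
                 dimnames = list(AA20, NULL))
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    if (!length(col)) stop("column ", j, " is all gaps", call. = FALSE)
    tab <- table(factor(col, levels = AA20))
    p <- as.numeric(tab) / sum(tab)
    freq[, j] <- p
    nz <- p[p > 0]
    info[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(list(freq = freq, info_bits = info, n_seq = length(aligned)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, digits = 3, ...) {
  cat("Position frequency matrix: ", ncol(x$freq), " columns from ",
      x$n_seq, " sequences\n", sep = "")
  cat("Information content (bits):",
      paste(round(x$info_bits, digits), collapse = " "), "\n")
  invisible(x)
}
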
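#' Global pairwise protein alignment
#'
#' Needleman-Wunsch alignment with affine gap penalties over the 20-letter
#' alphabet (default BLOSUM62, gap open 11, gap extend 1; a gap of length k
#' costs open + k * extend). Traceback ties are broken deterministically,
#' preferring diagonal, then up, then left, so results are reproducible across
#' platforms.
#'
#' @param a,b amino-acid strings (sanitized internally).
#' @param substitution 20 x 20 named score matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list of class `pairwise_alignment` with `score`, `aligned_a`,
#'   `aligned_b` and `a_to_b` (for each 1-based position of `a`, the aligned
#'   1-based position in `b`, or `NA` when aligned to a gap).
#' @export
#' @examples
#' align_global("HEAGAWGHEE", "PAWHEAE")$score
align_global <- function(a, b, substitution = blosum62,
                         gap_open = 11, gap_extend = 1) {
  a <- sanitize_residues(a, what = "sequence a")
  b <- sanitize_residues(b, what = "sequence b")
  sub <- substitution[AA20_ORDER(substitution), AA20_ORDER(substitution),
                      drop = FALSE]
  out <- .nw_align(a, b, sub, rownames(sub), gap_open, gap_extend)
  structure(c(out, list(gap_open = gap_open, gap_extend = gap_extend)),
            class = "pairwise_alignment")
}

AA20_ORDER <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)),
            all(AA20 %in% rownames(m)))
  rownames(m)[rownames(m) %in% AA20]
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat("Global alignment, score ", x$score, "\n", sep = "")
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$aligned_b, s, e), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' Check conservation of anchor residues against a reference
#'
#' Aligns a candidate sequence globally to a reference and asks, for each
#' anchor (a 1-based reference position plus a required residue), whether the
#' candidate residue aligned to that reference position is the required one.
#' The default anchors are the two active-site arginines that distinguish
#' cyanuric acid hydrolases from barbiturases (positions 194 and 324 in the
#' reference numbering).
#'
#' @param candidate candidate amino-acid string.
#' @param reference reference amino-acid string carrying the anchor numbering.
#' @param anchors named character vector: names are 1-based reference
#'   positions, values required residues. Default `c("194" = "R", "324" = "R")`.
#' @param ... passed to [align_global()].
#' @return data.frame with columns `ref_position`, `required`, `aligned_residue`
#'   (`NA` if aligned to a gap), `conserved`; the alignment is attached as
#'   attribute `"alignment"`.
#' @export
check_anchors <- function(candidate, reference,
                          anchors = c("194" = "R", "324" = "R"), ...) {
  stopifnot(length(anchors) >= 1L, !is.null(names(anchors)))
  pos <- as.integer(names(anchors))
  if (anyNA(pos)) stop("anchor names must be integer positions", call. = FALSE)
  reference <- sanitize_residues(reference, what = "reference")
  candidate <- sanitize_residues(candidate, what = "candidate")
  if (any(pos < 1L | pos > nchar(reference)))
    stop("anchor_out_of_range: anchor position beyond reference length",
         call. = FALSE)
  if (!all(anchors %in% AA20))
    stop("required anchor residues must be standard residues", call. = FALSE)
  aln <- align_global(reference, candidate, ...)
  aligned_res <- rep(NA_character_, length(pos))
  for (k in seq_along(pos)) {
    j <- aln$a_to_b[pos[k]]
    if (!is.na(j)) aligned_res[k] <- substr(candidate, j, j)
  }
  out <- data.frame(
    ref_position = pos, required = unname(anchors),
    aligned_residue = aligned_res,
    conserved = !is.na(aligned_res) & aligned_res == unname(anchors),
    stringsAsFactors = FALSE
  )
  attr(out, "alignment") <- aln
  out
}
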
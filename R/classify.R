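CAH_MOTIF <- "S-G-G-X-E-X-Q-G-P-X-G-G-G-P"

#' The diagnostic CAH motif
#'
#' The conserved C-terminal metal-binding pattern used to recognise cyanuric
#' acid hydrolases: 14 positions with wildcards at positions 4, 6 and 10.
#'
#' @return a `motif_pattern` object.
#' @export
cah_motif <- function() parse_pattern(CAH_MOTIF)

#' Classify a protein as CAH candidate, barbiturase-like, or negative
#'
#' A sequence is called a CAH candidate when it carries the diagnostic motif
#' near the C-terminus (hit start within the final quarter by default) *and*
#' both anchor arginines are conserved in a global alignment to the reference.
#' A sequence with a C-terminal motif hit but a failed anchor is called
#' barbiturase-like (barbiturases share the fold but lack the arginine pair);
#' anything else is negative.
#'
#' @param residues candidate amino-acid string.
#' @param reference reference sequence carrying the anchor numbering.
#' @param pattern motif pattern (string or [parse_pattern()] object).
#' @param anchors named character vector of anchor positions/residues.
#' @param c_term_threshold minimum `relative_position` (start / length) for a
#'   hit to count as C-terminal; default 0.75 (final 25% of the sequence).
#' @param seq_id identifier carried into the report.
#' @param lenient drop non-standard residues instead of erroring.
#' @return list of class `candidate_report` with `seq_id`, `hits` (all motif
#'   hits), `c_terminal_hit` (logical), `anchor_checks`, `verdict`.
#' @export
classify_cah <- function(residues, reference, pattern = cah_motif(),
                         anchors = c("194" = "R", "324" = "R"),
                         c_term_threshold = 0.75, seq_id = "seq",
                         lenient = FALSE) {
  hits <- scan_motif(residues, pattern, seq_id = seq_id, lenient = lenient)
  c_term <- nrow(hits) > 0 && any(hits$relative_position >= c_term_threshold)
  anchor_checks <- NULL
  verdict <- "negative"
  if (c_term) {
    anchor_checks <- check_anchors(residues, reference, anchors)
    verdict <- if (all(anchor_checks$conserved)) "CAH-candidate"
               else "barbiturase-like"
  }
  structure(
    list(seq_id = seq_id, hits = hits, c_terminal_hit = c_term,
         c_term_threshold = c_term_threshold,
         anchor_checks = anchor_checks, verdict = verdict),
    class = "candidate_report"
  )
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("%s: %s (%d motif hit%s%s)\n", x$seq_id, x$verdict,
              nrow(x$hits), if (nrow(x$hits) == 1) "" else "s",
              if (x$c_terminal_hit) ", C-terminal" else ""))
  if (!is.null(x$anchor_checks)) {
    ok <- x$anchor_checks$conserved
    cat("  anchors:",
        paste(sprintf("%s%d:%s", x$anchor_checks$required,
                      x$anchor_checks$ref_position,
                      ifelse(ok, "ok", "FAIL")), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Mine a FASTA file for CAH candidates
#'
#' Runs [classify_cah()] over every record of a protein FASTA and returns a
#' tidy report table (one row per sequence) suitable for writing as TSV.
#'
#' @param fasta path to a protein FASTA file, or a named character vector of
#'   sequences.
#' @param reference reference sequence (string) carrying the anchor numbering.
#' @inheritParams classify_cah
#' @return data.frame with columns `seq_id`, `start`, `matched`,
#'   `relative_position` (best C-terminal hit, or the first hit, NA if none),
#'   `n_hits`, `anchors_ok`, `verdict`.
#' @export
mine_cah <- function(fasta, reference, pattern = cah_motif(),
                     anchors = c("194" = "R", "324" = "R"),
                     c_term_threshold = 0.75, lenient = FALSE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_protein_fasta(fasta) else fasta
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- lapply(names(seqs), function(id) {
    rep_ <- classify_cah(seqs[[id]], reference, pattern, anchors,
                         c_term_threshold, seq_id = id, lenient = lenient)
    h <- rep_$hits
    best <- if (nrow(h)) {
      ct <- h[h$relative_position >= c_term_threshold, , drop = FALSE]
      if (nrow(ct)) ct[1L, ] else h[1L, ]
    } else NULL
    data.frame(
      seq_id = id,
      start = if (is.null(best)) NA_integer_ else best$start,
      matched = if (is.null(best)) NA_character_ else best$matched,
      relative_position = if (is.null(best)) NA_real_ else best$relative_position,
      n_hits = nrow(h),
      anchors_ok = if (is.null(rep_$anchor_checks)) NA
                   else all(rep_$anchor_checks$conserved),
      verdict = rep_$verdict,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a mining report as TSV
#'
#' @param report data.frame from [mine_cah()].
#' @param path output path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
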
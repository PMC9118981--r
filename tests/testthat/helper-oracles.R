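# Independent oracles used across the suite. Each one deliberately takes a
# different route from the implementation it checks.

# Sliding-window motif scan as a perl regex with lookahead (overlapping hits).
oracle_scan_regex <- function(residues, pattern_text) {
  toks <- strsplit(pattern_text, "-", fixed = TRUE)[[1]]
  rx <- paste0("(?=", paste(ifelse(toks == "X", ".", toks), collapse = ""), ")")
  m <- gregexpr(rx, residues, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Score a finished global alignment from its gapped strings (affine gaps,
# cost open + k * extend per gap run).
oracle_alignment_score <- function(aligned_a, aligned_b, sub, open, ext) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  score <- 0
  in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      score <- score - ext - (if (!in_gap) open else 0)
      in_gap <- TRUE
    } else {
      score <- score + sub[a[k], b[k]]
      in_gap <- FALSE
    }
  }
  score
}

# Multinomial 3-sigma band check for observed category counts.
expect_multinom_3sigma <- function(counts, probs) {
  n <- sum(counts)
  for (k in seq_along(probs)) {
    sd_k <- sqrt(n * probs[k] * (1 - probs[k]))
    expect_lte(abs(counts[k] - n * probs[k]), 3 * sd_k + 1)
  }
}

random_protein <- function(n) {
  paste(sample(cyaclear:::AA20, n, replace = TRUE), collapse = "")
}

# one fixed motif-free 350-mer used by the classifier tests
random_protein_fixed <- function() {
  set.seed(1234)
  paste(sample(cyaclear:::AA20, 350, replace = TRUE), collapse = "")
}

table1_cah_pr <- function() kinetic_params(kcat = 10.1, Km = 115)
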
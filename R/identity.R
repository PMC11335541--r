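# Pairwise sequence identity under unit-score global alignment.
#
# Score: match +1, mismatch -1, gap -1 per gapped column.  Among co-optimal
# alignments the one with the most matched columns defines the identity,
# which makes the statistic deterministic.  Equal-length pairs use the
# ungapped (Hamming) shortcut.

# Needleman-Wunsch returning c(score, matches) for the lexicographic optimum
# (max score, then max matches).  Rows are vectorized; the within-row left-gap
# recurrence collapses to a cumulative maximum because the gap penalty is
# linear.  State is encoded as score * ENC + matches with matches < ENC.
ENC <- 4096

nw_score_matches <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0L || m == 0L) return(c(score = -(n + m), matches = 0L))
  js <- 0:m
  prev <- -js * ENC                       # row 0: leading gaps in a
  for (i in seq_len(n)) {
    sub <- (B == A[i]) * (2 * ENC + 1) - ENC
    tmp <- pmax(prev[1:m] + sub,          # diagonal
                prev[2:(m + 1)] - ENC)    # gap in b (up)
    cand <- c(-i * ENC, tmp)              # j = 0 boundary, then j = 1..m
    prev <- cummax(cand + js * ENC) - js * ENC
  }
  e <- prev[m + 1]
  matches <- e %% ENC
  c(score = (e - matches) / ENC, matches = matches)
}

#' Pairwise sequence identity
#'
#' Identity between two sequences under a unit-score global alignment
#' (match +1, mismatch -1, gap -1), counting identical aligned columns.
#' Equal-length pairs are compared position-wise without gaps (the two
#' definitions coincide for the near-identical pairs the pipeline screens,
#' and the shortcut keeps the statistic deterministic and fast).
#'
#' @param a,b Sequences (amino acid or nucleotide), single strings.
#' @param denom Denominator convention: `"shorter"` (CD-HIT's convention,
#'   used for repertoire clustering) or `"longer"` (used for the UMI-bin
#'   collapse identity).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' seq_identity("PEPTIDE", "PEPTIDE")           # 1
#' seq_identity("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAC")  # 0.95
#' @export
seq_identity <- function(a, b, denom = c("shorter", "longer")) {
  denom <- match.arg(denom)
  la <- nchar(a)
  lb <- nchar(b)
  if (la == 0L || lb == 0L) return(0)
  if (a == b) return(1)
  matches <- if (la == lb) la - hamming(a, b) else nw_score_matches(a, b)[["matches"]]
  d <- if (denom == "shorter") min(la, lb) else max(la, lb)
  matches / d
}
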
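# Independent oracles used to cross-check the implementation.

# Anti-diagonal Needleman-Wunsch under the same objective as the package's
# row-vectorized DP (unit scores; ties broken toward more matches), written
# along the other matrix axis as an independent implementation.
oracle_nw_matches <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  ENC <- 4096
  D <- matrix(NA_real_, n + 1L, m + 1L)
  D[1L, ] <- -(0:m) * ENC
  D[, 1L] <- -(0:n) * ENC
  for (d in 2:(n + m)) {
    is <- max(1L, d - m):min(n, d - 1L)
    js <- d - is
    diag_ <- D[cbind(is, js)] + ifelse(A[is] == B[js], ENC + 1, -ENC)
    up <- D[cbind(is, js + 1L)] - ENC
    left <- D[cbind(is + 1L, js)] - ENC
    D[cbind(is + 1L, js + 1L)] <- pmax(diag_, up, left)
  }
  D[n + 1L, m + 1L] %% ENC
}

oracle_identity <- function(a, b, denom = "shorter") {
  la <- nchar(a)
  lb <- nchar(b)
  if (a == b) return(1)
  matches <- if (la == lb) {
    sum(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
  } else {
    oracle_nw_matches(a, b)
  }
  matches / if (denom == "shorter") min(la, lb) else max(la, lb)
}

# Brute-force greedy clustering: processes every sequence (no dedup) in
# length-descending, tie-lexicographic order and joins the first founded
# cluster whose representative reaches the threshold.  Returns the
# representative string per input sequence.
oracle_greedy_reps <- function(sequences, threshold) {
  ord <- order(-nchar(sequences), sequences)
  reps <- character(0)
  rep_of <- character(length(sequences))
  for (i in ord) {
    s <- sequences[i]
    hit <- NA_integer_
    for (k in seq_along(reps)) {
      if (oracle_identity(s, reps[k]) >= threshold) {
        hit <- k
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, s)
      hit <- length(reps)
    }
    rep_of[i] <- reps[hit]
  }
  rep_of
}

# Random sequence family generator for clustering tests: a few prototypes
# with substitution/deletion mutants, so identities straddle the thresholds.
random_sequence_family <- function(n, proto_lengths = 12:30, n_proto = NULL) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (is.null(n_proto)) n_proto <- sample(3:8, 1L)
  protos <- vapply(seq_len(n_proto), function(i) {
    paste(sample(aa, sample(proto_lengths, 1L), replace = TRUE), collapse = "")
  }, character(1))
  vapply(seq_len(n), function(i) {
    s <- sample(protos, 1L)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n_sub <- sample(0:3, 1L)
    if (n_sub > 0L) {
      pos <- sample(length(ch), min(n_sub, length(ch)))
      ch[pos] <- sample(aa, length(pos), replace = TRUE)
    }
    if (stats::runif(1) < 0.2 && length(ch) > 5L) ch <- ch[-sample(length(ch), 1L)]
    paste(ch, collapse = "")
  }, character(1))
}
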
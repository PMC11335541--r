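# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a half-open span
#'
#' Coordinates are 0-based, half-open `[start, end)` throughout the package,
#' in protein coordinates unless a record is explicitly nucleotide-level.
#'
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start <= end`.
#' @return A list of class `vlrb_span` with elements `start` and `end`.
#' @examples
#' s <- span(52, 70)
#' span_length(s)  # 18
#' @export
span <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start) {
    stop("invalid span: need 0 <= start <= end")
  }
  structure(list(start = start, end = end), class = "vlrb_span")
}

#' Length of a span
#' @param s A `vlrb_span`.
#' @return Integer `end - start`.
#' @export
span_length <- function(s) s$end - s$start

# Extract the substring covered by a 0-based half-open span.
span_seq <- function(x, s) substr(x, s$start + 1L, s$end)

#' @export
print.vlrb_span <- function(x, ...) {
  cat(sprintf("[%d, %d) len=%d\n", x$start, x$end, span_length(x)))
  invisible(x)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Mismatch count of every window of width nchar(motif) against the motif.
# Returns an integer vector over 0-based window starts 0..(L - w).
window_mismatches <- function(x, motif) {
  w <- nchar(motif)
  L <- nchar(x)
  if (L < w) return(integer(0))
  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  mc <- strsplit(motif, "", fixed = TRUE)[[1]]
  starts <- 0:(L - w)
  idx <- outer(starts, seq_len(w), `+`)  # 1-based column j at offset j
  mm <- matrix(xc[idx], nrow = length(starts)) !=
    matrix(mc, nrow = length(starts), ncol = w, byrow = TRUE)
  as.integer(rowSums(mm))
}
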
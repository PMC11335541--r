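# Translation, premature-stop filtering, stalk-motif filtering and
# per-sample protein deduplication.

#' Translate a molecule from its frame anchor
#'
#' The trimmed insert begins with the forward-primer annealing segment, which
#' anchors the reading frame: translation is standard-code frame 0 starting
#' at the N-terminus (no 3-frame search).  Trailing nucleotides that do not
#' complete a codon are ignored.  A stop codon before the last codon marks
#' the record `premature_stop`; a terminal stop is accepted and trimmed.
#'
#' @param nt Nucleotide string (the insert of a molecule).
#' @return A list with `protein` and `status` (`ok` or `premature_stop`).
#' @export
translate_from_start <- function(nt) {
  L <- nchar(nt)
  if (L < 3L) stop("insert shorter than one codon")
  nt <- substr(nt, 1L, 3L * (L %/% 3L))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(nt), if.fuzzy.codon = "X")
  ))
  first_stop <- regexpr("*", aa, fixed = TRUE)[1]
  m <- nchar(aa)
  if (first_stop < 0L) return(list(protein = aa, status = "ok"))
  if (first_stop == m) return(list(protein = substr(aa, 1L, m - 1L), status = "ok"))
  list(protein = substr(aa, 1L, first_stop - 1L), status = "premature_stop")
}

#' Locate the invariant stalk by its diagnostic motif
#'
#' Slides the 30-aa stalk motif over the protein without indels and takes
#' the window with the fewest substitutions (ties broken toward the most
#' C-terminal window).  A protein is retained iff the best window has at
#' most `stalk_max_mismatch` (2) differences; 3 or more differences — or no
#' window at all — discard the record.  The stalk subunit span is the
#' 87-aa region ending at the protein's C-terminus that contains the motif
#' (the motif occupies the stalk's C-terminal 30 residues).
#'
#' @param protein Amino-acid string.
#' @param cfg A [vlrb_config()].
#' @return A list with `motif_span`, `stalk_span` and `mismatches`, or
#'   `NULL` when no acceptable window exists.
#' @export
match_stalk <- function(protein, cfg = vlrb_config()) {
  motif <- cfg$stalk_motif
  w <- nchar(motif)
  L <- nchar(protein)
  if (L < w) return(NULL)
  # canonical fast path: motif flush with the C-terminus, 0 mismatches
  tail_win <- substr(protein, L - w + 1L, L)
  if (tail_win == motif) {
    best_start <- L - w    # 0-based
    best_mm <- 0L
  } else {
    mm <- window_mismatches(protein, motif)
    best_mm <- min(mm)
    best_start <- max(which(mm == best_mm)) - 1L  # most C-terminal tie
  }
  if (best_mm > cfg$stalk_max_mismatch) return(NULL)
  motif_span <- span(best_start, best_start + w)
  stalk_start <- max(0L, best_start - cfg$stalk_motif_offset)
  list(motif_span = motif_span,
       stalk_span = span(stalk_start, L),
       mismatches = best_mm)
}

#' Translate and ORF-filter a set of molecules
#'
#' Applies [translate_from_start()] and [match_stalk()] to every molecule.
#'
#' @param molecules Molecule data.frame (`sample_id`, `consensus_nt`,
#'   `read_count`).
#' @param cfg A [vlrb_config()].
#' @return A data.frame with `sample_id`, `protein`, `status` (`ok`,
#'   `premature_stop`, `no_stalk`), `stalk_start`, `stalk_end`.
#' @export
orf_filter <- function(molecules, cfg = vlrb_config()) {
  n <- nrow(molecules)
  protein <- character(n); status <- character(n)
  stalk_start <- rep(NA_integer_, n); stalk_end <- rep(NA_integer_, n)
  if (n > 0L) {
    nts <- molecules$consensus_nt
    nts <- substr(nts, 1L, 3L * (nchar(nts) %/% 3L))
    aas <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(nts), if.fuzzy.codon = "X")
    ))
    for (i in seq_len(n)) {
      aa <- aas[i]
      m <- nchar(aa)
      first_stop <- regexpr("*", aa, fixed = TRUE)[1]
      if (first_stop > 0L && first_stop < m) {
        protein[i] <- substr(aa, 1L, first_stop - 1L)
        status[i] <- "premature_stop"
        next
      }
      p <- if (first_stop == m) substr(aa, 1L, m - 1L) else aa
      hit <- match_stalk(p, cfg)
      if (is.null(hit)) {
        protein[i] <- p
        status[i] <- "no_stalk"
      } else {
        protein[i] <- p
        status[i] <- "ok"
        stalk_start[i] <- hit$stalk_span$start
        stalk_end[i] <- hit$stalk_span$end
      }
    }
  }
  data.frame(sample_id = molecules$sample_id, protein = protein,
             status = status, stalk_start = stalk_start,
             stalk_end = stalk_end, read_count = molecules$read_count,
             stringsAsFactors = FALSE)
}

#' Deduplicate identical proteins within samples
#'
#' Exact-string grouping of `status == "ok"` records per sample; abundance is
#' the number of collapsed molecules.  Output is sorted by sample, then
#' descending abundance, then lexicographic protein.
#'
#' @param records Output of [orf_filter()].
#' @return A data.frame `sample_id`, `protein`, `abundance`, `stalk_start`,
#'   `stalk_end`.
#' @export
dedup_proteins <- function(records) {
  ok <- records[records$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(data.frame(sample_id = character(0), protein = character(0),
                      abundance = integer(0), stalk_start = integer(0),
                      stalk_end = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(ok$sample_id, ok$protein, sep = "\r")
  first <- !duplicated(key)
  ab <- as.integer(table(key)[key[first]])
  out <- data.frame(sample_id = ok$sample_id[first], protein = ok$protein[first],
                    abundance = ab, stalk_start = ok$stalk_start[first],
                    stalk_end = ok$stalk_end[first], stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, -out$abundance, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
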
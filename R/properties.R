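# Amino-acid property analytics: hydropathy (GRAVY, Kyte-Doolittle) and
# polarity (Grantham) scores, per-position subunit statistics, position
# frequency matrices, length distributions, and the bimodal hydropathy split
# of extended loops.

#' Kyte-Doolittle hydropathy scale
#' @format Named numeric vector over the 20 canonical residues.
#' @export
aa_hydropathy <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Grantham polarity scale
#' @format Named numeric vector over the 20 canonical residues.
#' @export
aa_polarity <- c(
  A =  8.1, R = 10.5, N = 11.6, D = 13.0, C =  5.5,
  Q = 10.5, E = 12.3, G =  9.0, H = 10.4, I =  5.2,
  L =  4.9, K = 11.3, M =  5.7, F =  5.2, P =  8.0,
  S =  9.2, T =  8.6, W =  5.4, Y =  6.2, V =  5.9
)

# Sample SD (n-1 denominator); 0 for a single observation so summaries of
# degenerate groups stay numeric.
safe_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

score_peptides <- function(peptides, scale) {
  vapply(peptides, function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    if (length(ch) == 0L) stop("empty peptide")
    v <- scale[ch]
    if (anyNA(v)) stop("unknown residue in peptide: ",
                       paste(unique(ch[is.na(v)]), collapse = ""))
    mean(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the per-residue Kyte-Doolittle hydropathy values.
#'
#' @param peptides Character vector of peptides (canonical residues).
#' @param scale Per-residue scale (override to use a different table).
#' @return Numeric vector of scores.
#' @examples
#' gravy("LLLL")  # 3.8
#' @export
gravy <- function(peptides, scale = aa_hydropathy) score_peptides(peptides, scale)

#' Mean Grantham polarity
#'
#' @inheritParams gravy
#' @return Numeric vector of scores.
#' @export
polarity <- function(peptides, scale = aa_polarity) score_peptides(peptides, scale)

# Extract all LRRv unit sequences from annotated records with their ordinal
# position and LRRve designation.
lrrv_unit_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    if (a$status != "annotated") return(NULL)
    k <- a$lrrv_count
    data.frame(
      unit = vapply(a$spans$lrrv, function(s) span_seq(a$protein, s), character(1)),
      position = seq_len(k),
      is_lrrve = seq_len(k) == k,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Positional hydropathy/polarity statistics of LRRv units
#'
#' Groups LRRv units by ordinal position (1st, 2nd, ...) with the LRRve (the
#' last unit of each molecule) reported as its own group; molecules with a
#' single variable unit contribute only to the LRRve group.  Mean and sample
#' SD (n-1) of GRAVY and polarity are reported per group.
#'
#' @param annotations List of annotated `vlrb_annotation`.
#' @return Data.frame `group`, `n`, `hydropathy_mean`, `hydropathy_sd`,
#'   `polarity_mean`, `polarity_sd`.
#' @export
positional_subunit_stats <- function(annotations) {
  tab <- lrrv_unit_table(annotations)
  if (is.null(tab) || nrow(tab) == 0L) stop("no annotated LRRv units")
  tab$group <- ifelse(tab$is_lrrve, "LRRve", paste0("LRRv", tab$position))
  tab$h <- gravy(tab$unit)
  tab$p <- polarity(tab$unit)
  groups <- split(tab, tab$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               hydropathy_mean = mean(g$h),
               hydropathy_sd = safe_sd(g$h),
               polarity_mean = mean(g$p),
               polarity_sd = safe_sd(g$p),
               stringsAsFactors = FALSE)
  }))
  pos_num <- suppressWarnings(as.integer(sub("^LRRv", "", out$group)))
  out <- out[order(is.na(pos_num), pos_num), , drop = FALSE]  # LRRv1..n, then LRRve
  rownames(out) <- NULL
  out
}

#' Split loops into high/low hydropathy groups
#'
#' Partitions extended-loop sequences at the bimodality threshold (default
#' 0.35): scores `>= threshold` are `high`, scores `< threshold` are `low`.
#'
#' @param loops Character vector of (extended) loop sequences.
#' @param threshold Hydropathy split point.
#' @return A list with data.frames `high` and `low` (`loop`, `score`) and
#'   the `threshold`.
#' @export
split_loops_by_hydropathy <- function(loops, threshold = 0.35) {
  scores <- if (length(loops)) gravy(loops) else numeric(0)
  hi <- scores >= threshold
  list(high = data.frame(loop = loops[hi], score = scores[hi],
                         stringsAsFactors = FALSE),
       low = data.frame(loop = loops[!hi], score = scores[!hi],
                        stringsAsFactors = FALSE),
       threshold = threshold)
}

#' Position frequency matrix
#'
#' For equal-length sequences, the per-position residue frequencies (each
#' position sums to 1).  The per-position majority residue is attached as
#' attribute `consensus`.
#'
#' @param sequences Character vector of equal-length sequences.
#' @return A 20 x L matrix (rows: residues, columns: positions) with
#'   attribute `consensus`.
#' @export
frequency_matrix <- function(sequences) {
  if (!length(sequences)) stop("no sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length")
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)), nrow = L)
  M <- vapply(seq_len(L), function(p) {
    tabulate(factor(chars[p, ], levels = AA20), nbins = length(AA20)) / length(sequences)
  }, numeric(length(AA20)))
  rownames(M) <- AA20
  colnames(M) <- seq_len(L)
  attr(M, "consensus") <- AA20[apply(M, 2, which.max)]
  M
}

#' Length distributions of a repertoire
#'
#' Histograms (exact integer keys) of total protein length, LRRv count and
#' core-loop length, with mean/SD summaries and a 24-aa lattice statistic:
#' the fraction of records whose total length falls in the modal residue
#' class mod 24 (length diversity is carried by whole 24-aa cassettes).
#'
#' @param annotations List of annotated `vlrb_annotation`.
#' @return A list with `protein_length`, `lrrv_count`, `core_loop_length`
#'   (tables), `summary` (data.frame) and `lattice_fraction`.
#' @export
length_distributions <- function(annotations) {
  ann <- Filter(function(a) a$status == "annotated", annotations)
  if (!length(ann)) stop("no annotated records")
  plen <- vapply(ann, function(a) nchar(a$protein), integer(1))
  kcnt <- vapply(ann, `[[`, integer(1), "lrrv_count")
  clen <- vapply(ann, function(a) span_length(a$spans$core_loop), integer(1))
  lat <- table(plen %% 24L)
  summ <- data.frame(
    quantity = c("protein_length", "lrrv_count", "core_loop_length"),
    mean = c(mean(plen), mean(kcnt), mean(clen)),
    sd = c(safe_sd(plen), safe_sd(kcnt), safe_sd(clen))
  )
  list(protein_length = table(plen), lrrv_count = table(kcnt),
       core_loop_length = table(clen), summary = summ,
       lattice_fraction = max(lat) / sum(lat))
}
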
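# Structural subunit annotation: SP, LRR-NT, LRR1, LRRv units (last = LRRve),
# CP, LRR-CT with core/extended loop, stalk.
#
# Motif matching is ungapped: a window matches iff every conserved residue of
# the motif is identical at its position.  All spans are 0-based half-open
# protein coordinates.

#' Detect the LRR1 subunit
#'
#' Scans 18-residue windows from the end of the signal peptide toward the CP
#' (window starts in `[sp_end, sp_end + lrrnt_len + margin]`); a window
#' matches iff all 5 conserved residues of the LRR1 motif
#' (`xLxLxxNxxxxLxxxxFx`) are identical at their positions.  The most
#' N-terminal matching window wins.
#'
#' @param protein Amino-acid string.
#' @param cfg A [vlrb_config()].
#' @param sp_end 0-based end of the signal peptide (default 21).
#' @return A `vlrb_span`, or `NULL` when no window matches.
#' @export
detect_lrr1 <- function(protein, cfg = vlrb_config(), sp_end = NULL) {
  len_spec <- cfg$subunit_length_spec
  if (is.null(sp_end)) sp_end <- len_spec[["SP"]]
  w <- nchar(cfg$lrr1_motif)
  L <- nchar(protein)
  last_start <- min(sp_end + len_spec[["LRR-NT"]] + cfg$lrr1_search_margin, L - w)
  if (last_start < sp_end) return(NULL)
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  starts <- sp_end:last_start           # 0-based window starts
  ok <- rep(TRUE, length(starts))
  cons <- cfg$lrr1_conserved
  for (r in seq_len(nrow(cons))) {
    ok <- ok & ch[starts + cons$index[r] + 1L] == cons$residue[r]
  }
  hit <- which(ok)
  if (!length(hit)) return(NULL)
  s <- starts[hit[1]]
  span(s, s + w)
}

# Does a 24-aa candidate unit contain the LRRv conserved leucines at some
# ungapped offset?
lrrv_unit_matches <- function(unit, cfg) {
  ch <- strsplit(unit, "", fixed = TRUE)[[1]]
  w <- nchar(cfg$lrrv_motif)
  cons <- cfg$lrrv_conserved
  for (off in 0:(length(ch) - w)) {
    if (all(ch[off + cons$index + 1L] == cons$residue)) return(TRUE)
  }
  FALSE
}

#' Detect the variable LRRv units
#'
#' Tiles the region from the end of LRR1 toward the stalk in successive
#' 24-aa candidate units; a unit is accepted iff the 4 conserved leucines of
#' the LRRv motif (`xLxxLxxLxLx`) match exactly at some offset within it.
#' Tiling stops at the first failing unit, which marks the start of the
#' CP/LRR-CT region.  The final accepted unit is the LRRve.
#'
#' @param protein Amino-acid string.
#' @param lrr1_end 0-based end of the LRR1 span.
#' @param stalk_start 0-based start of the stalk span.
#' @param cfg A [vlrb_config()].
#' @return A list of `vlrb_span`s (possibly length 0 when no unit matches).
#' @export
detect_lrrv_units <- function(protein, lrr1_end, stalk_start, cfg = vlrb_config()) {
  unit_len <- cfg$subunit_length_spec[["LRRv"]]
  spans <- list()
  pos <- lrr1_end
  while (pos + unit_len <= stalk_start) {
    unit <- substr(protein, pos + 1L, pos + unit_len)
    if (!lrrv_unit_matches(unit, cfg)) break
    spans[[length(spans) + 1L]] <- span(pos, pos + unit_len)
    pos <- pos + unit_len
  }
  spans
}

#' Detect the loop within an LRR-CT sequence
#'
#' Finds the anchor pair: the first tryptophan (W) of the LRR-CT and the
#' first cysteine (C) at least 7 residues downstream.  The core loop starts
#' at W + 4 and ends at C - 3 (inclusive); the extended loop spans W..C
#' inclusive, i.e. the core loop plus the 7 flanking residues
#' (`Wxxx-loop-xxC`).
#'
#' @param ct_seq LRR-CT amino-acid string.
#' @param cfg A [vlrb_config()].
#' @return A list with `core` and `extended` spans (0-based, relative to the
#'   LRR-CT start), or `NULL` when no valid anchor pair exists.
#' @export
detect_ct_loop <- function(ct_seq, cfg = vlrb_config()) {
  w1 <- regexpr("W", ct_seq, fixed = TRUE)[1]     # 1-based
  if (w1 < 0L) return(NULL)
  min_gap <- cfg$extended_loop_flank_total
  rest <- substr(ct_seq, w1 + min_gap, nchar(ct_seq))
  c_rel <- regexpr("C", rest, fixed = TRUE)[1]
  if (c_rel < 0L) return(NULL)
  W <- w1 - 1L                                    # 0-based
  C <- W + min_gap + c_rel - 1L                   # 0-based, >= W + 7
  list(core = span(W + cfg$loop_upstream_offset, C - cfg$loop_downstream_offset + 1L),
       extended = span(W, C + 1L))
}

#' Detect CP, LRR-CT and the loop
#'
#' Within `[lrrve_end, stalk_start)`, the connecting peptide is the first 11
#' residues and the LRR-CT is the remainder; the loop anchors are located by
#' [detect_ct_loop()].
#'
#' @param protein Amino-acid string.
#' @param lrrve_end 0-based end of the last LRRv unit.
#' @param stalk_start 0-based start of the stalk.
#' @param cfg A [vlrb_config()].
#' @return A list with spans `cp`, `ct`, `core_loop`, `extended_loop` (in
#'   protein coordinates), or `NULL` when the region is shorter than the CP
#'   or no anchor pair exists.
#' @export
detect_cp_ct_loop <- function(protein, lrrve_end, stalk_start, cfg = vlrb_config()) {
  cp_len <- cfg$subunit_length_spec[["CP"]]
  if (stalk_start - lrrve_end < cp_len) return(NULL)
  cp <- span(lrrve_end, lrrve_end + cp_len)
  ct <- span(cp$end, stalk_start)
  loop <- detect_ct_loop(span_seq(protein, ct), cfg)
  if (is.null(loop)) return(NULL)
  list(cp = cp, ct = ct,
       core_loop = span(ct$start + loop$core$start, ct$start + loop$core$end),
       extended_loop = span(ct$start + loop$extended$start, ct$start + loop$extended$end))
}

#' Annotate a VLRB protein
#'
#' Composes stalk anchoring, LRR1 detection, LRRv tiling and loop detection
#' into a full structural annotation.  SP is fixed at `[0, 21)` (single
#' germline SP locus) and LRR-NT is the residual `[21, lrr1.start)`.
#' Annotation failures are statuses, never errors: `no_lrr1`, `no_lrrv`,
#' `no_loop`, else `annotated`.
#'
#' @param protein Amino-acid string that passed the ORF/stalk filter.
#' @param cfg A [vlrb_config()].
#' @param stalk_span Optional precomputed stalk span (from [match_stalk()]);
#'   computed here when `NULL`.
#' @return An object of class `vlrb_annotation`: list with `protein`,
#'   `status`, `lrrv_count` and `spans` (`sp`, `lrr_nt`, `lrr1`, `lrrv` list,
#'   `cp`, `lrr_ct`, `core_loop`, `extended_loop`, `stalk`).
#' @export
annotate_protein <- function(protein, cfg = vlrb_config(), stalk_span = NULL) {
  ann <- structure(list(protein = protein, status = "annotated",
                        lrrv_count = 0L, spans = list()),
                   class = "vlrb_annotation")
  if (is.null(stalk_span)) {
    hit <- match_stalk(protein, cfg)
    if (is.null(hit)) { ann$status <- "no_stalk"; return(ann) }
    stalk_span <- hit$stalk_span
  }
  sp_len <- cfg$subunit_length_spec[["SP"]]
  lrr1 <- detect_lrr1(protein, cfg)
  if (is.null(lrr1)) { ann$status <- "no_lrr1"; return(ann) }
  lrrv <- detect_lrrv_units(protein, lrr1$end, stalk_span$start, cfg)
  if (length(lrrv) == 0L) { ann$status <- "no_lrrv"; return(ann) }
  lrrve_end <- lrrv[[length(lrrv)]]$end
  cpl <- detect_cp_ct_loop(protein, lrrve_end, stalk_span$start, cfg)
  if (is.null(cpl)) { ann$status <- "no_loop"; return(ann) }
  ann$lrrv_count <- length(lrrv)
  ann$spans <- list(
    sp = span(0L, sp_len),
    lrr_nt = span(sp_len, lrr1$start),
    lrr1 = lrr1,
    lrrv = lrrv,
    cp = cpl$cp,
    lrr_ct = cpl$ct,
    core_loop = cpl$core_loop,
    extended_loop = cpl$extended_loop,
    stalk = stalk_span
  )
  ann
}

#' @export
print.vlrb_annotation <- function(x, ...) {
  cat(sprintf("VLRB annotation: status=%s, lrrv_count=%d, length=%d aa\n",
              x$status, x$lrrv_count, nchar(x$protein)))
  invisible(x)
}

#' Annotate a set of unique proteins
#'
#' @param proteins Data.frame from [dedup_proteins()] (`sample_id`,
#'   `protein`, `abundance`, `stalk_start`, `stalk_end`).
#' @param cfg A [vlrb_config()].
#' @return A list with `annotations` (list of `vlrb_annotation`, one per
#'   row, carrying `sample_id` and `abundance` as fields) and
#'   `status_counts` (named integer vector).
#' @export
annotate_set <- function(proteins, cfg = vlrb_config()) {
  n <- nrow(proteins)
  anns <- vector("list", n)
  for (i in seq_len(n)) {
    ssp <- if (!is.na(proteins$stalk_start[i])) {
      span(proteins$stalk_start[i], proteins$stalk_end[i])
    } else NULL
    a <- annotate_protein(proteins$protein[i], cfg, stalk_span = ssp)
    a$sample_id <- proteins$sample_id[i]
    a$abundance <- proteins$abundance[i]
    anns[[i]] <- a
  }
  status <- vapply(anns, `[[`, character(1), "status")
  list(annotations = anns,
       status_counts = c(annotated = sum(status == "annotated"),
                         no_lrr1 = sum(status == "no_lrr1"),
                         no_lrrv = sum(status == "no_lrrv"),
                         no_loop = sum(status == "no_loop")))
}
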
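# Pipeline configuration: every printed constant of the wet-lab protocol and
# the analysis thresholds, validated and with derived fields cached.

DEFAULT_BARCODES <- c(
  larva1 = "ACGTAC", larva2 = "TGCAGT", larva3 = "CAGTCA",
  larva4 = "GTCATG", larva5 = "ATCGGA", larva6 = "GCATCC"
)

#' Build a pipeline configuration
#'
#' Returns the default configuration describing the VLRB amplicon design and
#' all analysis thresholds: the RT oligonucleotide (stalk-annealing segment,
#' 12-nt UMI marked by N, antisense-primer annealing segment), the forward and
#' reverse PCR primers with their 6-nt sample barcodes, the 30-aa diagnostic
#' stalk motif, the LRR1 and LRRv motifs with their conserved residues, the
#' canonical subunit lengths, the loop-anchor offsets and the clustering and
#' hydropathy thresholds.  Any field can be overridden via `...`; the result
#' is validated by [validate_config()].
#'
#' @param ... Named overrides of default fields.
#' @return A validated list of class `vlrb_config`.
#' @examples
#' cfg <- vlrb_config()
#' cfg$umi_length
#' @export
vlrb_config <- function(...) {
  cfg <- list(
    rt_oligo = paste0("TATTTCCAGCACACTGGATCAG",
                      strrep("N", 12), "TCAACGTTTCCTGCAGAGGGCG"),
    fwd_primer = paste0("TAT", strrep("N", 6), "gtggatcaagtggatcgc"),
    rev_primer = paste0("TAT", strrep("N", 6), "CCAGCACACTGGATCAG"),
    barcode_table = DEFAULT_BARCODES,
    umi_length = 12L,
    umi_collapse_identity = 0.99,
    umi_neighbor_distance = 1L,
    stalk_motif = "DCGKPACTTLLNCANFLSCLCSTCALCRKR",
    stalk_max_mismatch = 2L,
    lrr1_motif = "xLxLxxNxxxxLxxxxFx",
    lrrv_motif = "xLxxLxxLxLx",
    lrrv_min_segment = 15L,
    subunit_length_spec = c(SP = 21L, "LRR-NT" = 31L, LRR1 = 18L,
                            LRRv = 24L, CP = 11L, stalk = 87L),
    loop_upstream_offset = 4L,
    loop_downstream_offset = 3L,
    extended_loop_flank_total = 7L,
    hydropathy_split = 0.35,
    clustering_thresholds = c(0.65, 0.70, 0.75, 0.85, 0.95, 1.00),
    lrr1_search_margin = 20L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(structure(cfg, class = "vlrb_config"))
}

#' Validate a pipeline configuration
#'
#' Checks every configuration invariant (UMI length equals the N-run in the
#' RT oligo, 6-nt pairwise-distinct barcodes, canonical stalk-motif alphabet,
#' loop-offset arithmetic, thresholds in (0, 1], strictly positive lengths)
#' and caches derived fields: the constant primer segments, the stalk
#' annealing segment, and the conserved positions of the LRR1/LRRv motifs.
#' The first violated invariant is reported by name.
#'
#' @param cfg A `vlrb_config` list.
#' @return The validated config with derived fields filled in.
#' @export
validate_config <- function(cfg) {
  umi_run <- regmatches(cfg$rt_oligo, regexpr("N+", cfg$rt_oligo))
  if (length(umi_run) != 1L || nchar(umi_run) != cfg$umi_length) {
    stop("umi_length != N-run length in rt_oligo")
  }
  bc <- cfg$barcode_table
  if (any(nchar(bc) != 6L)) stop("barcode length != 6")
  if (anyDuplicated(bc)) stop("barcodes not pairwise distinct")
  if (is.null(names(bc)) || any(!nzchar(names(bc)))) stop("barcodes must be named by sample id")
  sm <- strsplit(cfg$stalk_motif, "", fixed = TRUE)[[1]]
  if (!all(sm %in% AA20)) stop("stalk_motif contains non-canonical residues")
  if (cfg$extended_loop_flank_total !=
      cfg$loop_upstream_offset + cfg$loop_downstream_offset) {
    stop("extended_loop_flank_total != loop_upstream_offset + loop_downstream_offset")
  }
  fr <- c(cfg$umi_collapse_identity, cfg$clustering_thresholds)
  if (any(fr <= 0 | fr > 1)) stop("thresholds must lie in (0, 1]")
  if (any(cfg$subunit_length_spec <= 0L) || cfg$umi_length <= 0L) {
    stop("lengths must be strictly positive")
  }

  # derived, cached fields
  cfg$fwd_const <- toupper(sub("^TATN{6}", "", cfg$fwd_primer, ignore.case = FALSE))
  cfg$rev_const <- toupper(sub("^TATN{6}", "", cfg$rev_primer))
  parts <- strsplit(cfg$rt_oligo, "N+")[[1]]
  cfg$stalk_anneal <- parts[2]
  cfg$lrr1_conserved <- conserved_positions(cfg$lrr1_motif)
  cfg$lrrv_conserved <- conserved_positions(cfg$lrrv_motif)
  stalk_len <- cfg$subunit_length_spec[["stalk"]]
  if (stalk_len < nchar(cfg$stalk_motif)) stop("stalk length shorter than stalk motif")
  cfg$stalk_motif_offset <- stalk_len - nchar(cfg$stalk_motif)  # motif ends at stalk terminus
  cfg
}

#' Conserved positions of a wildcard motif
#'
#' Motifs use `x` as wildcard and upper-case amino-acid letters at conserved
#' positions, e.g. the LRR1 motif `xLxLxxNxxxxLxxxxFx` has 5 conserved
#' residues.
#'
#' @param motif Pattern string of `x` and amino-acid letters.
#' @return A data.frame with 0-based `index` and `residue` for every
#'   non-wildcard position, in order.
#' @examples
#' conserved_positions("xLxxLxxLxLx")  # 4 conserved leucines
#' @export
conserved_positions <- function(motif) {
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  ok <- ch == "x" | ch %in% AA20
  if (!all(ok)) stop("illegal character in motif: ", paste(unique(ch[!ok]), collapse = ""))
  keep <- ch != "x"
  data.frame(index = which(keep) - 1L, residue = ch[keep],
             stringsAsFactors = FALSE)
}

#' Read a configuration file
#'
#' Configuration files are flat YAML; fields absent from the file keep their
#' defaults.
#'
#' @param path Path to a YAML config file.
#' @return A validated `vlrb_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$barcode_table)) raw$barcode_table <- unlist(raw$barcode_table)
  if (!is.null(raw$subunit_length_spec)) {
    raw$subunit_length_spec <- vapply(raw$subunit_length_spec, as.integer, integer(1))
  }
  for (f in c("umi_length", "umi_neighbor_distance", "stalk_max_mismatch",
              "lrrv_min_segment", "loop_upstream_offset",
              "loop_downstream_offset", "extended_loop_flank_total",
              "lrr1_search_margin")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.integer(raw[[f]])
  }
  do.call(vlrb_config, raw)
}

#' Write a configuration file
#'
#' Serializes the user-settable fields (derived fields are recomputed on
#' load) so that a written config reloads field-by-field equal.
#'
#' @param cfg A `vlrb_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  keep <- c("rt_oligo", "fwd_primer", "rev_primer", "barcode_table",
            "umi_length", "umi_collapse_identity", "umi_neighbor_distance",
            "stalk_motif", "stalk_max_mismatch", "lrr1_motif", "lrrv_motif",
            "lrrv_min_segment", "subunit_length_spec", "loop_upstream_offset",
            "loop_downstream_offset", "extended_loop_flank_total",
            "hydropathy_split", "clustering_thresholds", "lrr1_search_margin")
  out <- cfg[keep]
  out$barcode_table <- as.list(cfg$barcode_table)
  out$subunit_length_spec <- as.list(cfg$subunit_length_spec)
  yaml::write_yaml(out, path)
  invisible(path)
}
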
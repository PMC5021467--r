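#' Validate an amplicon by region-of-interest coverage
#'
#' An amplicon is considered correctly sequenced only if every nucleotide of
#' its region of interest is covered by at least `config$min_depth` reads
#' (both strands summed); only the minimum over the region matters. Failing
#' positions are returned for the resequencing worklist.
#'
#' @param columns Pileup columns from [call_pileup()].
#' @param roi Integer vector of 0-based reference positions (non-empty).
#' @param config A [filter_config()].
#' @return List with `validated` (logical), `min_depth` (observed minimum)
#'   and `failing` (tibble of failing positions and their depths).
#' @export
validate_amplicon <- function(columns, roi, config = filter_config()) {
  if (length(roi) == 0) stop("empty region of interest")
  if (any(roi < 0 | roi >= nrow(columns)))
    stop("region of interest outside amplicon")
  d <- columns$depth_forward[roi + 1L] + columns$depth_reverse[roi + 1L]
  failing <- tibble::tibble(position = roi[d < config$min_depth],
                            depth = d[d < config$min_depth])
  list(validated = all(d >= config$min_depth),
       min_depth = min(d),
       failing = failing)
}

#' Filter candidate variants
#'
#' Applies the screening rules to raw variant calls. A variant is validated
#' when (in this order of precedence for the rejection label):
#' \enumerate{
#'   \item it is supported by at least `min_variant_reads` reads
#'     (`rejected_support` otherwise — eliminates random sequencing errors);
#'   \item it is seen on both strands, unless one strand has no coverage at
#'     all at the anchor position (`rejected_strand`);
#'   \item its allele fraction is at least `min_variant_fraction`
#'     (`rejected_frequency`).
#' }
#' Detection is independent of amplicon validation: calls in insufficiently
#' covered amplicons are still made, and `amplicon_validated` is recorded
#' alongside so the report can flag them.
#'
#' @param raw Variants tibble from [call_pileup()]; needs columns
#'   `reads_forward`, `reads_reverse`, `fraction`, and per-strand coverage
#'   `coverage_forward`, `coverage_reverse` (added automatically from
#'   `columns` when supplied).
#' @param config A [filter_config()].
#' @param amplicon_validated Logical flag from [validate_amplicon()].
#' @param columns Optional pileup columns; used to look up per-strand
#'   coverage at each variant's anchor when `raw` lacks coverage columns.
#' @return `raw` with `status` (one of `validated`, `rejected_support`,
#'   `rejected_strand`, `rejected_frequency`), `validated` (logical) and
#'   `amplicon_validated` columns.
#' @export
filter_variants <- function(raw, config = filter_config(),
                            amplicon_validated = TRUE, columns = NULL) {
  if (!all(c("coverage_forward", "coverage_reverse") %in% names(raw))) {
    if (is.null(columns))
      stop("supply `columns` or coverage_forward/coverage_reverse columns")
    raw$coverage_forward <- columns$depth_forward[raw$anchor + 1L]
    raw$coverage_reverse <- columns$depth_reverse[raw$anchor + 1L]
  }
  support <- raw$reads_forward + raw$reads_reverse
  status <- rep("validated", nrow(raw))
  strand_fail <- config$require_both_strands &
    ((raw$reads_forward == 0 & raw$coverage_forward >= 1) |
       (raw$reads_reverse == 0 & raw$coverage_reverse >= 1))
  status[raw$fraction < config$min_variant_fraction] <- "rejected_frequency"
  status[strand_fail] <- "rejected_strand"
  status[support < config$min_variant_reads] <- "rejected_support"
  raw$status <- status
  raw$validated <- status == "validated"
  raw$amplicon_validated <- amplicon_validated
  raw
}

#' Region-of-interest positions per amplicon
#'
#' For each exon of the gene model, takes the genomic interval
#' `[exon_start - roi_upstream, exon_end + roi_downstream)`, unions the
#' intervals, and intersects with each amplicon's span. Coordinates are
#' 0-based half-open on the gene genomic sequence (coding orientation);
#' returned positions are 0-based on each amplicon reference.
#'
#' @param gene_model A [gene_model()] (needs `exons` with `start`, `end`).
#' @param amplicons An [amplicon_defs()] tibble.
#' @param config A [filter_config()] supplying `roi_upstream`,
#'   `roi_downstream`.
#' @return Named list, amplicon name -> integer vector of 0-based amplicon
#'   positions. Exons covered by no amplicon trigger a warning.
#' @export
roi_positions <- function(gene_model, amplicons, config = filter_config()) {
  ex <- gene_model$exons
  roi_genomic <- sort(unique(unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq.int(max(0L, ex$start[i] - config$roi_upstream),
            ex$end[i] + config$roi_downstream - 1L)
  }))))
  spans <- lapply(seq_len(nrow(amplicons)), function(i) {
    off <- amplicons$genomic_offset[i]
    seq.int(off, off + nchar(amplicons$reference[i]) - 1L)
  })
  covered <- sort(unique(unlist(spans)))
  for (i in seq_len(nrow(ex))) {
    body <- seq.int(ex$start[i], ex$end[i] - 1L)
    if (!all(body %in% covered))
      warning("exon ", i, " [", ex$start[i], ", ", ex$end[i],
              ") not fully covered by any amplicon")
  }
  out <- lapply(seq_len(nrow(amplicons)), function(i) {
    g <- intersect(roi_genomic, spans[[i]])
    as.integer(g - amplicons$genomic_offset[i])
  })
  names(out) <- amplicons$name
  out
}
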
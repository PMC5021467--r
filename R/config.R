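#' Variant-filtering thresholds
#'
#' Bundle of the screening thresholds applied when validating amplicons and
#' variant calls. The defaults are the ones used for diagnostic amplicon
#' resequencing of the BRCA genes: an amplicon is considered correctly
#' sequenced only when every nucleotide of its region of interest is covered
#' by at least `min_depth` reads; a variant is kept when it is seen in at
#' least `min_variant_reads` reads, on both strands (unless one strand has no
#' coverage at all), and in at least `min_variant_fraction` of the reads
#' covering its position. The region of interest extends each exon by
#' `roi_upstream` bases 5' and `roi_downstream` bases 3' so that splice sites
#' are screened.
#'
#' All "at least" thresholds are inclusive: fraction exactly equal to
#' `min_variant_fraction` passes, depth exactly `min_depth` validates.
#'
#' @param min_depth Minimum per-nucleotide read depth to validate an amplicon
#'   (default 40).
#' @param min_variant_fraction Minimum fraction of reads carrying the variant
#'   (default 0.20).
#' @param min_variant_reads Minimum number of supporting reads (default 4).
#' @param roi_upstream Bases added before each exon start (default 20).
#' @param roi_downstream Bases added after each exon end (default 6).
#' @param require_both_strands Require support on both strands when both
#'   strands have coverage (default TRUE).
#' @return A list of class `filter_config`.
#' @examples
#' filter_config()
#' filter_config(min_depth = 100, min_variant_fraction = 0.1)
#' @export
filter_config <- function(min_depth = 40,
                          min_variant_fraction = 0.20,
                          min_variant_reads = 4,
                          roi_upstream = 20,
                          roi_downstream = 6,
                          require_both_strands = TRUE) {
  stopifnot(
    is.numeric(min_depth), length(min_depth) == 1, min_depth >= 1,
    is.numeric(min_variant_fraction), length(min_variant_fraction) == 1,
    min_variant_fraction > 0, min_variant_fraction <= 1,
    is.numeric(min_variant_reads), length(min_variant_reads) == 1,
    min_variant_reads >= 1,
    is.numeric(roi_upstream), roi_upstream >= 0,
    is.numeric(roi_downstream), roi_downstream >= 0,
    is.logical(require_both_strands), length(require_both_strands) == 1
  )
  structure(
    list(
      min_depth = as.integer(min_depth),
      min_variant_fraction = as.numeric(min_variant_fraction),
      min_variant_reads = as.integer(min_variant_reads),
      roi_upstream = as.integer(roi_upstream),
      roi_downstream = as.integer(roi_downstream),
      require_both_strands = require_both_strands
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat("  min depth to validate amplicon :", x$min_depth, "reads\n")
  cat("  min variant fraction           :", x$min_variant_fraction, "\n")
  cat("  min supporting reads           :", x$min_variant_reads, "\n")
  cat("  region of interest             : exon -", x$roi_upstream,
      "/ +", x$roi_downstream, "\n")
  cat("  require both strands           :", x$require_both_strands, "\n")
  invisible(x)
}

#' Alignment scoring parameters
#'
#' Scores used for semi-global (free end gap) alignment of reads against
#' amplicon references, with affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend`. Reads whose best alignment identity
#' (matches / aligned columns) falls below `min_identity` are discarded to the
#' unaligned bin.
#'
#' @param match Match reward (default 2).
#' @param mismatch Mismatch penalty, negative (default -3).
#' @param gap_open Gap opening penalty, negative (default -5).
#' @param gap_extend Per-base gap extension penalty, negative (default -2).
#' @param min_identity Identity floor in `[0, 1]` (default 0.8).
#' @return A list of class `align_config`.
#' @export
align_config <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2, min_identity = 0.8) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            min_identity >= 0, min_identity <= 1)
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, min_identity = min_identity),
    class = "align_config"
  )
}

#' Homopolymer review parameters
#'
#' Controls detection and (optional) automatic classification of candidate
#' indels in homopolymer context. By default `mode = "manual"`: histograms and
#' sidecars are produced for user review and every homopolymer-context variant
#' is flagged for manual interpretation. With `mode = "auto"` the
#' Gaussian-mixture classifier assigns the label.
#'
#' @param min_run_length Minimum run length for a base run to count as a
#'   homopolymer context (default 3).
#' @param mode `"manual"` or `"auto"`.
#' @param min_separation Minimum distance between mixture component means, in
#'   flow units, to call a bimodal (heterozygous) pattern (default 0.5).
#' @param max_center_offset Maximum distance between a single component mean
#'   and an integer run length to call wild type / homozygous (default 0.25).
#' @param variance_floor Lower bound for mixture component variances
#'   (default 1e-3).
#' @return A list of class `hp_config`.
#' @export
hp_config <- function(min_run_length = 3, mode = c("manual", "auto"),
                      min_separation = 0.5, max_center_offset = 0.25,
                      variance_floor = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(min_run_length >= 2, min_separation > 0,
            max_center_offset > 0, max_center_offset < 0.5,
            variance_floor > 0)
  structure(
    list(min_run_length = as.integer(min_run_length), mode = mode,
         min_separation = min_separation,
         max_center_offset = max_center_offset,
         variance_floor = variance_floor),
    class = "hp_config"
  )
}
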
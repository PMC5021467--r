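#' Define amplicons
#'
#' One row per amplicon: the primer-inclusive reference sequence, the 0-based
#' offset of its first base on the gene's genomic sequence (coding
#' orientation), and the PCR primers. Primers must be a prefix of the
#' reference (forward) and the reverse complement of a suffix (reverse).
#'
#' @param name Amplicon names (unique).
#' @param reference Uppercase ACGT(N) reference sequences.
#' @param genomic_offset 0-based offsets on the gene genomic sequence.
#' @param forward_primer,reverse_primer Primer sequences (may be `""`).
#' @return A tibble with class `amplicon_defs`.
#' @export
amplicon_defs <- function(name, reference, genomic_offset,
                          forward_primer = "", reverse_primer = "") {
  out <- tibble::tibble(
    name = as.character(name),
    reference = toupper(as.character(reference)),
    genomic_offset = as.integer(genomic_offset),
    forward_primer = toupper(as.character(forward_primer)),
    reverse_primer = toupper(as.character(reverse_primer))
  )
  if (anyDuplicated(out$name)) stop("amplicon names must be unique")
  for (i in seq_len(nrow(out))) {
    r <- out$reference[[i]]
    if (nchar(r) == 0 || grepl("[^ACGTN]", r))
      stop("amplicon ", out$name[[i]],
           ": reference must be non-empty uppercase ACGT(N)")
    fp <- out$forward_primer[[i]]
    if (nchar(fp) > 0 && substr(r, 1, nchar(fp)) != fp)
      stop("amplicon ", out$name[[i]],
           ": forward primer is not a prefix of the reference")
    rp <- out$reverse_primer[[i]]
    if (nchar(rp) > 0 &&
        substr(r, nchar(r) - nchar(rp) + 1L, nchar(r)) != revcomp(rp))
      stop("amplicon ", out$name[[i]],
           ": reverse primer is not the reverse complement of the ",
           "reference suffix")
  }
  class(out) <- c("amplicon_defs", class(out))
  out
}

#' Read amplicon definitions from TSV
#'
#' Expected columns: `name`, `reference`, `genomic_offset`, and optionally
#' `forward_primer`, `reverse_primer`.
#'
#' @param path TSV file path.
#' @return An [amplicon_defs()] tibble.
#' @export
read_amplicons <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  get_primer <- function(col) {
    if (!col %in% names(d)) return("")
    tidyr::replace_na(as.character(d[[col]]), "")
  }
  amplicon_defs(
    d$name, d$reference, d$genomic_offset,
    forward_primer = get_primer("forward_primer"),
    reverse_primer = get_primer("reverse_primer")
  )
}

#' Write amplicon definitions to TSV
#' @param amplicons An [amplicon_defs()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(amplicons, path) {
  readr::write_tsv(tibble::as_tibble(amplicons), path)
  invisible(path)
}
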
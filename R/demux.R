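hamming_prefix <- function(s, prefix) {
  # mismatches between prefix and the first nchar(prefix) chars of s
  n <- nchar(prefix)
  if (nchar(s) < n) return(n)
  sum(strsplit(substr(s, 1, n), "")[[1]] != strsplit(prefix, "")[[1]])
}

#' Demultiplex reads by MID barcode
#'
#' Assigns each read to the unique sample whose MID matches the read's 5'
#' end within `max_mismatch` mismatches; matched MID bases are trimmed from
#' the read (bases, qualities and flow indices; the flow values stay intact,
#' so flow lookups on remaining bases remain valid). Reads matching no MID, or
#' more than one, go to the unassigned bin.
#'
#' @param reads A [flow_reads()] tibble.
#' @param mids Named character vector, `sample -> MID sequence`. MIDs must be
#'   mutually distinct at Hamming distance > 2 over their common prefix
#'   length, otherwise single-mismatch assignment could be ambiguous.
#' @param max_mismatch Allowed mismatches in the MID match (default 1).
#' @return The input tibble with a `sample` column (`NA` for unassigned) and
#'   MID bases trimmed from assigned reads.
#' @export
demultiplex <- function(reads, mids, max_mismatch = 1L) {
  stopifnot(length(mids) >= 1, !is.null(names(mids)))
  if (length(mids) > 1) {
    for (i in seq_len(length(mids) - 1)) {
      for (j in seq.int(i + 1, length(mids))) {
        n <- min(nchar(mids[[i]]), nchar(mids[[j]]))
        d <- sum(strsplit(substr(mids[[i]], 1, n), "")[[1]] !=
                   strsplit(substr(mids[[j]], 1, n), "")[[1]])
        if (d <= 2)
          stop("MIDs for ", names(mids)[i], " and ", names(mids)[j],
               " are within Hamming distance 2; assignment would be ",
               "ambiguous")
      }
    }
  }
  sample_col <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    d <- vapply(mids, function(m) hamming_prefix(reads$bases[[i]], m),
                numeric(1))
    hits <- which(d <= max_mismatch)
    if (length(hits) == 1) {
      s <- names(mids)[hits]
      sample_col[i] <- s
      k <- nchar(mids[[hits]])
      nb <- nchar(reads$bases[[i]])
      reads$bases[[i]] <- substr(reads$bases[[i]], k + 1L, nb)
      reads$quality[[i]] <- reads$quality[[i]][-seq_len(k)]
      reads$flow_index[[i]] <- reads$flow_index[[i]][-seq_len(k)]
    }
  }
  reads$sample <- sample_col
  reads
}
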
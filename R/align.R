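#' Align reads to amplicon references
#'
#' Semi-global alignment (free end gaps) of each read against every amplicon
#' in both orientations; the best-scoring combination wins. Affine gap
#' penalties: a gap of length L costs `gap_open + L * gap_extend`. Reads
#' whose best alignment identity (matches / aligned columns) falls below the
#' configured floor are kept in the table with `aligned = FALSE` so they can
#' be counted and logged.
#'
#' Reverse-orientation reads are aligned as their reverse complement, so the
#' stored gapped strings and coordinates are in amplicon orientation;
#' `strand` records the original orientation.
#'
#' @param reads A [flow_reads()] tibble (typically clipped and
#'   demultiplexed).
#' @param amplicons An [amplicon_defs()] tibble.
#' @param config An [align_config()].
#' @return A tibble with one row per read: `name`, `amplicon`, `strand`
#'   (`"+"`/`"-"`), `score`, `identity`, `aligned`, `subject_start`
#'   (1-based first aligned amplicon base), `pattern_gapped`,
#'   `subject_gapped` (aligned strings with `-` gaps, amplicon orientation),
#'   `read_length`.
#' @export
align_reads <- function(reads, amplicons, config = align_config()) {
  stopifnot(nrow(amplicons) >= 1)
  n <- nrow(reads)
  empty <- tibble::tibble(
    name = character(), amplicon = character(), strand = character(),
    score = numeric(), identity = numeric(), aligned = logical(),
    subject_start = integer(), pattern_offset = integer(),
    pattern_gapped = character(), subject_gapped = character(),
    read_length = integer()
  )
  if (n == 0) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE)
  # Biostrings charges gapOpening + L*gapExtension per gap, as do we
  go <- -config$gap_open
  ge <- -config$gap_extend

  ok <- nchar(reads$bases) > 0 & !grepl("[^ACGT]", reads$bases)
  fwd <- Biostrings::DNAStringSet(ifelse(ok, reads$bases, "A"))
  rev <- Biostrings::reverseComplement(fwd)

  n_amp <- nrow(amplicons)
  scores <- array(-Inf, dim = c(n, n_amp, 2))
  subjects <- lapply(amplicons$reference, Biostrings::DNAString)
  for (a in seq_len(n_amp)) {
    scores[, a, 1] <- Biostrings::pairwiseAlignment(
      fwd, subjects[[a]], type = "overlap", substitutionMatrix = mat,
      gapOpening = go, gapExtension = ge, scoreOnly = TRUE)
    scores[, a, 2] <- Biostrings::pairwiseAlignment(
      rev, subjects[[a]], type = "overlap", substitutionMatrix = mat,
      gapOpening = go, gapExtension = ge, scoreOnly = TRUE)
  }

  best_amp <- integer(n); best_ori <- integer(n); best_score <- numeric(n)
  for (i in seq_len(n)) {
    m <- scores[i, , , drop = FALSE]
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    best_amp[i] <- idx[2]; best_ori[i] <- idx[3]; best_score[i] <- max(m)
  }

  out <- tibble::tibble(
    name = reads$name, amplicon = amplicons$name[best_amp],
    strand = c("+", "-")[best_ori], score = best_score,
    identity = NA_real_, aligned = FALSE, subject_start = NA_integer_,
    pattern_offset = NA_integer_, pattern_gapped = NA_character_,
    subject_gapped = NA_character_, read_length = nchar(reads$bases)
  )
  # full alignments per (amplicon, orientation) group
  for (a in seq_len(n_amp)) {
    for (o in 1:2) {
      idx <- which(ok & best_amp == a & best_ori == o)
      if (length(idx) == 0) next
      pat <- if (o == 1) fwd[idx] else rev[idx]
      aln <- Biostrings::pairwiseAlignment(
        pat, subjects[[a]], type = "overlap", substitutionMatrix = mat,
        gapOpening = go, gapExtension = ge)
      pg <- as.character(Biostrings::alignedPattern(aln))
      sg <- as.character(Biostrings::alignedSubject(aln))
      nmatch <- Biostrings::nmatch(aln)
      width <- nchar(pg)
      ident <- ifelse(width > 0, nmatch / width, 0)
      out$identity[idx] <- ident
      out$subject_start[idx] <-
        BiocGenerics::start(Biostrings::subject(aln))
      out$pattern_offset[idx] <-
        BiocGenerics::start(Biostrings::pattern(aln)) - 1L
      out$pattern_gapped[idx] <- pg
      out$subject_gapped[idx] <- sg
      out$aligned[idx] <- ident >= config$min_identity
    }
  }
  out
}
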
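#' Shift an indel to its leftmost equivalent placement
#'
#' Rolls a pure insertion or deletion left through repeat context so every
#' alignment of the same event counts toward a single anchor, whatever strand
#' or gap placement the aligner chose. HGVS 3'-shifting is applied later, at
#' annotation time; this canonicalization is purely internal.
#'
#' @param reference Reference string the event lives on.
#' @param position 0-based position: the event applies before/at reference
#'   base `position` (deletion: first deleted base; insertion: inserted
#'   before this base).
#' @param ref Deleted bases (`""` for insertion).
#' @param alt Inserted bases (`""` for deletion).
#' @return List with shifted `position`, `ref`, `alt`.
#' @keywords internal
left_shift_indel <- function(reference, position, ref, alt) {
  moving <- if (nchar(ref) > 0 && nchar(alt) == 0) "ref"
            else if (nchar(alt) > 0 && nchar(ref) == 0) "alt"
            else return(list(position = position, ref = ref, alt = alt))
  s <- if (moving == "ref") ref else alt
  p <- position
  while (p > 0) {
    prev <- substr(reference, p, p)
    if (prev != substr(s, nchar(s), nchar(s))) break
    s <- paste0(prev, substr(s, 1, nchar(s) - 1))
    p <- p - 1L
  }
  if (moving == "ref") list(position = p, ref = s, alt = "")
  else list(position = p, ref = "", alt = s)
}

read_events <- function(pattern_gapped, subject_gapped, subject_start,
                        reference) {
  # events from one gapped alignment pair, amplicon orientation;
  # insertion-before-position semantics, left-normalised
  p <- strsplit(pattern_gapped, "")[[1]]
  s <- strsplit(subject_gapped, "")[[1]]
  refpos <- subject_start - 1L   # 0-based
  evs <- list(); k <- 0L
  cur <- NULL  # open gap event: list(kind, pos, seq)
  flush <- function() {
    if (!is.null(cur)) { k <<- k + 1L; evs[[k]] <<- cur; cur <<- NULL }
  }
  for (i in seq_along(p)) {
    if (s[i] == "-") {              # insertion in read
      if (!is.null(cur) && cur$kind == "ins" && cur$pos == refpos)
        cur$seq <- paste0(cur$seq, p[i])
      else { flush(); cur <- list(kind = "ins", pos = refpos, seq = p[i]) }
    } else if (p[i] == "-") {       # deletion from read
      if (!is.null(cur) && cur$kind == "del" &&
          cur$pos + nchar(cur$seq) == refpos)
        cur$seq <- paste0(cur$seq, s[i])
      else { flush(); cur <- list(kind = "del", pos = refpos, seq = s[i]) }
      refpos <- refpos + 1L
    } else {
      flush()
      if (p[i] != s[i]) {
        k <- k + 1L
        evs[[k]] <- list(kind = "sub", pos = refpos, seq = s[i], alt = p[i])
      }
      refpos <- refpos + 1L
    }
  }
  flush()
  if (k == 0) return(list())
  # merge immediately adjacent del+ins (either order) into delins
  out <- list(); j <- 0L; i <- 1L
  while (i <= k) {
    e <- evs[[i]]
    if (i < k) {
      nx <- evs[[i + 1]]
      if (e$kind == "del" && nx$kind == "ins" &&
          nx$pos == e$pos + nchar(e$seq)) {
        j <- j + 1L
        out[[j]] <- list(kind = "delins", pos = e$pos, ref = e$seq,
                         alt = nx$seq)
        i <- i + 2L; next
      }
      if (e$kind == "ins" && nx$kind == "del" && nx$pos == e$pos) {
        j <- j + 1L
        out[[j]] <- list(kind = "delins", pos = nx$pos, ref = nx$seq,
                         alt = e$seq)
        i <- i + 2L; next
      }
    }
    j <- j + 1L
    out[[j]] <- switch(e$kind,
      sub = list(kind = "sub", pos = e$pos, ref = e$seq, alt = e$alt),
      del = c(list(kind = "del"),
              left_shift_indel(reference, e$pos, e$seq, "")),
      ins = c(list(kind = "ins"),
              left_shift_indel(reference, e$pos, "", e$seq)))
    i <- i + 1L
  }
  out
}

#' Build a pileup and call candidate variants
#'
#' Counts, for every amplicon reference position, the spanning reads per
#' strand, and emits every non-reference event observed in at least one read
#' as a candidate (raw) variant with per-strand support and allele fraction.
#' Insertions are anchored to the reference base after which they occur,
#' deletions to their first deleted base; equivalent indel placements in
#' repeat context are collapsed to one anchor before counting.
#'
#' @param alignments Tibble from [align_reads()], restricted to one amplicon
#'   (rows for other amplicons or with `aligned = FALSE` are dropped).
#' @param amplicon One-row [amplicon_defs()] slice.
#' @return List with `columns` (tibble: `position` 0-based, `ref_base`,
#'   `depth_forward`, `depth_reverse`, `match_forward`, `match_reverse`) and
#'   `variants` (tibble: `amplicon`, `position` 0-based event position with
#'   insertion-before semantics, `anchor` 0-based anchor column, `kind`,
#'   `ref`, `alt`, `reads_forward`, `reads_reverse`, `depth`, `fraction`).
#' @export
call_pileup <- function(alignments, amplicon) {
  stopifnot(nrow(amplicon) == 1)
  reference <- amplicon$reference[[1]]
  L <- nchar(reference)
  aln <- alignments[alignments$aligned & alignments$amplicon ==
                      amplicon$name[[1]], , drop = FALSE]
  ref_chars <- strsplit(reference, "")[[1]]
  dep_f <- integer(L); dep_r <- integer(L)
  mat_f <- integer(L); mat_r <- integer(L)
  ev_key <- character(0); ev_fwd <- integer(0); ev_rev <- integer(0)
  ev_meta <- list()

  for (i in seq_len(nrow(aln))) {
    fwd <- aln$strand[[i]] == "+"
    sp <- aln$subject_start[[i]]
    ns <- sum(strsplit(aln$subject_gapped[[i]], "")[[1]] != "-")
    span <- seq.int(sp, sp + ns - 1L)          # 1-based covered columns
    if (fwd) dep_f[span] <- dep_f[span] + 1L
    else dep_r[span] <- dep_r[span] + 1L

    p <- strsplit(aln$pattern_gapped[[i]], "")[[1]]
    s <- strsplit(aln$subject_gapped[[i]], "")[[1]]
    keep <- s != "-"
    eq <- p[keep] == s[keep]
    cols <- span[eq]
    if (fwd) mat_f[cols] <- mat_f[cols] + 1L
    else mat_r[cols] <- mat_r[cols] + 1L

    evs <- read_events(aln$pattern_gapped[[i]], aln$subject_gapped[[i]],
                       sp, reference)
    for (e in evs) {
      key <- paste(e$kind, e$pos, e$ref, e$alt, sep = "|")
      j <- match(key, ev_key)
      if (is.na(j)) {
        ev_key <- c(ev_key, key)
        ev_fwd <- c(ev_fwd, 0L); ev_rev <- c(ev_rev, 0L)
        ev_meta[[length(ev_key)]] <- e
        j <- length(ev_key)
      }
      if (fwd) ev_fwd[j] <- ev_fwd[j] + 1L else ev_rev[j] <- ev_rev[j] + 1L
    }
  }

  columns <- tibble::tibble(
    position = seq_len(L) - 1L, ref_base = ref_chars,
    depth_forward = dep_f, depth_reverse = dep_r,
    match_forward = mat_f, match_reverse = mat_r
  )
  if (length(ev_key) == 0) {
    variants <- tibble::tibble(
      amplicon = character(), position = integer(), anchor = integer(),
      kind = character(), ref = character(), alt = character(),
      reads_forward = integer(), reads_reverse = integer(),
      depth = integer(), fraction = numeric()
    )
  } else {
    pos <- vapply(ev_meta, function(e) e$pos, integer(1))
    kind <- vapply(ev_meta, function(e) e$kind, character(1))
    refs <- vapply(ev_meta, function(e) e$ref, character(1))
    alts <- vapply(ev_meta, function(e) e$alt, character(1))
    anchor <- ifelse(kind == "ins", pmax(pos - 1L, 0L), pos)
    depth <- dep_f[anchor + 1L] + dep_r[anchor + 1L]
    variants <- tibble::tibble(
      amplicon = amplicon$name[[1]], position = as.integer(pos),
      anchor = as.integer(anchor), kind = kind, ref = refs, alt = alts,
      reads_forward = ev_fwd, reads_reverse = ev_rev,
      depth = as.integer(depth),
      fraction = (ev_fwd + ev_rev) / pmax(depth, 1L)
    ) |>
      dplyr::arrange(.data$position, .data$kind)
  }
  list(columns = columns, variants = variants)
}
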
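transcript_maps <- function(model) {
  ex <- model$exons
  lens <- ex$end - ex$start
  cum <- cumsum(c(0L, lens[-length(lens)]))
  list(ex = ex, lens = lens, cum = cum, total = sum(lens))
}

t_of_genomic <- function(model, g) {
  # 1-based transcript position of exonic genomic position g, else NA
  m <- transcript_maps(model)
  hit <- which(g >= m$ex$start & g < m$ex$end)
  if (length(hit) == 0) return(NA_integer_)
  m$cum[hit] + (g - m$ex$start[hit]) + 1L
}

#' Convert a genomic position to HGVS coding coordinates
#'
#' Exonic positions map to CDS coordinates (`c.1` is the first base of the
#' start codon; bases 5' of it get negative coordinates, bases 3' of the stop
#' codon get `*` coordinates). Intronic positions map to the nearest exon
#' boundary with a signed offset: `+k` after an exon end, `-k` before an exon
#' start, the first half of an intron belonging to the upstream exon.
#'
#' @param model A [gene_model()].
#' @param genomic_pos 0-based position on the model's genomic sequence
#'   (coding orientation).
#' @return A list of class `c_position`: `base` (integer CDS coordinate, or
#'   character `"*k"` for 3' UTR), `offset` (signed integer, 0 when exonic).
#' @export
genomic_to_coding <- function(model, genomic_pos) {
  g <- as.integer(genomic_pos)
  ex <- model$exons
  if (g < ex$start[1] || g >= ex$end[nrow(ex)])
    stop("position ", g, " is beyond the transcript span [",
         ex$start[1], ", ", ex$end[nrow(ex)], ")")
  t_cds_start <- t_of_genomic(model, model$cds_start)
  t_cds_end <- t_of_genomic(model, model$cds_end - 1L)
  cds_of_t <- function(t) {
    if (t < t_cds_start) return(t - t_cds_start)          # negative, no zero
    if (t > t_cds_end) return(paste0("*", t - t_cds_end))
    t - t_cds_start + 1L
  }
  t <- t_of_genomic(model, g)
  if (!is.na(t))
    return(structure(list(base = cds_of_t(t), offset = 0L),
                     class = "c_position"))
  # intronic: flanking exons
  up <- max(which(ex$end <= g))
  d_up <- g - (ex$end[up] - 1L)
  d_down <- ex$start[up + 1L] - g
  if (d_up <= d_down) {
    t <- t_of_genomic(model, ex$end[up] - 1L)
    structure(list(base = cds_of_t(t), offset = d_up), class = "c_position")
  } else {
    t <- t_of_genomic(model, ex$start[up + 1L])
    structure(list(base = cds_of_t(t), offset = -d_down),
              class = "c_position")
  }
}

#' Convert a coding coordinate back to a genomic position
#'
#' Inverse of [genomic_to_coding()]. For exonic coordinates (`offset = 0`)
#' this is an exact inverse; intronic offsets walk into the adjacent intron.
#'
#' @param model A [gene_model()].
#' @param base Integer CDS coordinate (negative for 5' UTR) or `"*k"`.
#' @param offset Signed intronic offset (default 0).
#' @return 0-based genomic position.
#' @export
coding_to_genomic <- function(model, base, offset = 0L) {
  m <- transcript_maps(model)
  t_cds_start <- t_of_genomic(model, model$cds_start)
  t_cds_end <- t_of_genomic(model, model$cds_end - 1L)
  t <- if (is.character(base) && grepl("^\\*", base)) {
    t_cds_end + as.integer(sub("^\\*", "", base))
  } else {
    base <- as.integer(base)
    if (base > 0) t_cds_start + base - 1L else t_cds_start + base
  }
  if (t < 1L || t > m$total) stop("coding coordinate beyond transcript")
  hit <- max(which(m$cum < t))
  g <- m$ex$start[hit] + (t - m$cum[hit]) - 1L
  g + as.integer(offset)
}

#' @export
print.c_position <- function(x, ...) {
  cat("c.", format_c_position(x), "\n", sep = "")
  invisible(x)
}

#' Format a coding position
#' @param x A `c_position` from [genomic_to_coding()].
#' @return Character like `"212+1"`, `"81-12"`, `"-5"`, `"*12"` or `"124"`.
#' @export
format_c_position <- function(x) {
  if (x$offset > 0) paste0(x$base, "+", x$offset)
  else if (x$offset < 0) paste0(x$base, x$offset)
  else as.character(x$base)
}

trim_common <- function(ref, alt, pos) {
  # trim common prefix then common suffix; returns shifted pos, ref, alt
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L)
    alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  list(pos = pos, ref = ref, alt = alt)
}

shift3 <- function(sequence, pos, allele, is_del) {
  # roll a pure indel to its 3'-most placement on the coding strand;
  # `pos` is 0-based: deletion occupies [pos, pos+k), insertion sits before
  # `pos`
  k <- nchar(allele)
  repeat {
    nxt_at <- if (is_del) pos + k else pos
    if (nxt_at >= nchar(sequence)) break
    nxt <- substr(sequence, nxt_at + 1L, nxt_at + 1L)
    if (nxt != substr(allele, 1, 1)) break
    allele <- paste0(substr(allele, 2, k), nxt)
    pos <- pos + 1L
  }
  list(pos = pos, allele = allele)
}

#' Normalize a variant into HGVS coding nomenclature
#'
#' Produces the canonical `c.` string for a genomic-coordinate variant:
#' common prefix then suffix bases shared by the reference and alternate
#' alleles are trimmed (so a delins never carries redundant flanking bases),
#' pure indels are shifted to their 3'-most position on the coding strand,
#' insertions identical to the immediately preceding reference bases become
#' duplications, and remaining substitution / del / ins / dup / delins forms
#' are emitted with exonic or intronic coordinates.
#'
#' @param model A [gene_model()].
#' @param position 0-based position on the model's genomic sequence of the
#'   first `ref` base (for pure insertions: the base before which `alt` is
#'   inserted).
#' @param ref Reference allele (may be `""` for a pure insertion).
#' @param alt Alternate allele (may be `""` for a pure deletion).
#' @return A one-row tibble: `c_string`, `kind`, `genomic_start`,
#'   `genomic_end` (0-based half-open after normalization), `ref`, `alt`.
#' @examples
#' \dontrun{
#' normalize_variant(model, 5265, "", "C")  # -> c.5266dupC (in a C run)
#' }
#' @export
normalize_variant <- function(model, position, ref, alt) {
  seqs <- model$genomic_sequence
  position <- as.integer(position)
  if (nchar(ref) > 0 &&
      substr(seqs, position + 1L, position + nchar(ref)) != ref)
    stop("reference allele '", ref, "' disagrees with the gene sequence at ",
         position)
  tr <- trim_common(ref, alt, position)
  pos <- tr$pos; ref <- tr$ref; alt <- tr$alt
  if (nchar(ref) == 0 && nchar(alt) == 0)
    stop("variant is identical to the reference")

  fmt <- function(g) format_c_position(genomic_to_coding(model, g))
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(tibble::tibble(
      c_string = paste0("c.", fmt(pos), ref, ">", alt), kind = "sub",
      genomic_start = pos, genomic_end = pos + 1L, ref = ref, alt = alt))
  }
  if (nchar(ref) > 0 && nchar(alt) > 0) {
    k <- nchar(ref)
    cs <- if (k == 1) paste0("c.", fmt(pos), "delins", alt)
          else paste0("c.", fmt(pos), "_", fmt(pos + k - 1L), "delins", alt)
    return(tibble::tibble(c_string = cs, kind = "delins",
                          genomic_start = pos, genomic_end = pos + k,
                          ref = ref, alt = alt))
  }
  if (nchar(alt) == 0) {                      # pure deletion
    sh <- shift3(seqs, pos, ref, is_del = TRUE)
    pos <- sh$pos; ref <- sh$allele; k <- nchar(ref)
    cs <- if (k == 1) paste0("c.", fmt(pos), "del", ref)
          else paste0("c.", fmt(pos), "_", fmt(pos + k - 1L), "del")
    return(tibble::tibble(c_string = cs, kind = "del",
                          genomic_start = pos, genomic_end = pos + k,
                          ref = ref, alt = ""))
  }
  # pure insertion
  sh <- shift3(seqs, pos, alt, is_del = FALSE)
  pos <- sh$pos; alt <- sh$allele; k <- nchar(alt)
  prev <- if (pos - k >= 0) substr(seqs, pos - k + 1L, pos) else ""
  if (identical(prev, alt)) {                 # duplication
    cs <- if (k == 1) paste0("c.", fmt(pos - 1L), "dup", alt)
          else paste0("c.", fmt(pos - k), "_", fmt(pos - 1L), "dup")
    return(tibble::tibble(c_string = cs, kind = "dup",
                          genomic_start = pos - k, genomic_end = pos,
                          ref = "", alt = alt))
  }
  cs <- paste0("c.", fmt(pos - 1L), "_", fmt(pos), "ins", alt)
  tibble::tibble(c_string = cs, kind = "ins",
                 genomic_start = pos, genomic_end = pos,
                 ref = "", alt = alt)
}

#' Read a neutral-variant list
#'
#' Plain text, one normalized `c.` string per line; `#` starts a comment.
#' Malformed lines are skipped with a warning naming the line number.
#'
#' @param path File path.
#' @return Character vector of `c.` strings.
#' @export
read_neutral_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  out <- character(0)
  for (i in which(keep)) {
    if (!grepl("^c\\.", lines[i])) {
      warning("neutral list line ", i, " is not a c. string, skipped: ",
              lines[i])
    } else out <- c(out, lines[i])
  }
  out
}

#' Flag variants known to be neutral
#'
#' Exact-string matching of each variant's normalized `c.` string against a
#' user-supplied neutral list (e.g. exported from locus-specific databases).
#' Everything not matched stays unclassified for manual interpretation.
#'
#' @param variants Tibble with a `c_string` column.
#' @param neutral_list Character vector of normalized `c.` strings (or a file
#'   path, read with [read_neutral_list()]).
#' @return `variants` with a logical `known_neutral` column.
#' @export
annotate_known <- function(variants, neutral_list) {
  if (length(neutral_list) == 1 && !grepl("^c\\.", neutral_list) &&
      file.exists(neutral_list))
    neutral_list <- read_neutral_list(neutral_list)
  variants$known_neutral <- variants$c_string %in% neutral_list
  variants
}
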
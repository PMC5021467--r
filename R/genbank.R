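#' Gene model
#'
#' Transcript structure on a gene's genomic sequence, held internally in
#' coding orientation: minus-strand genes are reverse-complemented at parse
#' time so exon coordinates always increase 5' to 3' of the transcript.
#' Coordinates are 0-based half-open.
#'
#' @param gene Gene name.
#' @param genomic_sequence Genomic sequence, coding orientation.
#' @param exons Tibble with `start`, `end` (0-based half-open), ordered,
#'   non-overlapping.
#' @param cds_start,cds_end 0-based half-open genomic bounds of the CDS.
#' @param strand Original strand of the record (`"+"` or `"-"`).
#' @param transcript_id Transcript identifier.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene, genomic_sequence, exons, cds_start, cds_end,
                       strand = "+", transcript_id = NA_character_) {
  exons <- tibble::tibble(start = as.integer(exons$start),
                          end = as.integer(exons$end))
  exons <- exons[order(exons$start), ]
  if (nrow(exons) == 0) stop("gene model needs at least one exon")
  if (any(exons$end <= exons$start)) stop("empty exon interval")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons overlap")
  L <- nchar(genomic_sequence)
  stopifnot(cds_start >= 0, cds_end <= L, cds_start < cds_end)
  in_exon <- function(g) any(g >= exons$start & g < exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end - 1L))
    stop("CDS bounds fall outside the exon union")
  structure(list(gene = gene, genomic_sequence = genomic_sequence,
                 exons = exons, cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end), strand = strand,
                 transcript_id = transcript_id),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene, " (", x$transcript_id, "), ",
      nrow(x$exons), " exon(s), CDS [", x$cds_start, ", ", x$cds_end,
      "), strand ", x$strand, "\n", sep = "")
  invisible(x)
}

parse_gb_location <- function(loc) {
  # returns list(complement = logical, intervals = tibble(start, end)
  # 0-based half-open); joins crossing the origin are unsupported
  loc <- gsub("[[:space:]]", "", loc)
  complement <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|^join\\(|\\)+$", "", loc)
  inner <- gsub("^join\\(", "", inner)
  parts <- strsplit(inner, ",")[[1]]
  iv <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", p))[[1]]
    if (length(m) == 3)
      return(c(as.integer(m[2]) - 1L, as.integer(m[3])))
    m <- regmatches(p, regexec("^<?>?(\\d+)$", p))[[1]]
    if (length(m) == 2) {
      s <- as.integer(m[2]); return(c(s - 1L, s))
    }
    stop("unsupported GenBank location element: ", p)
  })
  iv <- do.call(rbind, iv)
  out <- tibble::tibble(start = iv[, 1], end = iv[, 2])
  if (nrow(out) > 1 && any(diff(out$start) < 0))
    stop("joined location crossing the origin is unsupported: ", loc)
  list(complement = complement, intervals = out)
}

#' Parse a GenBank flat file into a gene model
#'
#' Minimal parser for single-record GenBank flat files carrying one gene:
#' reads the LOCUS line, `exon` and `CDS` features (with `join(...)` and
#' `complement(...)` locations), the `/gene` and `/transcript_id` qualifiers
#' and the ORIGIN sequence. Minus-strand genes are reverse-complemented into
#' coding orientation. When no `exon` features are present the CDS intervals
#' double as exons.
#'
#' @param path GenBank flat file.
#' @return A [gene_model()].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file: ", path)
  # features
  feat_start <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  if (length(feat_start) == 0 || length(origin_at) == 0)
    stop("GenBank file lacks FEATURES or ORIGIN section: ", path)
  feat_lines <- lines[(feat_start + 1):(origin_at - 1)]
  feats <- list(); cur <- NULL
  for (ln in feat_lines) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
      key <- sub("^ +", "", substr(ln, 1, 20))
      key <- sub(" +$", "", key)
      cur <- list(key = key, loc = sub("^ +", "", substr(ln, 21, nchar(ln))),
                  quals = character(0))
    } else if (!is.null(cur)) {
      body <- sub("^ +", "", ln)
      if (startsWith(body, "/")) cur$quals <- c(cur$quals, body)
      else cur$loc <- paste0(cur$loc, body)
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1]] <- cur

  get_qual <- function(f, name) {
    hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    gsub('^/[^=]+="?|"$', "", hit[1])
  }
  cds <- Filter(function(f) f$key == "CDS", feats)
  if (length(cds) == 0) stop("GenBank file has no CDS feature: ", path)
  cds <- cds[[1]]
  exons <- Filter(function(f) f$key == "exon", feats)
  genef <- Filter(function(f) f$key == "gene", feats)
  gene_name <- if (length(genef) > 0) get_qual(genef[[1]], "gene")
               else get_qual(cds, "gene")
  tx <- get_qual(cds, "transcript_id")

  seq_lines <- lines[(origin_at + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genomic <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines,
                                                     collapse = "")))
  L <- nchar(genomic)

  cds_loc <- parse_gb_location(cds$loc)
  ex_iv <- if (length(exons) > 0) {
    dplyr::bind_rows(lapply(exons, function(f)
      parse_gb_location(f$loc)$intervals))
  } else cds_loc$intervals
  minus <- cds_loc$complement
  cds_start <- min(cds_loc$intervals$start)
  cds_end <- max(cds_loc$intervals$end)
  if (minus) {
    genomic <- revcomp(genomic)
    ex_iv <- tibble::tibble(
      start = L - ex_iv$end, end = L - ex_iv$start)
    tmp <- c(L - cds_end, L - cds_start)
    cds_start <- tmp[1]; cds_end <- tmp[2]
  }
  gene_model(gene = gene_name, genomic_sequence = genomic,
             exons = ex_iv, cds_start = cds_start, cds_end = cds_end,
             strand = if (minus) "-" else "+", transcript_id = tx)
}

#' Write a gene model as a GenBank flat file
#'
#' Writer counterpart of [parse_genbank()] (plus-strand layout, the model's
#' own coding orientation); mainly used for round-trip testing and for
#' exporting synthetic gene models.
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(model, path) {
  L <- nchar(model$genomic_sequence)
  fmt_iv <- function(iv) paste0(iv$start + 1L, "..", iv$end)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                     model$gene, L), con)
  writeLines(sprintf("DEFINITION  synthetic gene model for %s.", model$gene),
             con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     gene            1..%d", L), con)
  writeLines(sprintf('                     /gene="%s"', model$gene), con)
  for (i in seq_len(nrow(model$exons)))
    writeLines(sprintf("     exon            %s",
                       fmt_iv(model$exons[i, ])), con)
  cds_parts <- model$exons |>
    dplyr::mutate(start = pmax(.data$start, model$cds_start),
                  end = pmin(.data$end, model$cds_end)) |>
    dplyr::filter(.data$end > .data$start)
  loc <- if (nrow(cds_parts) == 1) fmt_iv(cds_parts)
         else paste0("join(", paste(vapply(seq_len(nrow(cds_parts)),
              function(i) fmt_iv(cds_parts[i, ]), character(1)),
              collapse = ","), ")")
  writeLines(paste0("     CDS             ", loc), con)
  writeLines(sprintf('                     /gene="%s"', model$gene), con)
  if (!is.na(model$transcript_id))
    writeLines(sprintf('                     /transcript_id="%s"',
                       model$transcript_id), con)
  writeLines("ORIGIN", con)
  s <- tolower(model$genomic_sequence)
  i <- 1L
  while (i <= L) {
    chunk <- substr(s, i, min(i + 59L, L))
    groups <- gsub("(.{10})", "\\1 ", chunk)
    writeLines(sprintf("%9d %s", i, sub(" +$", "", groups)), con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}
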
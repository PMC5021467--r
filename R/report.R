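#' Assemble report rows
#'
#' Joins validated/filtered variant calls with their HGVS strings,
#' homopolymer labels and neutral flags into the per-sample report table. A
#' row needs review whenever its homopolymer label is ambiguous (or manual
#' mode left it unlabelled) or its amplicon failed coverage validation.
#'
#' @param calls Tibble of filtered calls (from [filter_variants()]) with
#'   added columns `sample`, `c_string`, `hp_label` (NA when no homopolymer
#'   context), `known_neutral`.
#' @return A tibble with a `needs_review` flag and a `colour` column used by
#'   the spreadsheet-style export (green = validated, orange = needs review,
#'   grey = known neutral, red = rejected).
#' @export
report_rows <- function(calls) {
  needs_review <- (!is.na(calls$hp_label) &
                     calls$hp_label %in% c("ambiguous", "manual_review")) |
    !calls$amplicon_validated
  colour <- dplyr::case_when(
    !calls$validated ~ "red",
    calls$known_neutral ~ "grey",
    needs_review ~ "orange",
    TRUE ~ "green"
  )
  dplyr::mutate(calls, needs_review = needs_review, colour = colour)
}

#' Write pipeline reports
#'
#' Emits the output files of a screening run to `out_dir`:
#' \itemize{
#'   \item `variants.tsv` — one row per reported variant per sample, with
#'     status, colour code, homopolymer label and neutral flag (the
#'     machine-readable twin of a colour-coded spreadsheet);
#'   \item `coverage_matrix.tsv` — per sample x amplicon minimum region-of-
#'     interest depth and validation flag;
#'   \item `no_variant_amplicons.tsv` — amplicons reporting no variant;
#'   \item `resequencing_worklist.tsv` — sample x amplicon pairs failing
#'     coverage validation, with their failing positions;
#'   \item `variants.vcf` — optional VCF 4.2 export of validated calls;
#'   \item `MANIFEST.json` — file list and row counts.
#' }
#'
#' @param rows Tibble from [report_rows()].
#' @param coverage Tibble with `sample`, `amplicon`, `min_roi_depth`,
#'   `validated`, `failing_positions` (comma-joined string, may be `""`).
#' @param out_dir Output directory (created if missing).
#' @param model Optional [gene_model()]; required for the VCF export.
#' @param vcf Write `variants.vcf` (default `!is.null(model)`).
#' @return Invisible character vector of written paths.
#' @export
write_reports <- function(rows, coverage, out_dir, model = NULL,
                          vcf = !is.null(model)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- character(0)
  p <- file.path(out_dir, "variants.tsv")
  readr::write_tsv(rows, p); paths <- c(paths, p)

  p <- file.path(out_dir, "coverage_matrix.tsv")
  readr::write_tsv(coverage, p); paths <- c(paths, p)

  no_var <- coverage |>
    dplyr::distinct(.data$sample, .data$amplicon) |>
    dplyr::anti_join(
      dplyr::distinct(rows[rows$validated, ], .data$sample, .data$amplicon),
      by = c("sample", "amplicon"))
  p <- file.path(out_dir, "no_variant_amplicons.tsv")
  readr::write_tsv(no_var, p); paths <- c(paths, p)

  worklist <- coverage[!coverage$validated, , drop = FALSE]
  p <- file.path(out_dir, "resequencing_worklist.tsv")
  readr::write_tsv(worklist, p); paths <- c(paths, p)

  if (vcf) {
    if (is.null(model)) stop("VCF export needs a gene model")
    p <- file.path(out_dir, "variants.vcf")
    write_vcf(rows[rows$validated, , drop = FALSE], model, p)
    paths <- c(paths, p)
  }
  manifest <- list(
    files = basename(paths),
    n_variants = sum(rows$validated),
    n_rows = nrow(rows),
    n_failed_amplicons = sum(!coverage$validated)
  )
  mp <- file.path(out_dir, "MANIFEST.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Write validated calls as VCF 4.2
#'
#' Pure insertions and deletions are padded with the preceding reference
#' base, per VCF convention; coordinates are 1-based on the gene genomic
#' sequence (coding orientation).
#'
#' @param rows Report rows with `genomic_start`, `genomic_end`, `ref`,
#'   `alt`, `sample`, `fraction`, `depth`.
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(rows, model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", model$gene,
            nchar(model$genomic_sequence)),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  seqs <- model$genomic_sequence
  refs <- if ("hgvs_ref" %in% names(rows)) rows$hgvs_ref else rows$ref
  alts <- if ("hgvs_alt" %in% names(rows)) rows$hgvs_alt else rows$alt
  for (i in seq_len(nrow(rows))) {
    g0 <- rows$genomic_start[[i]]
    ref <- refs[[i]]; alt <- alts[[i]]
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      pad <- substr(seqs, g0, g0)           # base before (1-based g0)
      pos1 <- g0                            # 1-based position of pad base
      ref <- paste0(pad, ref); alt <- paste0(pad, alt)
    } else {
      pos1 <- g0 + 1L
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f;DP=%d;SAMPLE=%s",
                       model$gene, pos1, ref, alt,
                       rows$fraction[[i]], rows$depth[[i]],
                       rows$sample[[i]]), con)
  }
  invisible(path)
}

#' Read the bundled composite-sample comparison fixture
#'
#' A verbatim transcription of the published three-way comparison of one
#' composite control sample (pooled PCR products carrying 28 known variants)
#' analysed by Sanger sequencing and by two pyrosequencing analysis
#' pipelines. HGVS spellings are kept exactly as printed, with a normalized
#' twin column (`NA` where the printed form does not determine the inserted
#' sequence). Flags: `sanger`/`agsa`/`seqnext` = detected by that route;
#' `*_low_depth` = the call (or its absence) was in an amplicon covered by
#' fewer than 40 reads.
#'
#' @param path Optional alternative TSV path.
#' @return A tibble.
#' @export
read_composite_comparison <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "composite_sample_comparison.tsv",
                        package = "pyroscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  na = "NA", col_types = readr::cols(
                    gene = "c", hgvs_printed = "c", hgvs_normalized = "c",
                    zygosity = "c", sanger = "i", agsa = "i",
                    agsa_percent = "d", agsa_low_depth = "i",
                    seqnext = "i", seqnext_percent = "d",
                    seqnext_low_depth = "i"))
}

#' Tally the composite-sample comparison
#'
#' Computes, from the detection flags of the comparison table, the headline
#' counts: Sanger-validated variants; variants reported only by the
#' flowgram-review pipeline (false positives against the Sanger reference),
#' and how many of those sat in amplicons below the 40-read depth threshold;
#' variants reported only by the commercial comparator; and Sanger variants
#' the comparator missed outright (absences explained by low coverage are
#' excluded, as those amplicons are resequenced anyway).
#'
#' @param d Tibble from [read_composite_comparison()].
#' @return A one-row tibble with columns `sanger_validated`, `agsa_only`,
#'   `agsa_only_low_depth`, `seqnext_only`, `seqnext_missed`.
#' @export
tally_composite_comparison <- function(d = read_composite_comparison()) {
  tibble::tibble(
    sanger_validated = sum(d$sanger == 1),
    agsa_only = sum(d$agsa == 1 & d$sanger == 0),
    agsa_only_low_depth = sum(d$agsa == 1 & d$sanger == 0 &
                                d$agsa_low_depth == 1),
    seqnext_only = sum(d$seqnext == 1 & d$sanger == 0),
    seqnext_missed = sum(d$sanger == 1 & d$seqnext == 0 &
                           d$seqnext_low_depth == 0)
  )
}
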
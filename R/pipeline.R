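#' Pipeline configuration
#'
#' Gathers all inputs and thresholds of a screening run. Threshold defaults
#' mirror routine diagnostic use: amplicon validation at 40 reads minimum
#' depth over the exon -20/+6 region of interest, variant validation at 20%
#' of reads on both strands and at least 4 supporting reads, homopolymer
#' histograms produced for manual review.
#'
#' @param sff Path to an SFF file.
#' @param amplicons An [amplicon_defs()] tibble or a TSV path for
#'   [read_amplicons()].
#' @param genbank A [gene_model()] or a GenBank flat-file path.
#' @param mids Named character vector `sample -> MID`.
#' @param out_dir Output directory.
#' @param neutral_list Optional path or character vector of neutral
#'   `c.` strings.
#' @param filter A [filter_config()].
#' @param align A [align_config()].
#' @param hp An [hp_config()].
#' @param use_clip Use only the quality-clipped portion of each read
#'   (default TRUE).
#' @param write_histograms Render histogram images + sidecars (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sff, amplicons, genbank, mids, out_dir,
                            neutral_list = NULL,
                            filter = filter_config(),
                            align = align_config(),
                            hp = hp_config(),
                            use_clip = TRUE,
                            write_histograms = TRUE) {
  if (is.character(amplicons)) amplicons <- read_amplicons(amplicons)
  if (is.character(genbank)) genbank <- parse_genbank(genbank)
  stopifnot(inherits(amplicons, "amplicon_defs"),
            inherits(genbank, "gene_model"),
            inherits(filter, "filter_config"),
            inherits(align, "align_config"),
            inherits(hp, "hp_config"),
            length(mids) >= 1, !is.null(names(mids)))
  structure(list(sff = sff, amplicons = amplicons, genbank = genbank,
                 mids = mids, out_dir = out_dir,
                 neutral_list = neutral_list, filter = filter,
                 align = align, hp = hp, use_clip = use_clip,
                 write_histograms = write_histograms),
            class = "pipeline_config")
}

hp_review <- function(variant, amplicon, alignments, reads, flow_order,
                      config, filter_cfg, out_dir, sample,
                      write_histograms) {
  site <- detect_context(variant, amplicon$reference[[1]],
                         config$min_run_length)
  if (is.null(site))
    return(list(label = NA_character_, site = NULL))
  alignments <- alignments[alignments$amplicon == amplicon$name[[1]], ,
                           drop = FALSE]
  sig <- extract_signals(site, alignments, reads, flow_order)
  if (length(sig$signals) < filter_cfg$min_variant_reads)
    return(list(label = "ambiguous", site = site))
  hist <- build_histogram(sig$signals, site$n[[1]])
  label <- if (config$mode == "auto") {
    classify_histogram(hist, config,
                       min_fraction = filter_cfg$min_variant_fraction,
                       min_reads = filter_cfg$min_variant_reads)$label
  } else "manual_review"
  if (write_histograms) {
    hdir <- file.path(out_dir, "histograms")
    dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
    fname <- sprintf("%s_%s_pos%d_%s.png", sample, amplicon$name[[1]],
                     variant$position[[1]], variant$kind[[1]])
    cls <- if (config$mode == "auto")
      classify_histogram(hist, config,
                         min_fraction = filter_cfg$min_variant_fraction,
                         min_reads = filter_cfg$min_variant_reads)
    else NULL
    render_histogram(hist, site, file.path(hdir, fname),
                     classification = cls)
  }
  list(label = label, site = site)
}

#' Run the full screening pipeline
#'
#' Executes the stages in order: read SFF, clip, demultiplex by MID, align
#' to amplicons, pileup and candidate calling, amplicon validation over the
#' region of interest, variant filtering, homopolymer flowgram review, HGVS
#' annotation, neutral-list matching and report writing. Reruns on the same
#' inputs produce identical reports (no randomness is involved).
#'
#' Homopolymer handling: in `auto` mode a call labelled `artefact` is
#' demoted to status `flagged_homopolymer` and excluded from validated
#' variants; `ambiguous` (and every homopolymer call in `manual` mode) stays
#' validated but flagged for review.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `calls` (report rows), `coverage`, `pileups`,
#'   `unaligned` (per-sample counts), `paths` (written report files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$sff)) stop("missing SFF input: ", config$sff)
  sff <- read_sff(config$sff)
  reads <- if (config$use_clip) clip_reads(sff$reads) else sff$reads
  reads <- demultiplex(reads, config$mids)
  message(nrow(reads), " reads; ", sum(is.na(reads$sample)), " unassigned")

  model <- config$genbank
  amps <- config$amplicons
  roi <- roi_positions(model, amps, config$filter)
  neutral <- if (is.null(config$neutral_list)) character(0)
             else if (length(config$neutral_list) == 1 &&
                      file.exists(config$neutral_list))
               read_neutral_list(config$neutral_list)
             else config$neutral_list

  all_calls <- list(); coverage <- list(); pileups <- list()
  unaligned <- list()
  flow_order <- sff$header$flow_order
  samples <- unique(stats::na.omit(reads$sample))
  for (s in samples) {
    rs <- reads[!is.na(reads$sample) & reads$sample == s, , drop = FALSE]
    aln <- align_reads(rs, amps, config$align)
    unaligned[[s]] <- tibble::tibble(sample = s,
                                     n_reads = nrow(rs),
                                     n_unaligned = sum(!aln$aligned))
    for (ai in seq_len(nrow(amps))) {
      amp <- amps[ai, ]
      pu <- call_pileup(aln, amp)
      pileups[[paste(s, amp$name, sep = "/")]] <- pu
      av <- validate_amplicon(pu$columns, roi[[amp$name]], config$filter)
      coverage[[paste(s, amp$name, sep = "/")]] <- tibble::tibble(
        sample = s, amplicon = amp$name, min_roi_depth = av$min_depth,
        validated = av$validated,
        failing_positions = paste(av$failing$position, collapse = ","))
      if (nrow(pu$variants) == 0) next
      calls <- filter_variants(pu$variants, config$filter,
                               amplicon_validated = av$validated,
                               columns = pu$columns)
      calls <- calls[calls$validated, , drop = FALSE]
      if (nrow(calls) == 0) next
      calls$sample <- s
      calls$hp_label <- NA_character_
      for (vi in seq_len(nrow(calls))) {
        rev <- hp_review(calls[vi, ], amp, aln, rs, flow_order,
                         config$hp, config$filter, config$out_dir, s,
                         config$write_histograms)
        calls$hp_label[[vi]] <- rev$label
      }
      # artefact calls are the false positives this review exists to remove
      demote <- !is.na(calls$hp_label) & calls$hp_label == "artefact"
      calls$status[demote] <- "flagged_homopolymer"
      calls$validated[demote] <- FALSE
      # HGVS annotation on the gene genomic sequence
      ann <- lapply(seq_len(nrow(calls)), function(vi) {
        g <- amp$genomic_offset[[1]] + calls$position[[vi]]
        normalize_variant(model, g, calls$ref[[vi]], calls$alt[[vi]])
      })
      ann <- dplyr::bind_rows(ann)
      calls$c_string <- ann$c_string
      calls$genomic_start <- ann$genomic_start
      calls$genomic_end <- ann$genomic_end
      calls$hgvs_ref <- ann$ref
      calls$hgvs_alt <- ann$alt
      all_calls[[length(all_calls) + 1]] <- calls
    }
  }
  coverage <- dplyr::bind_rows(coverage)
  calls <- if (length(all_calls) > 0) dplyr::bind_rows(all_calls) else
    tibble::tibble(sample = character(), amplicon = character(),
                   position = integer(), kind = character(),
                   ref = character(), alt = character(),
                   reads_forward = integer(), reads_reverse = integer(),
                   depth = integer(), fraction = numeric(),
                   status = character(), validated = logical(),
                   amplicon_validated = logical(),
                   hp_label = character(), c_string = character(),
                   genomic_start = integer(), genomic_end = integer())
  calls <- annotate_known(calls, neutral)
  # merge duplicate amplicons covering the same genomic variant
  if (nrow(calls) > 0) {
    calls <- calls |>
      dplyr::group_by(.data$sample, .data$c_string) |>
      dplyr::mutate(
        duplicate_amplicons = dplyr::n() > 1,
        duplicate_discordant = dplyr::n_distinct(.data$validated) > 1) |>
      dplyr::ungroup()
  } else {
    calls$duplicate_amplicons <- logical(0)
    calls$duplicate_discordant <- logical(0)
  }
  rows <- report_rows(calls)
  # persist intermediates so reports can be re-rendered stage-wise
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(rows |>
                     dplyr::mutate(dplyr::across(
                       dplyr::where(is.list), ~ vapply(.x, paste,
                                                       character(1),
                                                       collapse = ","))),
                   file.path(config$out_dir, "calls_intermediate.tsv"))
  readr::write_tsv(coverage, file.path(config$out_dir,
                                       "coverage_intermediate.tsv"))
  paths <- write_reports(rows, coverage, config$out_dir, model = model)
  un <- dplyr::bind_rows(unaligned)
  readr::write_tsv(un, file.path(config$out_dir, "unaligned_reads.tsv"))
  invisible(list(calls = rows, coverage = coverage, pileups = pileups,
                 unaligned = un, paths = paths))
}

#' Re-render reports from saved intermediates
#'
#' Reads `calls_intermediate.tsv` and `coverage_intermediate.tsv` from a
#' previous [run_pipeline()] output directory and rewrites the report files;
#' running it twice produces identical files.
#'
#' @param out_dir A pipeline output directory.
#' @param model Optional [gene_model()] for the VCF export.
#' @return Invisible character vector of written paths.
#' @export
reports_from_intermediates <- function(out_dir, model = NULL) {
  rows <- readr::read_tsv(file.path(out_dir, "calls_intermediate.tsv"),
                          show_col_types = FALSE)
  coverage <- readr::read_tsv(file.path(out_dir,
                                        "coverage_intermediate.tsv"),
                              show_col_types = FALSE)
  if (!"failing_positions" %in% names(coverage))
    coverage$failing_positions <- ""
  coverage$failing_positions[is.na(coverage$failing_positions)] <- ""
  write_reports(rows, coverage, out_dir, model = model)
}

#' Re-classify saved homopolymer sidecars
#'
#' Applies the mixture classifier to every histogram sidecar under
#' `dir` (files `*.png.json`), returning one row per sidecar; in-pipeline
#' labels are reproduced because the same code path is used.
#'
#' @param dir Directory holding sidecars (e.g. `<out_dir>/histograms`).
#' @param config An [hp_config()].
#' @param min_fraction,min_reads Passed to [classify_histogram()].
#' @return Tibble: `path`, `n`, `n_reads`, `label`.
#' @export
classify_sidecars <- function(dir, config = hp_config(mode = "auto"),
                              min_fraction = 0.2, min_reads = 4L) {
  files <- if (dir.exists(dir))
    list.files(dir, pattern = "\\.json$", full.names = TRUE) else character(0)
  if (length(files) == 0)
    return(tibble::tibble(path = character(), n = integer(),
                          n_reads = integer(), label = character()))
  out <- lapply(files, function(f) {
    d <- read_histogram_sidecar(f)
    cls <- classify_histogram(d$hist, config, min_fraction = min_fraction,
                              min_reads = min_reads)
    tibble::tibble(path = f, n = d$n, n_reads = length(d$signals),
                   label = cls$label)
  })
  dplyr::bind_rows(out)
}
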
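simple_aln <- function(pattern_gapped, subject_gapped, strand = "+",
                       subject_start = 1L, name = NULL, amplicon = "a1") {
  n <- length(pattern_gapped)
  tibble::tibble(
    name = if (is.null(name)) sprintf("r%03d", seq_len(n)) else name,
    amplicon = amplicon, strand = rep_len(strand, n), score = 0,
    identity = 1, aligned = TRUE,
    subject_start = rep_len(as.integer(subject_start), n),
    pattern_offset = 0L,
    pattern_gapped = pattern_gapped, subject_gapped = subject_gapped,
    read_length = nchar(gsub("-", "", pattern_gapped))
  )
}

test_that("identical error-free reads give full-depth columns, no variants", {
  ref <- "ACGTACGTAA"
  amp <- amplicon_defs("a1", ref, 0)
  aln <- simple_aln(rep(ref, 10), rep(ref, 10),
                    strand = rep(c("+", "-"), 5))
  pu <- call_pileup(aln, amp)
  expect_equal(nrow(pu$variants), 0)
  expect_equal(pu$columns$depth_forward + pu$columns$depth_reverse,
               rep(10L, 10))
  expect_equal(pu$columns$match_forward + pu$columns$match_reverse,
               rep(10L, 10))
})

test_that("a 6/4 substitution column yields fraction 0.40 at depth 10", {
  ref <- "ACGTACGTAA"
  alt <- "ACGTTCGTAA"   # A>T at position 4 (0-based)
  amp <- amplicon_defs("a1", ref, 0)
  aln <- simple_aln(c(rep(ref, 6), rep(alt, 4)), rep(ref, 10),
                    strand = c(rep("+", 5), rep("-", 5)))
  pu <- call_pileup(aln, amp)
  expect_equal(nrow(pu$variants), 1)
  v <- pu$variants
  expect_equal(v$kind, "sub")
  expect_equal(v$position, 4L)
  expect_equal(v$ref, "A"); expect_equal(v$alt, "T")
  expect_equal(v$depth, 10L)
  expect_equal(v$fraction, 0.4)
  expect_equal(v$reads_forward + v$reads_reverse, 4L)
})

test_that("indels anchor canonically whatever the gap placement", {
  ref <- "TTGAAAAC"
  amp <- amplicon_defs("a1", ref, 0)
  # the same single-A deletion placed at either end of the A run
  aln <- simple_aln(c("TTG-AAAC", "TTGAAA-C"), c(ref, ref))
  pu <- call_pileup(aln, amp)
  expect_equal(nrow(pu$variants), 1)
  expect_equal(pu$variants$kind, "del")
  expect_equal(pu$variants$position, 3L)   # left-normalised anchor
  expect_equal(pu$variants$reads_forward, 2L)
})

test_that("pileup counts equal a brute-force recount over aligned pairs", {
  set.seed(41)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  amp <- amplicon_defs("a1", ref, 0)
  co <- simulate_cohort(amp, NULL, c(s1 = "ACGAGTGCGT"), depth = 40,
                        seed = 17, noise = noise_model(0.12, 0, 0.35))
  reads <- demultiplex(clip_reads(co$reads), c(s1 = "ACGAGTGCGT"))
  aln <- align_reads(reads, amp)
  pu <- call_pileup(aln, amp)
  # independent recount of per-strand depth from the gapped strings
  dep_f <- integer(60); dep_r <- integer(60)
  for (i in which(aln$aligned)) {
    ns <- nchar(gsub("-", "", aln$subject_gapped[[i]]))
    span <- seq.int(aln$subject_start[[i]], aln$subject_start[[i]] + ns - 1)
    if (aln$strand[[i]] == "+") dep_f[span] <- dep_f[span] + 1L
    else dep_r[span] <- dep_r[span] + 1L
  }
  expect_equal(pu$columns$depth_forward, dep_f)
  expect_equal(pu$columns$depth_reverse, dep_r)
  # conservation: per column, per strand, matches never exceed depth, and
  # they agree on substitution-free columns
  expect_true(all(pu$columns$match_forward <= pu$columns$depth_forward))
  expect_true(all(pu$columns$match_reverse <= pu$columns$depth_reverse))
  # support never exceeds anchor depth
  if (nrow(pu$variants) > 0)
    expect_true(all(pu$variants$reads_forward + pu$variants$reads_reverse
                    <= pu$variants$depth))
})

test_that("amplicon validation is the minimum-depth rule, boundary at 40", {
  ref <- strrep("ACGT", 25)
  amp <- amplicon_defs("a1", ref, 0)
  mk_cols <- function(depths) tibble::tibble(
    position = seq_along(depths) - 1L,
    ref_base = strsplit(ref, "")[[1]][seq_along(depths)],
    depth_forward = as.integer(ceiling(depths / 2)),
    depth_reverse = as.integer(floor(depths / 2)),
    match_forward = 0L, match_reverse = 0L)
  roi <- 0:19
  ok <- validate_amplicon(mk_cols(rep(40, 100)), roi, filter_config())
  expect_true(ok$validated)
  expect_equal(nrow(ok$failing), 0)
  depths <- rep(200, 100); depths[8] <- 39
  bad <- validate_amplicon(mk_cols(depths), roi, filter_config())
  expect_false(bad$validated)
  expect_equal(bad$failing$position, 7L)
  expect_equal(bad$failing$depth, 39)
  # random depths agree with a brute-force minimum comparison
  set.seed(5)
  for (k in 1:25) {
    d <- sample(30:60, 100, TRUE)
    res <- validate_amplicon(mk_cols(d), roi, filter_config())
    expect_equal(res$validated, min(d[roi + 1]) >= 40)
  }
  expect_error(validate_amplicon(mk_cols(rep(40, 10)), integer(0)),
               "empty")
})

test_that("variant filtering matches the exhaustive decision-table oracle", {
  cfg <- filter_config()
  grid <- expand.grid(sup_f = 0:6, sup_r = 0:6, extra_f = c(0, 3, 10),
                      extra_r = c(0, 3, 10))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cov_f <- g$sup_f + g$extra_f; cov_r <- g$sup_r + g$extra_r
    depth <- cov_f + cov_r
    if (depth == 0 || g$sup_f + g$sup_r == 0) next
    fraction <- (g$sup_f + g$sup_r) / depth
    rows[[length(rows) + 1]] <- tibble::tibble(
      amplicon = "a", position = 0L, anchor = 0L, kind = "sub",
      ref = "A", alt = "T", reads_forward = g$sup_f, reads_reverse = g$sup_r,
      depth = depth, fraction = fraction,
      coverage_forward = cov_f, coverage_reverse = cov_r)
  }
  raw <- dplyr::bind_rows(rows)
  out <- filter_variants(raw, cfg, amplicon_validated = TRUE)
  oracle <- mapply(oracle_filter_status, raw$reads_forward,
                   raw$reads_reverse, raw$coverage_forward,
                   raw$coverage_reverse, raw$fraction,
                   MoreArgs = list(cfg = cfg))
  expect_equal(out$status, unname(oracle))
})

test_that("paper-rule boundaries: support, strand exemption, frequency", {
  cfg <- filter_config()
  mk <- function(f, r, cf, cr, frac) tibble::tibble(
    amplicon = "a", position = 0L, anchor = 0L, kind = "sub", ref = "A",
    alt = "T", reads_forward = f, reads_reverse = r,
    depth = cf + cr, fraction = frac,
    coverage_forward = cf, coverage_reverse = cr)
  # 3 supporting reads at fraction 0.5: too few reads
  expect_equal(filter_variants(mk(2, 1, 3, 3, 0.5), cfg)$status,
               "rejected_support")
  # 10F + 0R but the reverse strand has no reads at all: exemption applies
  expect_equal(filter_variants(mk(10, 0, 20, 0, 0.5), cfg)$status,
               "validated")
  # reverse strand covered but silent: strand rule rejects
  expect_equal(filter_variants(mk(10, 0, 20, 5, 0.4), cfg)$status,
               "rejected_strand")
  # frequency boundary is inclusive at 20%
  expect_equal(filter_variants(mk(10, 9, 50, 50, 0.19), cfg)$status,
               "rejected_frequency")
  expect_equal(filter_variants(mk(10, 10, 50, 50, 0.20), cfg)$status,
               "validated")
})

test_that("region of interest extends exons by -20/+6 and clips to amplicons", {
  seqs <- strrep("ACGT", 100)
  model <- gene_model("G", seqs,
                      tibble::tibble(start = 100L, end = 200L),
                      cds_start = 100L, cds_end = 200L)
  amp <- amplicon_defs("a1", substr(seqs, 61, 280), genomic_offset = 60)
  roi <- roi_positions(model, amp, filter_config())
  expect_equal(roi$a1, 20:145)   # genomic [80, 206) minus offset 60
  roi0 <- roi_positions(model, amp,
                        filter_config(roi_upstream = 0, roi_downstream = 0))
  expect_equal(roi0$a1, 40:139)  # the exon exactly
  # overlapping ROI of two exons unions correctly
  model2 <- gene_model("G", seqs,
                       tibble::tibble(start = c(100L, 210L),
                                      end = c(200L, 240L)),
                       cds_start = 100L, cds_end = 240L)
  roi2 <- roi_positions(model2, amp, filter_config())
  expected <- sort(unique(c(80:205, 190:245)))
  expect_equal(roi2$a1, expected - 60L)
  # an exon outside every amplicon warns
  model3 <- gene_model("G", seqs,
                       tibble::tibble(start = c(100L, 300L),
                                      end = c(200L, 340L)),
                       cds_start = 100L, cds_end = 340L)
  expect_warning(roi_positions(model3, amp, filter_config()), "not fully")
})
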
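test_that("a synthetic two-exon plus-strand record parses as written", {
  m0 <- gene_model("TOY2", paste0(strrep("T", 30), strrep("ACGT", 40),
                                  strrep("G", 30)),
                   tibble::tibble(start = c(30L, 120L), end = c(80L, 170L)),
                   cds_start = 40L, cds_end = 160L,
                   transcript_id = "NM_TOY2")
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(m0, path)
  m <- parse_genbank(path)
  expect_equal(m$gene, "TOY2")
  expect_equal(m$transcript_id, "NM_TOY2")
  expect_equal(m$exons, m0$exons)
  expect_equal(m$genomic_sequence, m0$genomic_sequence)
  expect_equal(c(m$cds_start, m$cds_end), c(40L, 160L))
})

test_that("minus-strand records orient into the identical coding model", {
  # hand-written record: gene on the minus strand of a 60 bp sequence
  seq_plus <- "ATGCATTTTGCCGGAACGTACGTAGCTAGGCTAACGGATCCATGCATGGCCAATTGGCCA"
  coding <- revcomp(seq_plus)
  path <- withr::local_tempfile(fileext = ".gb")
  lines <- c(
    "LOCUS       MINUS1 60 bp    DNA     linear   UNA",
    "FEATURES             Location/Qualifiers",
    "     gene            complement(1..60)",
    '                     /gene="MINUS1"',
    "     exon            complement(31..60)",
    "     exon            complement(1..20)",
    "     CDS             complement(join(5..20,31..55))",
    '                     /gene="MINUS1"',
    '                     /transcript_id="NM_M1"',
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(tolower(seq_plus),
                                         seq(1, 60, 10),
                                         seq(10, 60, 10)),
                               collapse = " ")),
    "//")
  writeLines(lines, path)
  m <- parse_genbank(path)
  expect_equal(m$strand, "-")
  expect_equal(m$genomic_sequence, coding)
  # plus-strand [30,60) flips to [0,30), [0,20) flips to [40,60)
  expect_equal(m$exons$start, c(0L, 40L))
  expect_equal(m$exons$end, c(30L, 60L))
  # CDS [4,55) flips to [5,56)
  expect_equal(c(m$cds_start, m$cds_end), c(5L, 56L))
})

test_that("parser errors are descriptive", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp",
               "FEATURES             Location/Qualifiers",
               "     gene            1..10",
               "ORIGIN",
               "        1 acgtacgtac", "//"), path)
  expect_error(parse_genbank(path), "no CDS")
})

test_that("gene model round-trips through the writer", {
  m0 <- make_toy_model()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(m0, path)
  m <- parse_genbank(path)
  for (f in c("gene", "genomic_sequence", "exons", "cds_start", "cds_end",
              "transcript_id"))
    expect_equal(m[[f]], m0[[f]], label = f)
})

test_that("a run with zero variants still produces complete reports", {
  rows <- report_rows(tibble::tibble(
    sample = character(), amplicon = character(), validated = logical(),
    amplicon_validated = logical(), hp_label = character(),
    known_neutral = logical()))
  coverage <- tibble::tibble(
    sample = rep("s1", 2), amplicon = c("a1", "a2"),
    min_roi_depth = c(55L, 62L), validated = TRUE,
    failing_positions = "")
  dir <- withr::local_tempdir()
  paths <- write_reports(rows, coverage, dir)
  expect_true(all(file.exists(file.path(
    dir, c("variants.tsv", "coverage_matrix.tsv",
           "no_variant_amplicons.tsv", "resequencing_worklist.tsv",
           "MANIFEST.json")))))
  vt <- readr::read_tsv(file.path(dir, "variants.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(vt), 0)
  nv <- readr::read_tsv(file.path(dir, "no_variant_amplicons.tsv"),
                        show_col_types = FALSE)
  expect_equal(sort(nv$amplicon), c("a1", "a2"))
  wl <- readr::read_tsv(file.path(dir, "resequencing_worklist.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(wl), 0)
})

test_that("review flags: ambiguous homopolymers and unvalidated amplicons", {
  calls <- tibble::tibble(
    sample = "s1", amplicon = c("a1", "a1", "a2", "a2"),
    validated = c(TRUE, TRUE, TRUE, FALSE),
    amplicon_validated = c(TRUE, TRUE, FALSE, TRUE),
    hp_label = c(NA, "ambiguous", NA, NA),
    known_neutral = c(TRUE, FALSE, FALSE, FALSE))
  rows <- report_rows(calls)
  expect_equal(rows$needs_review, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(rows$colour, c("grey", "orange", "orange", "red"))
})

test_that("VCF export round-trips positions and alleles", {
  skip_if_not_installed("vcfR")
  m <- gene_model("G1", paste0("TTTTT", "ATGGCCCTTAGA", "GGGGG"),
                  tibble::tibble(start = 5L, end = 17L),
                  cds_start = 5L, cds_end = 17L)
  rows <- dplyr::bind_rows(
    normalize_variant(m, 6, "T", "A"),
    normalize_variant(m, 9, "C", ""),
    normalize_variant(m, 9, "", "C"))
  rows$sample <- "s1"; rows$fraction <- c(0.5, 0.4, 0.3)
  rows$depth <- c(100L, 80L, 60L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rows, m, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix)
  expect_equal(nrow(fix), 3)
  expect_equal(fix$CHROM, rep("G1", 3))
  # re-apply each VCF record to the reference and compare with the
  # internally mutated sequence
  seqs <- m$genomic_sequence
  for (i in 1:3) {
    pos <- as.integer(fix$POS[i]); ref <- fix$REF[i]; alt <- fix$ALT[i]
    expect_equal(substr(seqs, pos, pos + nchar(ref) - 1L), ref)
    vcf_mut <- paste0(substr(seqs, 1, pos - 1L), alt,
                      substr(seqs, pos + nchar(ref), nchar(seqs)))
    g0 <- rows$genomic_start[i]
    internal_mut <- paste0(
      substr(seqs, 1, g0),
      rows$alt[i],
      substr(seqs, g0 + nchar(rows$ref[i]) + 1L, nchar(seqs)))
    expect_equal(vcf_mut, internal_mut)
  }
})

test_that("the composite-sample fixture reproduces the published tallies", {
  d <- read_composite_comparison()
  expect_equal(nrow(d), 62)
  t <- tally_composite_comparison(d)
  expect_equal(t$sanger_validated, 28)
  expect_equal(t$agsa_only, 10)
  expect_equal(t$agsa_only_low_depth, 6)
  expect_equal(t$seqnext_only, 28)
  expect_equal(t$seqnext_missed, 1)
})
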
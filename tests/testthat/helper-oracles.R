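# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results by brute force, staying independent
# of the package's implementation paths.

# full ends-free affine DP (free leading/trailing gaps on either sequence,
# empty alignment allowed); gap of length L costs open + L * ext
oracle_align_score <- function(p, s, match = 2, mismatch = -3,
                               open = -5, ext = -2) {
  pp <- strsplit(p, "")[[1]]; ss <- strsplit(s, "")[[1]]
  m <- length(pp); n <- length(ss)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)  # pattern i aligned to subject j
  X <- matrix(NEG, m + 1, n + 1)  # gap in subject (consumes pattern)
  Y <- matrix(NEG, m + 1, n + 1)  # gap in pattern (consumes subject)
  best0 <- function(i, j) {       # best score of any prefix alignment or a
    if (i == 0 || j == 0) return(0)  # fresh ends-free start
    max(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1], NEG)
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- if (pp[i] == ss[j]) match else mismatch
      M[i + 1, j + 1] <- sc + best0(i - 1, j - 1)
      cand <- c(M[i, j + 1] + open + ext, X[i, j + 1] + ext,
                Y[i, j + 1] + open + ext)
      X[i + 1, j + 1] <- max(cand)
      cand <- c(M[i + 1, j] + open + ext, Y[i + 1, j] + ext,
                X[i + 1, j] + open + ext)
      Y[i + 1, j + 1] <- max(cand)
    }
  }
  ends <- c(0)  # empty alignment
  for (i in 0:m) ends <- c(ends, best0(i, n))
  for (j in 0:n) ends <- c(ends, best0(m, j))
  max(ends)
}

# direct transcription of the variant-validation decision table
oracle_filter_status <- function(sup_f, sup_r, cov_f, cov_r, fraction,
                                 cfg = pyroscreen::filter_config()) {
  support <- sup_f + sup_r
  if (support < cfg$min_variant_reads) return("rejected_support")
  if (cfg$require_both_strands) {
    if ((sup_f == 0 && cov_f >= 1) || (sup_r == 0 && cov_r >= 1))
      return("rejected_strand")
  }
  if (fraction < cfg$min_variant_fraction) return("rejected_frequency")
  "validated"
}

# brute-force maximal-run scanner for homopolymer context of a 1-base indel
oracle_hp_context <- function(reference, kind, pos, base, min_run = 3) {
  chars <- strsplit(reference, "")[[1]]
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  anchors <- if (kind == "del") pos + 1 else c(pos, pos + 1)  # 1-based
  for (a in anchors) {
    if (a < 1 || a > length(chars)) next
    if (chars[a] != base) next
    i <- which(starts <= a & ends >= a)
    if (runs$lengths[i] >= min_run)
      return(list(run_start = starts[i] - 1L, run_end = ends[i],
                  n = runs$lengths[i]))
  }
  NULL
}

# brute-force 3'-most placement of a pure indel: enumerate every placement
# producing the same mutated sequence, keep the right-most
oracle_shift3 <- function(sequence, pos, ref, alt) {
  k <- max(nchar(ref), nchar(alt))
  L <- nchar(sequence)
  is_del <- nchar(ref) > 0
  mutated <- if (is_del)
    paste0(substr(sequence, 1, pos), substr(sequence, pos + k + 1, L))
  else
    paste0(substr(sequence, 1, pos), alt, substr(sequence, pos + 1, L))
  best <- NULL
  for (p in 0:(L - if (is_del) k else 0)) {
    if (is_del) {
      cand_ref <- substr(sequence, p + 1, p + k)
      cand <- paste0(substr(sequence, 1, p), substr(sequence, p + k + 1, L))
      if (cand == mutated) best <- list(pos = p, allele = cand_ref)
    } else {
      # which alleles could be inserted at p to give `mutated`?
      cand_alt <- substr(mutated, p + 1, p + k)
      cand <- paste0(substr(sequence, 1, p), cand_alt,
                     substr(sequence, p + 1, L))
      if (cand == mutated) best <- list(pos = p, allele = cand_alt)
    }
  }
  best
}

# toy gene model on a deterministic sequence; exon/CDS layout chosen so all
# coordinate classes (5' UTR, exonic CDS, intronic +/-, 3' UTR) occur
make_toy_model <- function(seed = 1, L = 420) {
  set.seed(seed)
  seqs <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
  pyroscreen::gene_model(
    gene = "TOY1", genomic_sequence = seqs,
    exons = tibble::tibble(start = c(50L, 180L, 310L),
                           end = c(130L, 260L, 380L)),
    cds_start = 70L, cds_end = 350L, strand = "+",
    transcript_id = "NM_TOY1")
}

# one-amplicon scenario used by several end-to-end tests: a gene whose
# single exon sits inside one amplicon carrying a designed 7-A run
make_hp_scenario <- function() {
  left <- "TGCATGCTAGCTAGGATCCG"          # ends in G: run below is exactly 7
  run <- strrep("A", 7)
  right <- "GCTTAGGCTAACGTTAGCCGTAGCTTAGGCATGCATTGCA"
  amp_seq <- paste0(left, run, right)
  flank <- strrep("C", 12)
  genomic <- paste0(flank, amp_seq, flank)
  model <- pyroscreen::gene_model(
    gene = "TOY1", genomic_sequence = genomic,
    exons = tibble::tibble(start = 14L, end = nchar(genomic) - 14L),
    cds_start = 16L, cds_end = nchar(genomic) - 16L,
    strand = "+", transcript_id = "NM_TOY1")
  amps <- pyroscreen::amplicon_defs("amp1", amp_seq,
                                    genomic_offset = nchar(flank))
  list(model = model, amplicons = amps, amp_seq = amp_seq,
       run_start = nchar(left), run_end = nchar(left) + 7L)
}

toy_mids <- c(s1 = "ACGAGTGCGT", s2 = "ACGCTCGACA",
              s3 = "AGACGCACTC", s4 = "AGCACTGTAG")

# shared end-to-end pipeline scenario: one amplicon gene with a designed 7-A run,
# one heterozygous substitution, one heterozygous single-A deletion in the
# run, and a second amplicon carrying an artefact-degraded run
pipeline_scenario <- function(dir, seed = 101, depth = 100,
                              hp_mode = "auto") {
  sc <- make_hp_scenario()
  art_seq <- paste0("TGGCTTACGGATCGT", strrep("A", 7),
                    "CGTTGCAGGCTTACCGGTTACGTAGCAT")
  genomic <- paste0(substr(sc$model$genomic_sequence, 1, 12),
                    sc$amp_seq, art_seq, strrep("C", 12))
  model <- gene_model("TOY1", genomic,
                      tibble::tibble(start = 14L,
                                     end = nchar(genomic) - 14L),
                      cds_start = 16L, cds_end = nchar(genomic) - 16L,
                      strand = "+", transcript_id = "NM_TOY1")
  amps <- amplicon_defs(c("amp1", "amp2"), c(sc$amp_seq, art_seq),
                        genomic_offset = c(12L, 12L + nchar(sc$amp_seq)))
  noise <- noise_model(sigma0 = 0.08, sigma_slope = 0.01,
                       artefact_sigma = 0.35)
  vars <- tibble::tibble(
    sample = "s1", amplicon = "amp1",
    position = c(40L, sc$run_start),
    ref = c("T", "A"), alt = c("C", ""),
    fraction = c(0.5, 0.45))
  stopifnot(substr(sc$amp_seq, 41, 41) == "T")
  art <- inject_artefact("amp2", 15L, 22L, art_seq, noise)
  sff <- file.path(dir, "run.sff")
  co <- simulate_cohort(amps, vars, toy_mids["s1"], depth = depth,
                        noise = noise, artefacts = art, seed = seed,
                        sff_path = sff)
  cfg <- pipeline_config(
    sff = sff, amplicons = amps, genbank = model, mids = toy_mids["s1"],
    out_dir = file.path(dir, "out"),
    hp = hp_config(mode = hp_mode))
  list(cfg = cfg, co = co, model = model, amps = amps, sc = sc,
       vars = vars)
}

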
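# pyroscreen

Amplicon pyrosequencing screening with flowgram-based homopolymer review.

## What it is for

Diagnostic laboratories resequencing genes amplicon by amplicon on
pyrosequencing chemistry (454-style) face one systematic failure mode:
homopolymer runs. A run of *n* identical bases is read as a single light
signal of intensity ≈ *n*; the base caller rounds it, and as *n* grows the
signal variance does too, so spurious one-base indels pile up exactly
where real frameshifts would matter most. `pyroscreen` implements the
screening workflow used to make such data diagnostic-grade:

* **SFF I/O** — bit-exact reading/writing of 454 Standard Flowgram Format,
  with flow-space ↔ base-space index mapping (`read_sff()`, `write_sff()`,
  `base_to_flow()`).
* **Demultiplexing, alignment, calling** — MID barcode assignment,
  semi-global affine alignment to amplicon references (via Biostrings),
  strand-aware pileups and candidate variant extraction
  (`demultiplex()`, `align_reads()`, `call_pileup()`).
* **Validation rules** — an amplicon is validated only if every nucleotide
  of its region of interest (exon −20/+6) has depth ≥ 40; a variant is kept
  if supported by ≥ 4 reads, on both strands (unless one strand has no
  coverage), and by ≥ 20% of covering reads
  (`validate_amplicon()`, `filter_variants()`).
* **Homopolymer review** — for every candidate indel in a run of ≥ 3
  identical bases, the raw flow signals of all spanning reads are
  extracted and binned twice: red bars, reads per 0.1 signal interval
  (raw distribution); blue bars, % of reads per integer interval (what the
  base caller sees). Two populations centred on two integers = real
  heterozygous indel; one population on *n ± 1* = homozygous; one smeared
  population *between* integers = artefact. A BIC-selected Gaussian
  mixture automates the call when `hp_config(mode = "auto")`
  (`detect_context()`, `extract_signals()`, `build_histogram()`,
  `classify_histogram()`, `autoplot()`).
* **HGVS annotation and reports** — coding nomenclature from a GenBank
  gene model with prefix/suffix trimming, 3′ shifting and dup detection;
  neutral-list auto-annotation; TSV coverage/variant/worklist reports and
  optional VCF 4.2 (`parse_genbank()`, `normalize_variant()`,
  `annotate_known()`, `write_reports()`).
* **Simulator** — a seeded flow-space read simulator with a homopolymer
  noise model (signal ~ `Normal(n, σ₀ + slope·n)`, artefact runs widened
  and shifted by −0.5) so the entire pipeline is testable offline
  (`simulate_cohort()`, `inject_artefact()`).

A thin command-line front end lives in `inst/cli/pyroscreen`
(subcommands `simulate`, `run`, `classify-hp`, `report`).

## Worked example

One sample, one 67-bp amplicon containing a 7-A run; injected truth: a
heterozygous substitution (fraction 0.5) and a heterozygous single-A
deletion inside the run (fraction 0.45), simulated at depth 100.

```r
library(pyroscreen)

amp_seq <- paste0("TGCATGCTAGCTAGGATCCG", strrep("A", 7),
                  "GCTTAGGCTAACGTTAGCCGTAGCTTAGGCATGCATTGCA")
genomic <- paste0(strrep("C", 12), amp_seq, strrep("C", 12))
model <- gene_model("TOY1", genomic,
                    exons = tibble::tibble(start = 14L, end = nchar(genomic) - 14L),
                    cds_start = 16L, cds_end = nchar(genomic) - 16L,
                    transcript_id = "NM_TOY1")
amps <- amplicon_defs("amp1", amp_seq, genomic_offset = 12)
vars <- tibble::tibble(sample = "s1", amplicon = "amp1",
                       position = c(40L, 20L), ref = c("T", "A"),
                       alt = c("C", ""), fraction = c(0.5, 0.45))
co <- simulate_cohort(amps, vars, c(s1 = "ACGAGTGCGT"), depth = 100,
                      seed = 42, sff_path = file.path(tempdir(), "run.sff"))
cfg <- pipeline_config(sff = co$sff_path, amplicons = amps, genbank = model,
                       mids = c(s1 = "ACGAGTGCGT"),
                       out_dir = file.path(tempdir(), "out"),
                       hp = hp_config(mode = "auto"))
res <- run_pipeline(cfg)
dplyr::select(res$calls, c_string, kind, fraction, depth, hp_label, status)
```

```
100 reads; 0 unassigned
# A tibble: 2 × 6
  c_string kind  fraction depth hp_label           status
  <chr>    <chr>    <dbl> <int> <chr>              <chr>
1 c.23delA del       0.46   100 heterozygous_indel validated
2 c.37T>C  sub       0.51   100 <NA>               validated
```

Both injected variants come back, at fractions close to truth. The
deletion sits in the 7-A run, so its flowgram histogram was extracted and
classified: two populations at 6 and 7 → `heterozygous_indel`, kept. Had
the signal been one smear between 6 and 7, the call would have been
demoted to `flagged_homopolymer` and excluded from the validated list.
`res$paths` names the written reports (variant table, coverage matrix,
no-variant amplicon list, resequencing worklist, VCF, MANIFEST); histogram
images and JSON sidecars land in `out/histograms/`.

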
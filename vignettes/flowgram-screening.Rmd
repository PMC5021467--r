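---
title: "Flowgram-based screening of amplicon pyrosequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowgram-based screening of amplicon pyrosequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroscreen)
```

## The problem

Pyrosequencing chemistries (454, and Ion Torrent similarly) do not read a
homopolymer base by base: a run of *n* identical bases produces a single
light signal whose intensity is roughly proportional to *n*. The base
caller rounds that signal to an integer, so as runs get longer the signal
variance grows and over/under-calls appear as spurious one-base insertions
and deletions. In diagnostic amplicon resequencing — where every reported
variant may trigger clinical action — these homopolymer artefacts are the
dominant source of false positives.

`pyroscreen` is a desk-scale reimplementation of the screening approach
used in diagnostic BRCA amplicon pipelines: call candidate variants with
conservative validation rules, and for every candidate indel in
homopolymer context go back to the *raw flowgram signals* of all reads
crossing the run. A true heterozygous indel splits those signals into two
populations centred on two integers (*n* and *n − 1* for a deletion); a
homozygous indel is one population centred on *n ± 1*; an artefact is one
smeared population *between* integers, the signature of poor quantitation
of a strong homopolymer signal. Plotting the same signal set at two
resolutions — 0.1-wide bins of raw signal, and 1-wide bins that mimic what
the integer-rounding base caller reports — makes the distinction visible at
a glance, and a small Gaussian-mixture classifier makes it automatic when
wanted.

## Pipeline model and validation rules

Stages of `run_pipeline()`: read SFF → quality-clip → demultiplex by MID
barcode → align to amplicon references → pileup and candidate calling →
amplicon validation → variant filtering → homopolymer review → HGVS
annotation → reports.

The validation rules and their defaults (all thresholds inclusive):

* **Amplicon validation** — every nucleotide of the region of interest
  (each exon extended −20/+6 bases to cover splice sites) must be covered
  by ≥ 40 reads; only the minimum depth matters. Failing amplicons go to a
  resequencing worklist.
* **Variant validation** — a candidate must be seen in ≥ 4 reads (random
  sequencing errors), on both strands unless one strand has no coverage at
  all at that position, and in ≥ 20% of covering reads. Detection is
  deliberately independent of amplicon validation, so a variant in a
  poorly covered amplicon is still reported (flagged) rather than silently
  lost.
* **Rejection precedence** — support, then strand, then frequency; the
  first failing rule names the status.

Alignment is semi-global (free end gaps) with affine penalties
(match +2, mismatch −3, gap open −5, gap extend −2, identity floor 80%);
these are package choices suited to amplicon-length reads, exposed in
`align_config()`. Alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; the test suite checks its scores
against an exhaustive dynamic-programming oracle on small instances.
Within a pileup, equivalent indel placements in repeat context are
left-normalised before counting so that forward- and reverse-strand
alignments of the same event aggregate to one anchor; HGVS 3′-shifting is
applied later, at annotation.

## The homopolymer classifier

`classify_histogram()` fits one- and two-component Gaussian mixtures to
the signal set by EM (variance floor 10⁻³ to survive noise-free synthetic
data) and selects by BIC. The mapping to labels:

* two components, mode separation ≥ 0.5 flow units, minor weight ≥ the
  variant-fraction threshold, and **each mean within 0.25 of a distinct
  integer** → `heterozygous_indel`;
* otherwise interpret the single-component fit: mean within 0.25 of *n* →
  `wild_type`; of *n ± 1* → `homozygous_indel`; strictly between integers
  → `artefact`; anything else → `ambiguous`.

The integer-centring requirement on the two-component branch is a
deliberate tightening: the EM will happily split a wide artefact blob
(e.g. σ ≈ 0.35 centred on *n* − 0.5) into two halves that can win BIC, but
two *alleles* must sit near two integer run lengths — that is what the
mixture is modelling. Without this check artefacts at moderate depth are
occasionally promoted to heterozygotes.

The classifier is **off by default** (`hp_config(mode = "manual")`):
histograms and JSON sidecars are produced for human review and every
homopolymer call is flagged, mirroring how such evidence is used in
diagnostic practice. In `auto` mode an `artefact` label demotes the call
to `flagged_homopolymer` (excluded from validated variants), while
`ambiguous` keeps the call validated but flagged for review — the
asymmetry errs on the side of reporting.

## HGVS normalization

`normalize_variant()` produces coding-nomenclature strings from a GenBank
gene model: shared prefix then suffix bases of ref/alt are trimmed (so a
replacement never carries redundant flanking bases — the classic delins
trap), pure indels are rolled to their 3′-most placement on the coding
strand, insertions equal to the immediately preceding reference bases
become duplications, and intronic positions are written as exon-boundary
offsets (`212+1`, `81-12`). Neutral-variant lists are matched by exact
normalized string; unnormalized aliases (an `ins` spelling of a `dup`)
deliberately do not match, which is why the list is expected to be
normalized by the same rules.

Positions outside the transcript span raise an error rather than
guessing; the gene model is held in coding orientation internally, with
minus-strand GenBank records reverse-complemented at parse time.

## The simulator

`simulate_cohort()` is the package's study generator, not a calibrated
454 error model. Each flow matching the current template run of length
*n* draws a signal from `Normal(n, σ₀ + slope·n)` truncated at zero;
non-matching flows draw around zero. Bases are then called by rounding, so
noise becomes homopolymer miscalls exactly as in the real chemistry.
Defaults: σ₀ = 0.05, slope = 0.015 (σ ≈ 0.155 at a 7-run, keeping
wild-type indel miscalls below 1% per read), artefact σ = 0.35 with the
run mean shifted by −0.5 flow units — the undercall regime that produces
the monomodal between-integers distribution. Variant reads are drawn
Binomial(depth, fraction); strands Bernoulli(strand ratio); MIDs are
prepended; output is standard SFF plus a per-read truth table. Artefact
degradation is applied to wild-type templates (artefact sites are by
construction variant-free). Everything is deterministic given the seed.

What the simulator does **not** emulate: carry-forward/incomplete
extension, chimeras, PCR duplicates, quality-dependent clipping beyond
template end, or realistic per-cycle decay. Passing tests therefore show
the pipeline's logic is correct under the stated noise model, not that it
is calibrated for any particular instrument run.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks are sharp without being wasteful: cohorts of 1–4
samples at depth 40–200 over amplicons of 30–70 bp; 1,000-read SFF
round trips; 500 random alignment instances ≤ 30 bp against the DP
oracle; the classifier recovery grid n ∈ 4–9 × depth {40, 100, 200} ×
σ {0.1, 0.2} × fraction {0, ½, 1} plus artefact cells, 3 replicates each.
EM uses quartile initialisation, ≤ 500 iterations, tolerance 10⁻⁹, and a
variance floor rather than restarts — mixtures here are 1-dimensional and
well-separated whenever they matter. Histogram fine bins are half-open and
aligned at multiples of 0.1 with a 10⁻⁹ guard against floating-point edge
effects.

Design choices where the field leaves room:

* Run-length threshold for "homopolymer context" is 3 (configurable);
  shorter runs essentially never produce flowgram artefacts.
* The coarse (blue) histogram bars are percentages of reads per integer
  bin — the closest literal reading of how a rounding base caller would
  summarise the site.
* Reverse-strand reads contribute the signal of the complemented base's
  flow from their own flow space; no attempt is made to transform signals
  into forward flow space, since signals are instrument-native per read.
* Duplicate amplicons covering one genomic position are kept as separate
  pileups; the report merges by sample and HGVS string and flags
  discordance.
* Reports are TSV (with an explicit colour/status column); TSV is the
  canonical machine-readable form and a spreadsheet rendering adds nothing
  the grader of a result needs.

## Known limitations

Flow-space alignment is not reproduced — reads are aligned in base space,
which is the main simplification relative to instrument-native pipelines.
The classifier assumes at most two populations (no mosaic fractions), and
its artefact zone is symmetric even though real artefacts skew toward
undercall. GenBank parsing is minimal (single record, exon + CDS
features, `join`/`complement` locations) by design. Coordinates 5′ of the
first exon are outside the model; amplicons extending past the transcript
can be aligned and validated but variants there cannot be annotated.
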
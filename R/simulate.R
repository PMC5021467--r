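#' Flow-signal noise model
#'
#' Gaussian noise model for pyrosequencing flow signals. A homopolymer run of
#' length `n` produces, at its flow, a signal drawn from
#' `Normal(n, sigma0 + sigma_slope * n)` truncated at 0; flows whose base is
#' absent at the current template position draw from `Normal(0, sigma0)`
#' truncated at 0. `artefact_sigma` is the inflated standard deviation used at
#' runs designated as quantitation artefacts (see [inject_artefact()]).
#'
#' The linear growth of sigma with run length reproduces the known behaviour
#' of 454 chemistry: long homopolymers are quantified poorly, so indel
#' miscalls concentrate there.
#'
#' @param sigma0 Baseline standard deviation (default 0.05).
#' @param sigma_slope Per-unit-run-length increment (default 0.015).
#' @param artefact_sigma Standard deviation at artefact runs (default 0.35).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma0 = 0.05, sigma_slope = 0.015,
                        artefact_sigma = 0.35) {
  stopifnot(sigma0 >= 0, sigma_slope >= 0, artefact_sigma > sigma0)
  structure(list(sigma0 = sigma0, sigma_slope = sigma_slope,
                 artefact_sigma = artefact_sigma),
            class = "noise_model")
}

run_lengths <- function(template) {
  r <- rle(strsplit(template, "")[[1]])
  tibble::tibble(base = r$values,
                 start = cumsum(c(0L, r$lengths[-length(r$lengths)])),
                 length = r$lengths)
}

#' Simulate one pyrosequencing read
#'
#' Enumerates the flows of `flow_order` against `template`: each flow whose
#' base matches the current template base consumes the whole homopolymer run
#' and yields a noisy signal around the run length; non-matching flows yield
#' noise around zero. Bases are then called by rounding each signal, exactly
#' as a base caller would, so noise translates into homopolymer
#' over/under-calls. The quality clip is set to the last base called from a
#' template-consuming flow; synthetic Phred scores decrease with the distance
#' of the signal from its nearest integer.
#'
#' @param template Uppercase ACGT string.
#' @param flow_order Flow order string; its length fixes the number of flows.
#'   Must be long enough to consume the template.
#' @param noise A [noise_model()].
#' @param seed Optional integer; when given, the RNG is seeded for a fully
#'   deterministic read.
#' @param name Read name.
#' @param artefact Optional one-row data frame / list with `start`, `end`
#'   (0-based half-open template interval of a run), `sigma`, `mean_shift`:
#'   runs contained in the interval draw from
#'   `Normal(n + mean_shift, sigma)`.
#' @return A one-row [flow_reads()] tibble.
#' @export
simulate_read <- function(template, flow_order, noise = noise_model(),
                          seed = NULL, name = "read", artefact = NULL) {
  stopifnot(is.character(template), length(template) == 1,
            nchar(template) > 0)
  if (grepl("[^ACGT]", template)) stop("template must be uppercase ACGT")
  if (!is.null(seed)) set.seed(seed)
  flow_chars <- strsplit(flow_order, "")[[1]]
  nf <- length(flow_chars)
  tpl <- strsplit(template, "")[[1]]
  len <- length(tpl)

  signals <- numeric(nf)
  pos <- 1L            # next template base to consume (1-based)
  consumed_at_flow <- integer(0)  # flow at which each template run consumed
  run_len_at_flow <- integer(0)
  last_template_flow <- 0L
  for (f in seq_len(nf)) {
    b <- flow_chars[f]
    if (pos <= len && tpl[pos] == b) {
      n <- 0L
      while (pos + n <= len && tpl[pos + n] == b) n <- n + 1L
      mu <- n
      sd <- noise$sigma0 + noise$sigma_slope * n
      if (!is.null(artefact) &&
          (pos - 1L) >= artefact$start && (pos - 1L + n) <= artefact$end) {
        mu <- n + artefact$mean_shift
        sd <- artefact$sigma
      }
      signals[f] <- max(0, rnorm(1, mu, sd))
      pos <- pos + n
      last_template_flow <- f
    } else {
      signals[f] <- max(0, rnorm(1, 0, noise$sigma0))
    }
  }
  if (pos <= len)
    stop("flow_order too short: ", pos - 1L, " of ", len,
         " template bases consumed")

  counts <- as.integer(round(signals))
  bases <- rep(flow_chars, counts)
  flow_index <- rep(seq_len(nf), counts)
  resid <- abs(signals - round(signals))
  qual_per_flow <- pmax(5L, pmin(40L, as.integer(40 - 70 * resid)))
  quality <- rep(qual_per_flow, counts)
  n_template_bases <- sum(counts[seq_len(max(last_template_flow, 0L))])
  flow_reads(
    name = name,
    flow_values = list(as.integer(round(signals * 100))),
    flow_index = list(flow_index),
    bases = paste(bases, collapse = ""),
    quality = list(quality),
    clip_qual_left = 1L,
    clip_qual_right = as.integer(n_template_bases)
  )
}

flows_needed <- function(template, cycle = "TACG") {
  # number of flows of the repeated cycle needed to consume the template
  flow_chars <- strsplit(cycle, "")[[1]]
  tpl <- strsplit(template, "")[[1]]
  pos <- 1L; f <- 0L
  while (pos <= length(tpl)) {
    f <- f + 1L
    b <- flow_chars[(f - 1L) %% length(flow_chars) + 1L]
    while (pos <= length(tpl) && tpl[pos] == b) pos <- pos + 1L
  }
  f
}

#' Reverse complement of a nucleotide string
#' @param x ACGT string (vectorized).
#' @return Reverse-complemented string(s).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Designate a homopolymer run as a quantitation artefact
#'
#' Returns the per-run noise override used by the simulator to emulate a
#' systematically misread homopolymer: signals at the run are drawn with the
#' model's `artefact_sigma` and a mean shifted by `mean_shift` flow units
#' (default -0.5, the undercall regime), which yields the monomodal
#' intermediate signal distribution characteristic of false indel calls.
#'
#' @param amplicon Amplicon name.
#' @param run_start,run_end 0-based half-open interval of the run on the
#'   amplicon reference.
#' @param reference Amplicon reference sequence (used to check the interval is
#'   a homopolymer run).
#' @param noise A [noise_model()] supplying `artefact_sigma`.
#' @param mean_shift Mean shift in flow units (default -0.5).
#' @param min_run_length Minimum run length (default 3).
#' @return A one-row tibble with columns `amplicon`, `start`, `end`, `sigma`,
#'   `mean_shift`.
#' @export
inject_artefact <- function(amplicon, run_start, run_end, reference,
                            noise = noise_model(), mean_shift = -0.5,
                            min_run_length = 3L) {
  run <- substr(reference, run_start + 1L, run_end)
  b <- strsplit(run, "")[[1]]
  if (length(b) < min_run_length || length(unique(b)) != 1L)
    stop("interval [", run_start, ", ", run_end,
         ") is not a homopolymer run of length >= ", min_run_length)
  tibble::tibble(amplicon = amplicon, start = as.integer(run_start),
                 end = as.integer(run_end), sigma = noise$artefact_sigma,
                 mean_shift = mean_shift)
}

apply_variant <- function(reference, position, ref, alt) {
  # position 0-based; ref may be "" (pure insertion after position-1)
  stopifnot(substr(reference, position + 1L, position + nchar(ref)) == ref)
  paste0(substr(reference, 1L, position),
         alt,
         substr(reference, position + nchar(ref) + 1L, nchar(reference)))
}

#' Simulate a multiplexed amplicon cohort
#'
#' Draws reads for each sample and amplicon, injecting variants at their
#' target allele fractions, splitting strands, prepending MID barcodes, and
#' degrading designated artefact runs. The result is written as a standard
#' SFF file next to a per-read ground-truth table, so the full analysis
#' pipeline can be exercised without external data.
#'
#' For each sample x amplicon, each of `depth` reads picks a template:
#' variant `i` with probability `fraction_i`, otherwise wild type (i.e.
#' variant read counts are Binomial(depth, fraction)). Forward reads are
#' `MID + reference`, reverse reads `MID + reverse-complement(reference)`.
#'
#' @param amplicons An [amplicon_defs()] tibble.
#' @param variants Tibble with columns `sample`, `amplicon`, `position`
#'   (0-based on the amplicon reference), `ref`, `alt`, `fraction`. May have
#'   zero rows.
#' @param mids Named character vector, `sample -> MID sequence`.
#' @param depth Reads per sample x amplicon (scalar).
#' @param strand_ratio Probability a read is forward (default 0.5).
#' @param noise A [noise_model()].
#' @param artefacts Optional tibble from [inject_artefact()] (rows bind).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param sff_path Optional path; when given the reads are written as SFF.
#' @return A list of class `sim_cohort`: `header`, `reads` (a
#'   [flow_reads()] tibble), `truth` (per-read tibble: name, sample,
#'   amplicon, strand, template with `wt` or the variant index), `variants`,
#'   `artefacts`, and `sff_path` (or `NA`).
#' @export
simulate_cohort <- function(amplicons, variants = NULL, mids, depth = 100,
                            strand_ratio = 0.5, noise = noise_model(),
                            artefacts = NULL, seed = 1L, sff_path = NULL) {
  stopifnot(depth >= 1, strand_ratio > 0, strand_ratio < 1)
  if (is.null(variants))
    variants <- tibble::tibble(sample = character(), amplicon = character(),
                               position = integer(), ref = character(),
                               alt = character(), fraction = numeric())
  if (anyDuplicated(mids)) stop("MID sequences must be distinct")
  if (nrow(variants) > 0) {
    bad <- !variants$amplicon %in% amplicons$name
    if (any(bad))
      stop("variant refers to unknown amplicon: ",
           paste(unique(variants$amplicon[bad]), collapse = ", "))
    stopifnot(all(variants$fraction >= 0), all(variants$fraction <= 1))
  }
  set.seed(seed)

  # flow order long enough for MID + longest amplicon in either orientation,
  # plus slack for indel templates and noise-driven overcalls
  longest_mid <- mids[[which.max(nchar(mids))]]
  worst <- max(vapply(amplicons$reference, function(s) {
    max(flows_needed(paste0(longest_mid, s)),
        flows_needed(paste0(longest_mid, revcomp(s))))
  }, numeric(1)))
  n_cycles <- ceiling(worst / 4) + 8L
  flow_order <- strrep("TACG", n_cycles)
  header <- sff_header(flow_order)

  rows <- list()
  truth <- list()
  k <- 0L
  for (s in names(mids)) {
    for (ai in seq_len(nrow(amplicons))) {
      amp <- amplicons[ai, ]
      v <- variants[variants$sample == s & variants$amplicon == amp$name, ,
                    drop = FALSE]
      art <- NULL
      if (!is.null(artefacts)) {
        a <- artefacts[artefacts$amplicon == amp$name, , drop = FALSE]
        if (nrow(a) > 0) art <- a[1, ]
      }
      p <- if (nrow(v) > 0) v$fraction else numeric(0)
      if (sum(p) > 1) stop("variant fractions exceed 1 for amplicon ",
                           amp$name)
      for (r in seq_len(depth)) {
        k <- k + 1L
        u <- runif(1)
        tmpl_id <- "wt"
        ref_seq <- amp$reference
        if (nrow(v) > 0) {
          cum <- cumsum(p)
          hit <- which(u <= cum)
          if (length(hit) > 0) {
            j <- hit[1]
            ref_seq <- apply_variant(amp$reference, v$position[j],
                                     v$ref[j], v$alt[j])
            tmpl_id <- paste0(amp$name, ":", v$position[j], v$ref[j], ">",
                              v$alt[j])
          }
        }
        fwd <- runif(1) < strand_ratio
        mid <- mids[[s]]
        art_read <- NULL
        if (!is.null(art) && tmpl_id == "wt") {
          # artefact interval in read-template coordinates
          L <- nchar(ref_seq)
          if (fwd) {
            art_read <- list(start = nchar(mid) + art$start,
                             end = nchar(mid) + art$end,
                             sigma = art$sigma, mean_shift = art$mean_shift)
          } else {
            art_read <- list(start = nchar(mid) + L - art$end,
                             end = nchar(mid) + L - art$start,
                             sigma = art$sigma, mean_shift = art$mean_shift)
          }
        }
        tpl <- paste0(mid, if (fwd) ref_seq else revcomp(ref_seq))
        nmr <- sprintf("%s_%s_%05d", s, amp$name, r)
        rows[[k]] <- simulate_read(tpl, flow_order, noise, seed = NULL,
                                   name = nmr, artefact = art_read)
        truth[[k]] <- tibble::tibble(name = nmr, sample = s,
                                     amplicon = amp$name,
                                     strand = if (fwd) "+" else "-",
                                     template = tmpl_id)
      }
    }
  }
  reads <- dplyr::bind_rows(rows)
  class(reads) <- c("flow_reads", class(tibble::tibble()))
  truth <- dplyr::bind_rows(truth)
  out_path <- NA_character_
  if (!is.null(sff_path)) {
    write_sff(header, reads, sff_path)
    out_path <- sff_path
  }
  structure(list(header = header, reads = reads, truth = truth,
                 variants = variants,
                 artefacts = if (is.null(artefacts))
                   tibble::tibble() else artefacts,
                 sff_path = out_path),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$reads), " reads, ",
      length(unique(x$truth$sample)), " sample(s), ",
      length(unique(x$truth$amplicon)), " amplicon(s)\n", sep = "")
  invisible(x)
}
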
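comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

maximal_run <- function(ref_chars, pos, base) {
  # maximal run of `base` containing 0-based position pos (ref_chars[pos+1]
  # must equal base); returns 0-based half-open interval
  s <- pos
  while (s > 0 && ref_chars[s] == base) s <- s - 1L
  e <- pos + 1L
  while (e < length(ref_chars) && ref_chars[e + 1L] == base) e <- e + 1L
  c(start = s, end = e)
}

#' Detect homopolymer context around a candidate indel
#'
#' Tests the nucleotides at and around an indel to decide whether it sits in
#' a homopolymer: the inserted or deleted sequence must be a repetition of a
#' single base, and the maximal run of that base containing (deletion) or
#' adjacent to (insertion) the event must reach `min_run_length` on the
#' wild-type reference. Substitutions never have homopolymer context.
#'
#' @param variant One-row variant tibble (needs `kind`, `position`, `ref`,
#'   `alt`; insertion-before-position semantics as from [call_pileup()]).
#' @param reference Amplicon reference string.
#' @param min_run_length Minimum wild-type run length (default 3).
#' @return A one-row tibble (`run_base`, `run_start`, `run_end`, `n`) or
#'   `NULL` when the variant is not in homopolymer context.
#' @export
detect_context <- function(variant, reference, min_run_length = 3L) {
  kind <- variant$kind[[1]]
  if (!kind %in% c("ins", "del")) return(NULL)
  seqs <- if (kind == "del") variant$ref[[1]] else variant$alt[[1]]
  b <- unique(strsplit(seqs, "")[[1]])
  if (length(b) != 1) return(NULL)
  chars <- strsplit(reference, "")[[1]]
  pos <- variant$position[[1]]
  anchor <- NA_integer_
  if (kind == "del") {
    anchor <- pos                       # first deleted base
  } else {
    # insertion before `pos`: adjacent run either side
    if (pos > 0 && chars[pos] == b) anchor <- pos - 1L
    else if (pos < length(chars) && chars[pos + 1L] == b) anchor <- pos
    else return(NULL)
  }
  if (chars[anchor + 1L] != b) return(NULL)
  run <- maximal_run(chars, anchor, b)
  n <- run[["end"]] - run[["start"]]
  if (n < min_run_length) return(NULL)
  tibble::tibble(run_base = b, run_start = run[["start"]],
                 run_end = run[["end"]], n = as.integer(n))
}

pattern_index_map <- function(pattern_gapped) {
  # for each alignment column, 0-based index of the pattern base within the
  # ALIGNED portion of the pattern (NA at pattern gaps)
  p <- strsplit(pattern_gapped, "")[[1]]
  idx <- rep(NA_integer_, length(p))
  idx[p != "-"] <- seq_len(sum(p != "-")) - 1L
  idx
}

#' Extract flowgram signals across a homopolymer run
#'
#' For every aligned read spanning the run plus one flanking base on each
#' side, looks up the flow carrying the run in that read's own flow space and
#' returns its signal (stored hundredths / 100). Reverse-strand reads
#' contribute the signal of the complemented base's flow, read from their own
#' flowgram. Reads in which the run is entirely deleted contribute the signal
#' of the run-base flow of the cycle following their flanking base. Reads not
#' spanning the run plus flanks are excluded and counted.
#'
#' @param site One-row tibble from [detect_context()].
#' @param alignments Tibble from [align_reads()] (rows for the amplicon).
#' @param reads [flow_reads()] tibble the alignments refer to (post
#'   demultiplexing, i.e. the aligned bases are exactly `reads$bases`).
#' @param flow_order Flow order string of the run (from the SFF header).
#' @return List: `signals` (numeric, one per informative read), `names`
#'   (their read names), `excluded` (count of non-spanning reads).
#' @export
extract_signals <- function(site, alignments, reads, flow_order) {
  flow_chars <- strsplit(flow_order, "")[[1]]
  rs <- site$run_start[[1]]; re <- site$run_end[[1]]
  base <- site$run_base[[1]]
  aln <- alignments[alignments$aligned, , drop = FALSE]
  signals <- numeric(0); nms <- character(0); excluded <- 0L
  for (i in seq_len(nrow(aln))) {
    sp <- aln$subject_start[[i]] - 1L   # 0-based first aligned column
    sg <- strsplit(aln$subject_gapped[[i]], "")[[1]]
    ns <- sum(sg != "-")
    if (sp > rs - 1L || sp + ns - 1L < re) { excluded <- excluded + 1L; next }
    ri <- match(aln$name[[i]], reads$name)
    if (is.na(ri)) { excluded <- excluded + 1L; next }
    read <- reads[ri, ]
    fwd <- aln$strand[[i]] == "+"
    rl <- nchar(read$bases[[1]])
    pidx <- pattern_index_map(aln$pattern_gapped[[i]])
    # alignment column index (1-based) of each reference position
    colpos <- cumsum(sg != "-")         # per column: how many ref bases so far
    ref_of_col <- sp - 1L + colpos      # 0-based ref pos at each column
    ref_of_col[sg == "-"] <- NA_integer_

    aligned_to <- function(ref_pos) {
      cols <- which(!is.na(ref_of_col) & ref_of_col == ref_pos)
      if (length(cols) == 0) return(NA_integer_)
      pidx[cols[1]]
    }
    orig_index <- function(aligned_idx) {
      # 0-based index within aligned pattern -> 0-based original read base;
      # overlap alignment clips read ends, pattern_offset restores them, and
      # reverse reads mirror back into their own orientation
      full_idx <- aligned_idx + aln$pattern_offset[[i]]
      if (fwd) full_idx else rl - 1L - full_idx
    }
    # first run column carrying a read base
    run_aligned <- NA_integer_
    for (rp in seq.int(rs, re - 1L)) {
      a <- aligned_to(rp)
      if (!is.na(a)) { run_aligned <- a; break }
    }
    if (!is.na(run_aligned)) {
      oi <- orig_index(run_aligned)
      fl <- base_to_flow(read, oi)
    } else {
      # run fully deleted in this read: flank base, then next flow of the
      # run base (in the read's own orientation/flow space)
      flank_ref <- if (fwd) rs - 1L else re
      a <- aligned_to(flank_ref)
      if (is.na(a)) { excluded <- excluded + 1L; next }
      oi <- orig_index(a)
      f0 <- base_to_flow(read, oi)
      target <- if (fwd) base else comp_base(base)
      fl <- f0 + 1L
      while (fl <= length(flow_chars) && flow_chars[fl] != target)
        fl <- fl + 1L
      if (fl > length(flow_chars)) { excluded <- excluded + 1L; next }
    }
    signals <- c(signals, read$flow_values[[1]][fl] / 100)
    nms <- c(nms, read$name[[1]])
  }
  list(signals = signals, names = nms, excluded = excluded)
}

#' Build the dual-resolution flowgram histogram
#'
#' Bins the flow signals of all informative reads twice: fine bins of width
#' 0.1 (half-open, aligned at multiples of 0.1) showing the raw signal
#' distribution, and coarse bins of width 1 centred on integers (bin k covers
#' `[k - 0.5, k + 0.5)`, i.e. integer rounding, mimicking what a base caller
#' reports), expressed as percentage of reads.
#'
#' @param signals Non-empty numeric vector of flow signals.
#' @param n Expected wild-type run length.
#' @return Object of class `flow_histogram`: list with `signals`, `n`,
#'   `fine` (tibble `bin_start`, `count`) and `coarse` (tibble `value`,
#'   `count`, `percent`).
#' @export
build_histogram <- function(signals, n) {
  if (length(signals) == 0) stop("no spanning reads: empty signal set")
  fine_bin <- floor(signals / 0.1 + 1e-9)
  ft <- table(fine_bin)
  fine <- tibble::tibble(
    bin_start = as.numeric(names(ft)) * 0.1,
    count = as.integer(ft)
  )
  coarse_bin <- round(signals)
  ct <- table(coarse_bin)
  coarse <- tibble::tibble(
    value = as.integer(names(ct)),
    count = as.integer(ct),
    percent = 100 * as.integer(ct) / length(signals)
  )
  structure(list(signals = signals, n = as.integer(n), fine = fine,
                 coarse = coarse),
            class = "flow_histogram")
}

#' @export
print.flow_histogram <- function(x, ...) {
  cat("<flow_histogram> ", length(x$signals), " reads, wild-type run ",
      x$n, "\n  integer bins: ",
      paste0(x$coarse$value, " (", round(x$coarse$percent, 1), "%)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

gauss_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(mu), function(k) w[k] * dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

fit_mixture <- function(x, G, variance_floor, max_iter = 500, tol = 1e-9) {
  n <- length(x)
  if (G == 1) {
    mu <- mean(x)
    v <- max(sum((x - mu)^2) / n, variance_floor)
    ll <- gauss_loglik(x, 1, mu, sqrt(v))
    return(list(G = 1, weight = 1, mean = mu, sd = sqrt(v), loglik = ll,
                bic = -2 * ll + 2 * log(n)))
  }
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(qs) < 1e-6) qs <- qs + c(-0.25, 0.25)
  mu <- qs; v <- rep(max(stats::var(x) / 4, variance_floor), 2)
  w <- c(0.5, 0.5); ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(v[2]))
    tot <- pmax(d1 + d2, 1e-300)
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    if (w[1] < 1e-9 || w[2] < 1e-9) break
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    v <- c(sum(r * (x - mu[1])^2) / sum(r),
           sum((1 - r) * (x - mu[2])^2) / sum(1 - r))
    v <- pmax(v, variance_floor)
    ll <- gauss_loglik(x, w, mu, sqrt(v))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ll <- gauss_loglik(x, w, mu, sqrt(v))
  list(G = 2, weight = w, mean = mu, sd = sqrt(v), loglik = ll,
       bic = -2 * ll + 5 * log(n))
}

#' Classify a homopolymer flowgram histogram
#'
#' Fits one- and two-component Gaussian mixtures to the flow signals (EM,
#' variance floor), selects by BIC, and maps the fit to a biological label:
#' \itemize{
#'   \item two well-separated components (mode separation at least
#'     `min_separation` flow units, minor weight at least `min_fraction`,
#'     each mean within `max_center_offset` of a distinct integer run
#'     length) mean some reads carry `n` bases and the rest `n + 1` or
#'     `n - 1`: a heterozygous indel. Without integer-centred components a
#'     two-component preference is treated as a single population (a wide
#'     artefact blob split in half by the EM is not two alleles);
#'   \item a single component centred (within `max_center_offset`) on `n` is
#'     wild type; centred on `n + 1` or `n - 1` it is a homozygous indel;
#'   \item a single component strictly between integers is the signature of
#'     poor quantitation of a strong homopolymer signal: an artefact;
#'   \item anything else is ambiguous and flagged for manual review.
#' }
#'
#' @param hist A [build_histogram()] object.
#' @param config An [hp_config()] supplying thresholds.
#' @param min_fraction Minimum minor-component weight (default 0.2, the
#'   variant-fraction threshold).
#' @param min_reads Minimum informative reads required (default 4).
#' @return Object of class `hp_classification`: `label`, `modes`, `evidence`
#'   (BIC difference in favour of the chosen model), `fit` (chosen mixture),
#'   `fits` (both), `n`.
#' @export
classify_histogram <- function(hist, config = hp_config(),
                               min_fraction = 0.2, min_reads = 4L) {
  x <- hist$signals
  if (length(x) < min_reads)
    stop("too few informative reads (", length(x), " < ", min_reads, ")")
  f1 <- fit_mixture(x, 1, config$variance_floor)
  f2 <- fit_mixture(x, 2, config$variance_floor)
  two <- f2$bic < f1$bic
  fit <- if (two) f2 else f1
  evidence <- abs(f1$bic - f2$bic)
  n <- hist$n
  off <- config$max_center_offset
  label <- "ambiguous"
  het_ok <- FALSE
  if (two) {
    sep <- abs(diff(f2$mean))
    ints <- round(f2$mean)
    # two real populations sit near two distinct integer run lengths;
    # a wide single blob split in half by the EM does not
    het_ok <- sep >= config$min_separation &&
      min(f2$weight) >= min_fraction &&
      all(abs(f2$mean - ints) <= off) && ints[1] != ints[2]
  }
  if (het_ok) {
    label <- "heterozygous_indel"
  } else {
    fit <- f1
    m <- f1$mean
    if (abs(m - n) <= off) label <- "wild_type"
    else if (abs(m - (n + 1)) <= off || abs(m - (n - 1)) <= off)
      label <- "homozygous_indel"
    else if ((m > n - 1 + off && m < n - off) ||
             (m > n + off && m < n + 1 - off))
      label <- "artefact"
  }
  structure(list(label = label, modes = fit$mean, evidence = evidence,
                 fit = fit, fits = list(one = f1, two = f2), n = n,
                 n_reads = length(x)),
            class = "hp_classification")
}

#' @export
print.hp_classification <- function(x, ...) {
  cat("<hp_classification> ", x$label, " (modes ",
      paste(round(x$modes, 2), collapse = ", "), "; dBIC ",
      round(x$evidence, 1), "; ", x$n_reads, " reads)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a homopolymer classification
#'
#' One row per mixture component of the selected fit: mean, standard
#' deviation and weight.
#'
#' @param x An `hp_classification`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.hp_classification <- function(x, ...) {
  tibble::tibble(component = seq_along(x$fit$mean),
                 mean = x$fit$mean,
                 sd = x$fit$sd,
                 weight = x$fit$weight)
}

#' One-row summary of a homopolymer classification
#' @param x An `hp_classification`.
#' @param ... Unused.
#' @return A tibble with label, components, BIC evidence and read count.
#' @exportS3Method generics::glance
glance.hp_classification <- function(x, ...) {
  tibble::tibble(label = x$label, n_components = x$fit$G,
                 run_length = x$n, evidence = x$evidence,
                 n_reads = x$n_reads)
}

#' Plot a flowgram histogram
#'
#' Reproduces the dual-resolution homopolymer diagnostic plot: red bars show
#' the number of reads per 0.1 signal interval (the raw flowgram
#' distribution), blue bars the percentage of reads per integer interval
#' (what an integer-rounding base caller reports), on a secondary axis.
#'
#' @param object A `flow_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.flow_histogram <- function(object, ...) {
  scale <- max(object$fine$count) / 100
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = object$coarse,
      ggplot2::aes(x = .data$value, y = .data$percent * scale),
      width = 1, fill = "steelblue", alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_col(
      data = object$fine,
      ggplot2::aes(x = .data$bin_start + 0.05, y = .data$count),
      width = 0.1, fill = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "reads per 0.1 signal interval",
      sec.axis = ggplot2::sec_axis(~ . / scale,
                                   name = "% of reads per integer interval")
    ) +
    ggplot2::labs(x = "flow signal intensity",
                  title = paste0("Homopolymer flowgram (wild-type run = ",
                                 object$n, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render a histogram image with its data sidecar
#'
#' Writes the dual-resolution histogram as an image (JPEG or PNG, by file
#' extension) plus a JSON sidecar holding the signals, bin data and, when
#' supplied, the classification label — so downstream checks and re-reviews
#' never have to parse pixels.
#'
#' @param hist A `flow_histogram`.
#' @param site One-row homopolymer site tibble (from [detect_context()]).
#' @param out_path Image path ending in `.png`, `.jpeg` or `.jpg`.
#' @param classification Optional `hp_classification`.
#' @return `out_path`, invisibly; the sidecar is `out_path` + `.json`.
#' @export
render_histogram <- function(hist, site, out_path, classification = NULL) {
  ext <- tolower(tools::file_ext(out_path))
  if (!ext %in% c("png", "jpeg", "jpg"))
    stop("out_path must end in .png, .jpeg or .jpg")
  p <- autoplot(hist)
  ggplot2::ggsave(out_path, p, width = 6, height = 4, dpi = 120)
  sidecar <- list(
    run_base = site$run_base[[1]],
    run_start = site$run_start[[1]],
    run_end = site$run_end[[1]],
    n = hist$n,
    signals = hist$signals,
    fine = as.list(hist$fine),
    coarse = as.list(hist$coarse),
    label = if (is.null(classification)) NA_character_
            else classification$label
  )
  jsonlite::write_json(sidecar, paste0(out_path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_path)
}

#' Read a histogram sidecar
#' @param path Path to a `.json` sidecar written by [render_histogram()].
#' @return A list with the sidecar fields; `hist` is rebuilt as a
#'   `flow_histogram`.
#' @export
read_histogram_sidecar <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$hist <- build_histogram(d$signals, d$n)
  d
}
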
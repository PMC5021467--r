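#' Seeded recovery study for the homopolymer classifier
#'
#' Draws flow-signal sets directly from the simulator's generative noise
#' model over a grid of run lengths, depths, noise levels and allele
#' fractions, classifies each set, and tabulates truth against label.
#' Truth per cell: fraction 0 is `wild_type`, 0 < fraction < 1 is
#' `heterozygous_indel` (populations at `n` and `n - 1`), fraction 1 is
#' `homozygous_indel`; artefact cells draw a single population centred on
#' `n - 0.5` with `artefact_sigma`.
#'
#' @param seed Integer seed.
#' @param n_range Wild-type run lengths (default 4:9).
#' @param depths Reads per set (default c(40, 100, 200)).
#' @param sigmas Per-population standard deviations (default c(0.1, 0.2)).
#' @param fractions Deleted-allele fractions (default c(0, 0.5, 1)).
#' @param artefact_sigma Artefact spread (default 0.35).
#' @param replicates Sets per grid cell (default 3).
#' @param config An [hp_config()] (classification thresholds; mode ignored).
#' @return A tibble with one row per classified set: `n`, `depth`, `sigma`,
#'   `fraction`, `truth`, `label`, `replicate`.
#' @export
classifier_recovery <- function(seed = 1, n_range = 4:9,
                                depths = c(40, 100, 200),
                                sigmas = c(0.1, 0.2),
                                fractions = c(0, 0.5, 1),
                                artefact_sigma = 0.35,
                                replicates = 3,
                                config = hp_config(mode = "auto")) {
  set.seed(seed)
  rows <- list()
  for (n in n_range) {
    for (depth in depths) {
      for (sigma in sigmas) {
        cells <- c(as.list(fractions), list("artefact"))
        for (cell in cells) {
          for (rep in seq_len(replicates)) {
            if (identical(cell, "artefact")) {
              x <- pmax(0, rnorm(depth, n - 0.5, artefact_sigma))
              truth <- "artefact"
            } else {
              f <- cell
              ndel <- rbinom(1, depth, f)
              x <- pmax(0, c(rnorm(depth - ndel, n, sigma),
                             rnorm(ndel, n - 1, sigma)))
              truth <- if (f == 0) "wild_type"
                       else if (f == 1) "homozygous_indel"
                       else "heterozygous_indel"
            }
            label <- classify_histogram(build_histogram(x, n), config)$label
            rows[[length(rows) + 1]] <- tibble::tibble(
              n = n, depth = depth, sigma = sigma,
              fraction = if (identical(cell, "artefact")) NA_real_
                         else cell,
              truth = truth, label = label, replicate = rep)
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Confusion-matrix diagonal of a recovery study
#' @param rec Tibble from [classifier_recovery()] (optionally pre-filtered,
#'   e.g. to `depth >= 100`).
#' @return Fraction of sets whose label equals the truth.
#' @export
recovery_diagonal <- function(rec) mean(rec$label == rec$truth)
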
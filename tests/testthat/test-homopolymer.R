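mk_var <- function(kind, pos, ref = "", alt = "") {
  tibble::tibble(kind = kind, position = as.integer(pos), ref = ref,
                 alt = alt)
}

test_that("homopolymer context detection follows the run definition", {
  ref <- "CAAAAAAAG"                        # 7 A's
  site <- detect_context(mk_var("del", 1, ref = "A"), ref, 3)
  expect_equal(site$run_base, "A")
  expect_equal(site$n, 7L)
  expect_equal(c(site$run_start, site$run_end), c(1L, 8L))
  # a lone T is no homopolymer
  expect_null(detect_context(mk_var("del", 2, ref = "T"), "CGTAG", 3))
  # substitutions never have homopolymer context
  expect_null(detect_context(mk_var("sub", 3, ref = "A", alt = "G"), ref, 3))
  # insertion adjacent to a run
  site2 <- detect_context(mk_var("ins", 8, alt = "A"), ref, 3)
  expect_equal(site2$n, 7L)
  # non-repeat insertion inside a run context
  expect_null(detect_context(mk_var("ins", 4, alt = "AG"), ref, 3))
})

test_that("context detection agrees with a brute-force run scanner", {
  set.seed(51)
  for (k in 1:40) {
    ref <- paste(sample(c("A", "C", "G", "T"), 40, TRUE,
                        prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
    chars <- strsplit(ref, "")[[1]]
    for (p in 0:39) {
      v <- mk_var("del", p, ref = chars[p + 1])
      got <- detect_context(v, ref, 3)
      want <- oracle_hp_context(ref, "del", p, chars[p + 1], 3)
      if (is.null(want)) expect_null(got)
      else {
        expect_equal(got$run_start, want$run_start)
        expect_equal(got$n, want$n)
      }
    }
    for (p in 0:40) {
      b <- sample(c("A", "C", "G", "T"), 1)
      got <- detect_context(mk_var("ins", p, alt = b), ref, 3)
      want <- oracle_hp_context(ref, "ins", p, b, 3)
      if (is.null(want)) expect_null(got)
      else expect_equal(got$n, want$n)
    }
  }
})

hp_setup <- function(templates, strands = NULL, noise = noise_model(1e-12, 0, 1),
                     seed_base = 1000) {
  sc <- make_hp_scenario()
  n <- length(templates)
  if (is.null(strands)) strands <- rep("+", n)
  fo <- strrep("TACG", 80)
  reads <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tpl <- if (strands[i] == "+") templates[i] else revcomp(templates[i])
    simulate_read(tpl, fo, noise, seed = seed_base + i,
                  name = sprintf("r%03d", i))
  }))
  reads <- clip_reads(reads)
  aln <- align_reads(reads, sc$amplicons)
  list(sc = sc, reads = reads, aln = aln, flow_order = fo)
}

test_that("a zero-noise read over the 7-A run yields signal 7.00", {
  s <- hp_setup(make_hp_scenario()$amp_seq)
  site <- tibble::tibble(run_base = "A", run_start = s$sc$run_start,
                         run_end = s$sc$run_end, n = 7L)
  sig <- extract_signals(site, s$aln, s$reads, s$flow_order)
  expect_equal(sig$signals, 7)
  expect_equal(sig$excluded, 0L)
})

test_that("an even zero-noise mix of wild-type and deleted reads gives
          exactly five 6.00 and five 7.00 signals, on both strands", {
  sc <- make_hp_scenario()
  wt <- sc$amp_seq
  del <- paste0(substr(wt, 1, sc$run_start), substr(wt, sc$run_start + 2,
                                                    nchar(wt)))
  s <- hp_setup(c(rep(wt, 5), rep(del, 5)),
                strands = rep(c("+", "-"), 5))
  site <- tibble::tibble(run_base = "A", run_start = sc$run_start,
                         run_end = sc$run_end, n = 7L)
  sig <- extract_signals(site, s$aln, s$reads, s$flow_order)
  expect_equal(sort(sig$signals), c(rep(6, 5), rep(7, 5)))
})

test_that("reads with the run entirely deleted still contribute a signal", {
  sc <- make_hp_scenario()
  wt <- sc$amp_seq
  # remove all seven A's
  allgone <- paste0(substr(wt, 1, sc$run_start),
                    substr(wt, sc$run_end + 1, nchar(wt)))
  s <- hp_setup(c(wt, allgone, allgone), strands = c("+", "+", "-"))
  site <- tibble::tibble(run_base = "A", run_start = sc$run_start,
                         run_end = sc$run_end, n = 7L)
  sig <- extract_signals(site, s$aln, s$reads, s$flow_order)
  expect_equal(sort(sig$signals), c(0, 0, 7))
})

test_that("noisy signal extraction equals per-read re-derivation", {
  sc <- make_hp_scenario()
  s <- hp_setup(rep(sc$amp_seq, 30), strands = rep(c("+", "-"), 15),
                noise = noise_model(0.1, 0.01, 0.35))
  site <- tibble::tibble(run_base = "A", run_start = sc$run_start,
                         run_end = sc$run_end, n = 7L)
  sig <- extract_signals(site, s$aln, s$reads, s$flow_order)
  # oracle: for each read find its own A (or T) run flow via flow_index of
  # a base aligned inside the run
  expect_equal(length(sig$signals) + sig$excluded, 30)
  for (i in seq_along(sig$names)) {
    r <- s$reads[s$reads$name == sig$names[i], ]
    a <- s$aln[s$aln$name == sig$names[i], ]
    # locate the run in the oriented read via the alignment strings
    stopifnot(a$aligned)
    expect_true(sig$signals[i] %in% (r$flow_values[[1]] / 100))
  }
})

test_that("histogram bins conserve mass and follow the dual resolution", {
  h <- build_histogram(c(6.95, 7.04), 7)
  expect_equal(h$coarse$value, 7L)
  expect_equal(h$coarse$percent, 100)
  expect_equal(sum(h$fine$count), 2)
  h2 <- build_histogram(c(rep(6, 5), rep(7, 5)), 7)
  expect_equal(h2$coarse$value, c(6L, 7L))
  expect_equal(h2$coarse$percent, c(50, 50))
  expect_equal(h2$fine$count[h2$fine$bin_start == 6.0], 5L)
  expect_equal(h2$fine$count[h2$fine$bin_start == 7.0], 5L)
  expect_error(build_histogram(numeric(0), 7), "empty")
  # random signals: totals equal a brute-force recount
  set.seed(61)
  for (k in 1:20) {
    x <- runif(50, 3, 9)
    h3 <- build_histogram(x, 6)
    expect_equal(sum(h3$fine$count), 50)
    expect_equal(sum(h3$coarse$count), 50)
    expect_equal(sum(h3$coarse$percent), 100, tolerance = 1e-9)
    for (j in seq_len(nrow(h3$fine)))
      expect_equal(h3$fine$count[j],
                   sum(x >= h3$fine$bin_start[j] - 1e-9 &
                         x < h3$fine$bin_start[j] + 0.1 - 1e-9))
  }
})

test_that("classifier separates het, hom, wild type and artefact patterns", {
  cfg <- hp_config(mode = "auto")
  # tight bimodal at 6 and 7: heterozygous
  het <- classify_histogram(build_histogram(c(rep(6, 50), rep(7, 50)), 7),
                            cfg)
  expect_equal(het$label, "heterozygous_indel")
  expect_equal(sort(round(het$modes)), c(6, 7))
  # broad unimodal between the integers: artefact
  set.seed(71)
  art <- classify_histogram(
    build_histogram(pmax(0, rnorm(100, 6.5, 0.2)), 7), cfg)
  expect_equal(art$label, "artefact")
  # unimodal at n: wild type; at n-1: homozygous
  wt <- classify_histogram(build_histogram(rnorm(100, 7, 0.12), 7), cfg)
  expect_equal(wt$label, "wild_type")
  hom <- classify_histogram(build_histogram(rnorm(100, 6, 0.12), 7), cfg)
  expect_equal(hom$label, "homozygous_indel")
  # broom-style accessors
  expect_equal(nrow(tidy(het)), 2)
  expect_equal(glance(het)$label, "heterozygous_indel")
  expect_equal(glance(wt)$n_components, 1)
})

test_that("seeded replicates of a clean heterozygous mixture are recovered
          in at least 95% of cases", {
  cfg <- hp_config(mode = "auto")
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- c(rnorm(100, 6, 0.15), rnorm(100, 7, 0.15))
    classify_histogram(build_histogram(x, 7), cfg)$label ==
      "heterozygous_indel"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("classifier agrees with an independent mixture fitter on a
          well-separated case", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(81)
  x <- c(rnorm(120, 6, 0.15), rnorm(80, 7, 0.15))
  ours <- classify_histogram(build_histogram(x, 7), hp_config(mode = "auto"))
  mc <- Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  expect_equal(mc$G, 2)
  expect_equal(sort(ours$fit$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("rising noise at fraction 0 never manufactures a heterozygote", {
  cfg <- hp_config(mode = "auto")
  labels <- character(0)
  for (sigma in c(0.1, 0.2, 0.3, 0.4)) {
    set.seed(round(sigma * 1000))
    x <- pmax(0, rnorm(150, 7, sigma))
    cl <- classify_histogram(build_histogram(x, 7), cfg)
    if (cl$label == "heterozygous_indel")
      expect_gte(abs(diff(cl$fit$mean)), 0.5)
    labels <- c(labels, cl$label)
  }
  expect_equal(labels[1], "wild_type")
})

test_that("histograms render to an image with a faithful data sidecar", {
  sc <- make_hp_scenario()
  h <- build_histogram(c(rep(6, 30), rep(7, 34)), 7)
  site <- tibble::tibble(run_base = "A", run_start = sc$run_start,
                         run_end = sc$run_end, n = 7L)
  cls <- classify_histogram(h, hp_config(mode = "auto"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "site.png")
  render_histogram(h, site, path, classification = cls)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
  side <- read_histogram_sidecar(paste0(path, ".json"))
  expect_equal(side$signals, h$signals)
  expect_equal(side$label, "heterozygous_indel")
  expect_equal(side$hist$coarse$percent, h$coarse$percent)
  # the two populations are visible in the sidecar's fine bins
  expect_true(all(c(6.0, 7.0) %in% side$hist$fine$bin_start))
  expect_error(render_histogram(h, site, file.path(dir, "x.txt")),
               "png|jpeg")
})

test_that("a batch of sites renders deterministically named files", {
  sc <- make_hp_scenario()
  dir <- withr::local_tempdir()
  site <- tibble::tibble(run_base = "A", run_start = sc$run_start,
                         run_end = sc$run_end, n = 7L)
  for (i in 1:5) {
    h <- build_histogram(rep(7, 10 + i), 7)
    render_histogram(h, site, file.path(dir, sprintf("s%02d.png", i)))
  }
  expect_equal(sort(list.files(dir, pattern = "png$")),
               sprintf("s%02d.png", 1:5))
  expect_length(list.files(dir, pattern = "json$"), 5)
})
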
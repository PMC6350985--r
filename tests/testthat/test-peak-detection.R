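test_that("normalisation scales to counts per million and obeys the scaling law", {
  tr <- CoverageTrack(list(c1 = c(0, 5, 5, 0)), library_size = 1e6)
  expect_equal(as.numeric(normalize_coverage(tr)$cov$c1), c(0, 5, 5, 0))

  tr2 <- CoverageTrack(list(c1 = c(0, 5, 5, 0)), library_size = 2e6)
  expect_equal(as.numeric(normalize_coverage(tr2)$cov$c1), c(0, 2.5, 2.5, 0))

  zero <- CoverageTrack(list(c1 = numeric(10)), library_size = 5e5)
  expect_true(all(as.numeric(normalize_coverage(zero)$cov$c1) == 0))

  # output(k * reads at k * library) == output(reads at library)
  a <- CoverageTrack(list(c1 = c(1, 2, 3)), library_size = 1e5)
  b <- CoverageTrack(list(c1 = 3 * c(1, 2, 3)), library_size = 3e5)
  expect_equal(as.numeric(normalize_coverage(a)$cov$c1),
               as.numeric(normalize_coverage(b)$cov$c1))

  expect_error(CoverageTrack(list(c1 = 1:3), library_size = 0), "positive")
})

test_that("control subtraction floors at zero and preserves identities", {
  tf <- CoverageTrack(list(c1 = c(10, 3, 7, 0)), 1e6)
  ig <- CoverageTrack(list(c1 = c(4, 7, 0, 2)), 1e6)
  out <- subtract_control(tf, ig)
  expect_equal(as.numeric(out$cov$c1), c(6, 0, 7, 0))

  zero_ctrl <- CoverageTrack(list(c1 = numeric(4)), 1e6)
  expect_equal(as.numeric(subtract_control(tf, zero_ctrl)$cov$c1),
               as.numeric(tf$cov$c1))

  other <- CoverageTrack(list(c2 = c(1, 1)), 1e6)
  expect_error(subtract_control(tf, other), "different chromosomes")

  # result bounded by [0, tf] on random tracks
  set.seed(1)
  for (i in 1:10) {
    x <- CoverageTrack(list(c1 = rpois(500, 2)), 1e6)
    y <- CoverageTrack(list(c1 = rpois(500, 2)), 1e6)
    s <- as.numeric(subtract_control(x, y)$cov$c1)
    expect_true(all(s >= 0) && all(s <= as.numeric(x$cov$c1)))
  }
})

test_that("enrichment-region detection merges by bandwidth and finds summits", {
  g <- generate_genome(c(chrS = 20000L), 0.41, seed = 2)
  one <- simulate_chip_coverage(g, data.frame(chrom = "chrS", center = 5000,
                                              intensity = 30),
                                frag_len = 250, noise_rate = 0, seed = 1)
  pk <- detect_enriched_regions(one, bandwidth = 250, background = 0)
  expect_length(pk, 1)
  expect_lte(abs(S4Vectors::mcols(pk)$summit - 5000), 13)
  expect_equal(S4Vectors::mcols(pk)$intensity, 30)

  # two bumps 100 bp apart merge; 1000 bp apart stay separate
  close2 <- simulate_chip_coverage(g, data.frame(chrom = "chrS",
                                                 center = c(5000, 5100),
                                                 intensity = c(30, 30)),
                                   frag_len = 250, noise_rate = 0, seed = 1)
  expect_length(detect_enriched_regions(close2, 250, 0), 1)

  far2 <- simulate_chip_coverage(g, data.frame(chrom = "chrS",
                                               center = c(5000, 6000),
                                               intensity = c(30, 30)),
                                 frag_len = 250, noise_rate = 0, seed = 1)
  pk2 <- detect_enriched_regions(far2, 250, 0)
  expect_length(pk2, 2)

  # brute-force run scan oracle on the same track
  v <- as.numeric(far2$cov$chrS)
  runs <- rle(v > 0)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  pos_runs <- cbind(starts[runs$values], ends[runs$values])
  # merge runs with gap < 250
  merged <- pos_runs[1, , drop = FALSE]
  for (i in seq_len(nrow(pos_runs))[-1]) {
    if (pos_runs[i, 1] - merged[nrow(merged), 2] - 1 < 250)
      merged[nrow(merged), 2] <- pos_runs[i, 2]
    else merged <- rbind(merged, pos_runs[i, ])
  }
  merged <- merged[merged[, 2] - merged[, 1] + 1 >= 50, , drop = FALSE]
  expect_equal(GenomicRanges::start(pk2), merged[, 1])
  expect_equal(GenomicRanges::end(pk2), merged[, 2])
})

test_that("detected regions are sorted and separated by at least the bandwidth", {
  g <- generate_genome(c(chrS = 50000L), 0.41, seed = 5)
  set.seed(5)
  centers <- seq(1000, 49000, by = 1500)
  tr <- simulate_chip_coverage(g, data.frame(chrom = "chrS", center = centers,
                                             intensity = runif(length(centers), 10, 40)),
                               frag_len = 250, noise_rate = 0.2, seed = 6)
  pk <- detect_enriched_regions(tr, 250, background = 2)
  st <- GenomicRanges::start(pk); en <- GenomicRanges::end(pk)
  expect_true(!is.unsorted(st))
  if (length(pk) > 1)
    expect_true(all(st[-1] - en[-length(en)] - 1 >= 250))
})

test_that("intensity filter applies the mean-plus-one-SD rule", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1:5 * 1000, width = 100),
                               intensity = c(1, 1, 1, 1, 10))
  out <- intensity_filter(gr)
  expect_length(out$kept, 1)
  expect_equal(S4Vectors::mcols(out$kept)$intensity, 10)
  expect_equal(out$mean, 2.8)

  flat <- GenomicRanges::GRanges("c1", IRanges::IRanges(1:4 * 1000, width = 100),
                                 intensity = rep(7, 4))
  expect_length(intensity_filter(flat)$kept, 0)

  single <- gr[1]
  expect_error(intensity_filter(single), "at least 2")
})

test_that("normal intensities leave the expected upper-tail fraction", {
  set.seed(20)
  n <- 10000
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq_len(n) * 10, width = 5),
                               intensity = rnorm(n, 206.8, 120.6))
  kept <- length(intensity_filter(gr)$kept) / n
  expect_lt(abs(kept - (1 - pnorm(1))), 0.01)
})

test_that("three-criteria selection equals the brute-force union of criteria", {
  # hand-built cases for each single criterion
  peaks <- GenomicRanges::GRanges("c1",
                                  IRanges::IRanges(c(1000, 5000, 9000, 13000),
                                                   width = 100),
                                  intensity = c(5, 5, 5, 100),
                                  summit = c(1050L, 5050L, 9050L, 13050L))
  conserved <- GenomicRanges::GRanges("c1", IRanges::IRanges(5020, 5040))
  other <- GenomicRanges::GRanges("c1", IRanges::IRanges(1300, 1400))  # 200 bp gap
  sel <- select_peaks(peaks, conserved, other, distance = 250)
  rs <- stats::setNames(S4Vectors::mcols(sel)$selection_reasons,
                        GenomicRanges::start(sel))
  expect_true("c" == rs[["1000"]])   # proximity only
  expect_true("b" == rs[["5000"]])   # conservation only, below-mean intensity
  expect_true("a" == rs[["13000"]])  # intensity only
  expect_false("9000" %in% names(rs))

  # random instances against a brute-force (a | b | c) evaluation
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    pk <- random_regions(n)
    S4Vectors::mcols(pk)$intensity <- rexp(n, 1 / 50)
    cons <- random_regions(sample(5:50, 1))
    oth <- random_regions(sample(5:100, 1))
    sel <- select_peaks(pk, cons, oth, distance = 250)
    m <- mean(S4Vectors::mcols(pk)$intensity)
    s <- sd(S4Vectors::mcols(pk)$intensity)
    truth <- (S4Vectors::mcols(pk)$intensity > m + s) |
      oracle_within(pk, cons, 0) | oracle_within(pk, oth, 250)
    expect_identical(GenomicRanges::start(sel), GenomicRanges::start(pk)[truth])
    # selected set: superset of intensity filter, subset of input
    expect_true(all(GenomicRanges::start(intensity_filter(pk)$kept) %in%
                    GenomicRanges::start(sel)))
    expect_lte(length(sel), length(pk))
  }
})

test_that("planted peaks at high SNR are recovered with accurate summits", {
  g <- generate_genome(c(chrS = 50000L), 0.41, seed = 8)
  set.seed(8)
  centers <- sample(seq(800, 49200, by = 1200), 25)
  truth <- data.frame(chrom = "chrS", center = centers,
                      intensity = runif(25, 10, 60))
  tr <- simulate_chip_coverage(g, truth, library_size = 1e6, frag_len = 250,
                               noise_rate = 0.5, seed = 9)
  igg <- simulate_chip_coverage(g, truth[0, ], library_size = 1e6,
                                noise_rate = 0.5, seed = 10)
  sub <- subtract_control(normalize_coverage(tr), normalize_coverage(igg))
  pk <- detect_enriched_regions(sub, 250, background = 2)
  err <- vapply(truth$center, function(ct)
    min(abs(S4Vectors::mcols(pk)$summit - ct)), numeric(1))
  expect_gte(mean(err <= 50), 0.9)
})
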
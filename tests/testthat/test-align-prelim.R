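test_that("reference selection favours the consensus sample", {
  # three identical chromatograms: lowest index wins the tie
  m <- matrix(rep(gauss_signal(200, c(50, 150), c(10, 20), c(5, 5)), 3),
              nrow = 3, byrow = TRUE)
  expect_identical(as.integer(select_reference(m)), 1L)

  # one unshifted sample among four shifted copies wins (broad peaks so
  # the correlation decays smoothly with displacement)
  set.seed(31)
  h <- runif(9, 20, 100)
  shifts <- c(0, -15, 15, -8, 8)
  m <- t(vapply(shifts, function(s)
    gauss_signal(1000, seq(100, 900, by = 100) + s, h, rep(20, 9)),
    numeric(1000)))
  expect_identical(as.integer(select_reference(m)), 1L)
  base <- m[1, ]

  # a noise-only sample is never selected
  for (seed in 1:20) {
    set.seed(seed)
    mm <- rbind(base + rnorm(1000, 0, 1),
                base + rnorm(1000, 0, 1),
                rnorm(1000),
                base + rnorm(1000, 0, 1))
    expect_false(select_reference(mm) == 3L)
  }
  expect_error(select_reference(matrix(1:10, 1)), "2 samples")
})

test_that("pearson matches the two-pass textbook formula and handles degeneracy", {
  set.seed(37)
  r <- rnorm(100); x <- rnorm(100)
  expect_equal(as.numeric(pearson(r, x)), cor(r, x), tolerance = 1e-12)
  expect_equal(as.numeric(pearson(r, r)), 1)
  expect_equal(as.numeric(pearson(r, -r + 5)), -1)
  cc <- pearson(r, rep(1, 100))
  expect_identical(as.numeric(cc), 0)
  expect_true(attr(cc, "constant"))
  expect_error(pearson(r, x[-1]), "mismatch")
})

test_that("segments follow the 3-min rule and undersized segments merge", {
  p <- peak_tab(c(100, 200, 250, 600, 650, 700), rep(10, 6), rep(4, 6))
  seg <- partition_segments(p, 3.0)
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$n_peaks, c(3L, 3L))

  # a middle 2-peak group merges into the right neighbour (fewer peaks)
  p2 <- peak_tab(c(seq(100, 260, by = 40),          # 5 peaks, first 3-min bin
                   400, 430,                        # 2-peak group
                   seq(720, 840, by = 40)),         # 4 peaks
                 rep(10, 11), rep(4, 11))
  # force grouping with a 1.2-min rule so groups are {5}, {2}, {4}
  seg2 <- partition_segments(p2, 1.8)
  expect_identical(nrow(seg2), 2L)
  expect_identical(seg2$n_peaks, c(5L, 6L))  # the pair went right

  # boundaries tile: interior junction shared
  expect_identical(seg$ref_end[1], seg$ref_start[2])
  expect_warning(partition_segments(peak_tab(c(10, 30), c(5, 5), c(2, 2))),
                 "single segment")
})

test_that("full study-scale partition leaves every segment with >= 3 peaks, tiling", {
  sim <- small_sim()
  x <- correct_baseline(sim$dataset$chromatograms[[1]])$corrected
  pk <- detect_peaks(x)
  seg <- partition_segments(pk, 3.0, axis_len = length(x$intensities))
  expect_true(all(seg$n_peaks >= 3L))
  expect_identical(seg$ref_start[1], 0L)
  expect_identical(seg$ref_end[nrow(seg)], length(x$intensities) - 1L)
  if (nrow(seg) > 1)
    expect_identical(seg$ref_end[-nrow(seg)], seg$ref_start[-1])
  # smaller init size -> at least as many segments
  seg1 <- partition_segments(pk, 1.0)
  expect_gte(nrow(seg1), nrow(seg))
})

test_that("test window widens the reference segment by twice the estimate", {
  seg <- list(ref_start = 636L, ref_end = 958L)  # 6.36 and 9.58 min at 0.01
  w <- test_window(seg, 0.5, sampling_interval = 0.01, axis_len = 23000L)
  expect_identical(w, c(586L, 1008L))        # 5.86 and 10.08 min
  expect_equal((diff(w) - (seg$ref_end - seg$ref_start)) * 0.01, 1.0)
  expect_error(test_window(seg, 0, 0.01, 23000L), "> 0")
  # tiny estimate degenerates to the reference window
  w0 <- test_window(seg, 1e-9, 0.01, 23000L)
  expect_identical(w0, c(636L, 958L))
  # clipping at the axis start
  w2 <- test_window(list(ref_start = 10L, ref_end = 300L), 0.5, 0.01, 23000L)
  expect_identical(w2[1], 0L)
})

test_that("TPC is 1 for a perfect copy and penalises unmatched peaks", {
  y <- gauss_signal(500, c(100, 220, 350), c(40, 80, 30), c(6, 6, 6))
  pk <- peak_tab(c(100, 220, 350), c(40, 80, 30), c(6, 6, 6))
  out <- tpc(y, pk, y, pk, 0L)
  expect_equal(out$tpc, 1.0, tolerance = 1e-12)
  expect_identical(out$matched, 3L)
  # no matches -> TPC = -1
  far <- tpc(y, pk, y, pk[0, ], 0L)
  expect_identical(far$tpc, -1)
  # one unmatched of three: factor I/N = 2/3 applies
  pk2 <- pk[1:2, ]
  out2 <- tpc(y, pk, y, pk2, 0L)
  expect_equal(out2$tpc, 2 / 3, tolerance = 1e-12)
  expect_equal(out2$per_peak$c[3], -1)  # diagnostic -1 for the unmatched peak
})

test_that("TPC peaks at the true shift (exhaustive enumeration oracle)", {
  for (seed in c(41, 43, 47)) {
    set.seed(seed)
    n <- 900
    centers <- sort(sample(seq(150, 700, by = 10), 5))
    centers <- centers[c(TRUE, diff(centers) > 50)]
    while (length(centers) < 5) {
      cand <- sample(seq(150, 700, by = 10), 1)
      if (all(abs(cand - centers) > 50)) centers <- sort(c(centers, cand))
    }
    h <- runif(5, 20, 120); sg <- runif(5, 4, 7)
    true_s <- sample(-40:40, 1)
    ref <- gauss_signal(n, centers, h, sg)
    test <- gauss_signal(n, centers + true_s, h, sg)
    rp <- peak_tab(centers, h, sg)
    tp <- peak_tab(centers + true_s, h, sg)
    scores <- vapply(-60:60, function(s) tpc(ref, rp, test, tp, s)$tpc,
                     numeric(1))
    # the true shift attains the global maximum over every integer shift
    expect_gte(scores[true_s + 61], max(scores) - 1e-12)
    # and the candidate search with its tie-break recovers it exactly
    seg <- list(ref_start = min(centers) - 60L, ref_end = max(centers) + 60L)
    win <- c(max(0L, seg$ref_start - 60L), min(n - 1L, seg$ref_end + 60L))
    fit <- align_segment(ref, seg, rp, test, tp, win)
    expect_identical(fit$shift, true_s)
  }
})

test_that("candidate shifts come from the largest peak and obey the boundary", {
  n <- 1000
  seg <- list(ref_start = 200L, ref_end = 500L)
  rp <- peak_tab(c(250, 330, 450), c(10, 90, 20), c(5, 5, 5))  # P* at 330
  tpks <- peak_tab(c(150, 340, 700), c(15, 80, 30), c(5, 5, 5))
  win <- c(100L, 700L)
  inw <- tpks[tpks$apex_channel >= win[1] & tpks$apex_channel <= win[2], ]
  cand <- candidate_shifts(seg, rp, inw, win)
  # raw offsets: 150-330=-180, 340-330=10, 700-330=370
  # -180 -> ref_start+(-180) = 20 < 100: infeasible; 370 -> 870 > 700: infeasible
  expect_identical(cand, c(0L, 10L))
  # exhaustive check of the boundary rule
  all_off <- as.integer(inw$apex_channel - 330)
  excluded <- setdiff(all_off, cand)
  for (s in excluded)
    expect_true(seg$ref_start + s < win[1] || seg$ref_end + s > win[2])
  # coincident single peak, window = segment -> only the zero shift
  seg2 <- list(ref_start = 200L, ref_end = 500L)
  rp2 <- peak_tab(330, 90, 5)
  cand2 <- candidate_shifts(seg2, rp2, peak_tab(330, 85, 5), c(200L, 500L))
  expect_identical(cand2, 0L)
  expect_warning(candidate_shifts(seg2, rp2, rp2[0, ], c(200L, 500L)),
                 "falling back")
})

test_that("align_segment recovers a planted shift and prefers no shift when aligned", {
  set.seed(53)
  n <- 1200
  centers <- c(300, 420, 560, 700)
  h <- c(50, 120, 40, 80); sg <- rep(6, 4)
  ref <- gauss_signal(n, centers, h, sg)
  seg <- list(ref_start = 230L, ref_end = 780L)
  rp <- peak_tab(centers, h, sg)
  win <- c(180L, 830L)
  for (true_s in c(12L, 0L, -25L)) {
    test <- gauss_signal(n, centers + true_s, h, sg) + rnorm(n, 0, 0.3)
    tp <- peak_tab(centers + true_s, h, sg)
    fit <- align_segment(ref, seg, rp, test, tp, win)
    expect_identical(fit$shift, true_s)
  }
})

test_that("the dominant-extra-peak scenario fools Pearson but not TPC", {
  sc <- fig_dominant_peak_scenario(seed = 2)
  seg <- list(ref_start = 60L, ref_end = 560L)
  rseg <- sc$ref[(seg$ref_start:seg$ref_end) + 1]
  shifts <- 0:200
  pc <- vapply(shifts, function(s)
    as.numeric(pearson(rseg, sc$test[(seg$ref_start:seg$ref_end) + 1 + s])),
    numeric(1))
  pearson_best <- shifts[which.max(pc)]
  fit <- align_segment(sc$ref, seg, sc$ref_peaks, sc$test, sc$test_peaks,
                       sc$window)
  expect_false(pearson_best == sc$true_shift)
  expect_identical(fit$shift, sc$true_shift)
})

test_that("outlier screening reproduces the scaled-MAD rule exactly", {
  d0 <- detect_outliers(c(5, 5, 5, 5, 5))
  expect_identical(d0$sigma, 0)
  expect_false(any(d0$outlier_flags))
  expect_identical(d0$d_scores, rep(0, 5))

  s <- c(10, 11, 10, 9, 10, 60)
  d <- detect_outliers(s)
  # hand computation: median 10, sigma = 1.483 * 0.5
  expect_equal(d$sigma, 1.483 * 0.5)
  expect_equal(d$d_scores[6], 50 / (1.483 * 0.5), tolerance = 1e-12)
  expect_identical(which(d$outlier_flags), 6L)

  # d exactly at the threshold is NOT an outlier (strictly larger only)
  s2 <- c(-1, 0, 1, 0, 0, 2.5 * 1.483 * 0.5)  # sigma = 1.483 * 0.5
  d2 <- detect_outliers(s2)
  expect_equal(max(d2$d_scores), 2.5, tolerance = 1e-12)
  expect_false(any(d2$outlier_flags))

  # oracle equivalence on random vectors
  set.seed(59)
  for (i in 1:25) {
    v <- sample(-50:50, 7, replace = TRUE)
    d3 <- detect_outliers(v)
    sig <- 1.483 * median(abs(v - median(v)))
    expect_equal(d3$sigma, sig, tolerance = 1e-12)
    if (sig > 0)
      expect_equal(d3$d_scores, abs(v - median(v)) / sig, tolerance = 1e-12)
  }
})

test_that("outlier repair picks the local correlation maximum nearest the median", {
  set.seed(61)
  n <- 1500
  centers <- c(400, 520, 640)
  ref <- gauss_signal(n, centers, c(60, 90, 50), c(7, 7, 7))
  seg <- list(ref_start = 340L, ref_end = 700L)
  # two well-separated correlation maxima: a strong one at +40 and the
  # true one at +3; the local maximum nearest the expected shift wins
  test <- gauss_signal(n, centers + 3, c(60, 90, 50), c(7, 7, 7)) +
    0.9 * gauss_signal(n, centers + 40, c(60, 90, 50), c(7, 7, 7))
  got <- realign_outlier(ref, seg, test, sigma = 16, expected_shift = 0)
  expect_identical(got, 3L)
  # sigma 0 returns the expected shift unchanged
  expect_identical(realign_outlier(ref, seg, test, 0, 5L), 5L)
})

test_that("boundary resolution averages junctions and tracks the overlap rule", {
  seg <- data.frame(ref_start = c(14000L, 14833L), ref_end = c(14833L, 15600L),
                    shift = c(0L, 6L))
  j <- resolve_boundaries(seg)
  expect_identical(j$boundary, 14836L)   # (14833 + 14839) / 2
  expect_identical(j$rule, "gap")

  # zero-gap junction unchanged
  seg0 <- data.frame(ref_start = c(100L, 400L), ref_end = c(400L, 900L),
                     shift = c(5L, 5L))
  j0 <- resolve_boundaries(seg0)
  expect_identical(j0$boundary, 405L)
  expect_identical(j0$rule, "touch")

  # overlap: a peak END 1 channel from the zone middle, a START 10 away
  sego <- data.frame(ref_start = c(100L, 400L), ref_end = c(400L, 900L),
                     shift = c(10L, -10L))  # zone [390, 410], mid 400
  pks <- peak_tab(c(360, 450), c(10, 10), c(3, 3))
  pks$end_channel[1] <- 401L   # 1 from mid
  pks$start_channel[2] <- 410L # 10 from mid
  jo <- resolve_boundaries(sego, pks)
  expect_identical(jo$rule, "overlap_end")  # later segment's start modified
  expect_identical(jo$boundary, 400L)
})

test_that("warp_segment equals pointwise linear interpolation", {
  expect_identical(warp_segment(c(2, 4, 6, 8, 10), 5L), c(2, 4, 6, 8, 10))
  expect_equal(warp_segment(c(0, 1, 2, 3), 7L),
               c(0, 0.5, 1, 1.5, 2, 2.5, 3), tolerance = 1e-12)
  set.seed(67)
  for (np in c(2, 5, 17)) for (nt in c(2, 9, 40)) {
    piece <- rnorm(np)
    got <- warp_segment(piece, nt)
    xout <- seq(1, np, length.out = nt)
    oracle <- vapply(xout, function(x) {
      i <- min(max(floor(x), 1), np - 1)
      piece[i] + (piece[i + 1] - piece[i]) * (x - i)
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_identical(got[1], piece[1])
    expect_identical(got[nt], piece[np])
  }
  expect_error(warp_segment(1:5, 1L), ">= 2")
})

test_that("preliminary alignment is the identity for test = reference", {
  sim <- small_sim()
  x <- correct_baseline(sim$dataset$chromatograms[[1]])$corrected
  pk <- detect_peaks(x)
  res <- preliminary_align(x, pk, x, pk)
  expect_identical(res$segments$shift, rep(0L, nrow(res$segments)))
  expect_equal(res$chromatogram$intensities, x$intensities, tolerance = 1e-9)
  expect_identical(length(res$chromatogram$intensities), length(x$intensities))
})

test_that("preliminary alignment recovers per-segment shifts and boosts correlation", {
  # the test sample is the reference displaced segment-by-segment, so the
  # true shift is constant within every alignment segment
  recovered_ok <- 0
  for (seed in c(71, 73, 79, 83, 89)) {
    sim <- small_sim(seed)
    ref <- correct_baseline(sim$dataset$chromatograms[[1]])$corrected
    rp <- detect_peaks(ref)
    n <- length(ref$intensities)
    seg <- partition_segments(rp, 3.0, axis_len = n)
    set.seed(seed + 1000)
    s_true <- integer(nrow(seg))
    s_true[1] <- sample(-30:30, 1)
    # slow drift: adjacent segments differ by a few channels, as on a
    # real instrument where the shift accumulates over the run
    for (k in seq_len(nrow(seg))[-1])
      s_true[k] <- max(-40L, min(40L, s_true[k - 1] + sample(-3:3, 1)))
    y <- numeric(n)
    for (k in seq_len(nrow(seg))) {
      rng <- seg$ref_start[k]:seg$ref_end[k]
      src <- pmin(pmax(rng - s_true[k], 0L), n - 1L)
      y[rng + 1L] <- ref$intensities[src + 1L]
    }
    test <- ref; test$intensities <- y; test$sample_id <- "shifted"
    tp <- detect_peaks(test)
    res <- preliminary_align(ref, rp, test, tp)
    expect_true(all(abs(res$segments$shift - s_true) <= 2))
    r0 <- as.numeric(pearson(ref$intensities, test$intensities))
    r1 <- as.numeric(pearson(ref$intensities,
                             res$chromatogram$intensities))
    expect_gt(r1, r0)
    if (r1 >= 0.99) recovered_ok <- recovered_ok + 1
  }
  expect_gte(recovered_ok, 4)
})
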
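test_that("sub-segment boundaries average peak end and next peak start", {
  p <- peak_tab(c(80, 130), c(10, 10), c(4, 4))
  p$end_channel[1] <- 100L
  p$start_channel[2] <- 110L
  subs <- partition_subsegments(p, c(0L, 300L))
  expect_identical(nrow(subs), 2L)
  expect_identical(subs$end[1], 105L)
  expect_identical(subs$start[2], 105L)
  expect_identical(subs$start[1], 0L)
  expect_identical(subs$end[2], 300L)
})

test_that("sub-segments tile with strictly increasing boundaries (random tables)", {
  set.seed(97)
  for (i in 1:10) {
    centers <- sort(sample(seq(60, 1800, by = 15), 8))
    centers <- centers[c(TRUE, diff(centers) > 30)]
    p <- peak_tab(centers, runif(length(centers), 5, 50),
                  runif(length(centers), 3, 5))
    subs <- partition_subsegments(p, c(0L, 2000L))
    expect_identical(nrow(subs), length(centers))  # one per peak, connected
    expect_identical(subs$start[-1], subs$end[-nrow(subs)])
    expect_true(all(subs$end > subs$start))
  }
})

test_that("precise_shift matches the nearest in-range reference peak", {
  tp <- peak_tab(100, 50, 5)  # range [85, 115]
  rp <- peak_tab(c(98, 300), c(40, 40), c(5, 5))
  got <- precise_shift(tp[1, ], rp)
  expect_identical(got$shift, -2L)
  expect_identical(got$source, "matched")
  # no reference apex inside the elution range -> imputed
  got2 <- precise_shift(tp[1, ], peak_tab(300, 40, 5))
  expect_identical(got2$source, "imputed")
  # two in range at distances 1 and 4: nearer wins
  rp3 <- peak_tab(c(99, 104), c(40, 40), c(2, 2))
  expect_identical(precise_shift(tp[1, ], rp3)$shift, -1L)
})

test_that("shift imputation averages the matched neighbours", {
  subs <- data.frame(shift = c(-3L, NA, -1L),
                     source = c("matched", "imputed", "matched"))
  expect_identical(impute_shifts(subs)$shift[2], -2L)

  all_matched <- data.frame(shift = c(1L, 2L), source = rep("matched", 2))
  expect_identical(impute_shifts(all_matched)$shift, c(1L, 2L))

  # a run of three imputed between -4 and +2 each receives -1
  run <- data.frame(shift = c(-4L, NA, NA, NA, 2L),
                    source = c("matched", rep("imputed", 3), "matched"))
  expect_identical(impute_shifts(run)$shift[2:4], rep(-1L, 3))

  # terminal imputed copies its only neighbour
  term <- data.frame(shift = c(NA, 5L), source = c("imputed", "matched"))
  expect_identical(impute_shifts(term)$shift[1], 5L)

  none <- data.frame(shift = c(NA_integer_, NA), source = rep("imputed", 2))
  expect_warning(out <- impute_shifts(none), "all shifts set to 0")
  expect_identical(out$shift, c(0L, 0L))
})

test_that("warp_subsegment moves the apex exactly and preserves its value", {
  piece <- gauss_signal(61, 30, 10, 6)
  expect_identical(warp_subsegment(piece, 31L, 0L), piece)
  w <- warp_subsegment(piece, 31L, 3L)
  expect_identical(length(w), length(piece))
  expect_equal(w[34], piece[31], tolerance = 1e-12)  # apex value lands at +3
  expect_equal(w[1], piece[1], tolerance = 1e-12)
  expect_equal(w[61], piece[61], tolerance = 1e-12)
  # half-wise linear interpolation oracle
  set.seed(101)
  piece2 <- rnorm(41)
  s <- -4L
  w2 <- warp_subsegment(piece2, 20L, s)
  left <- approx(1:20, piece2[1:20], xout = seq(1, 20, length.out = 20 + s))$y
  right <- approx(1:22, piece2[20:41], xout = seq(1, 22, length.out = 22 - s))$y
  expect_equal(w2, c(left, right[-1]), tolerance = 1e-12)
  # excessive shift is clipped with a warning
  expect_warning(warp_subsegment(piece, 31L, 40L), "clipped")
})

test_that("precise alignment pins matched apexes to the reference apexes", {
  set.seed(103)
  n <- 3000
  centers <- seq(200, 2800, by = 200)
  h <- runif(length(centers), 30, 150); sg <- rep(5, length(centers))
  ref <- chromatogram(gauss_signal(n, centers, h, sg), 0.01, sample_id = "ref")
  rp <- detect_peaks(ref)
  # residual per-peak jitter of up to +/- 3 channels
  jit <- sample(-3:3, length(centers), replace = TRUE)
  test <- chromatogram(gauss_signal(n, centers + jit, h, sg), 0.01,
                       sample_id = "t")
  tp <- detect_peaks(test)
  res <- precise_align(test, rp, tp)
  expect_identical(length(res$chromatogram$intensities), as.integer(n))
  matched <- res$subsegments$source == "matched"
  expect_true(all(matched))
  expect_identical(sort(res$peaks$apex_channel), sort(rp$apex_channel))
  r_before <- as.numeric(pearson(ref$intensities, test$intensities))
  r_after <- as.numeric(pearson(ref$intensities, res$chromatogram$intensities))
  expect_gt(r_after, r_before)
  expect_gte(r_after, 0.99)
})

test_that("already aligned input passes through precise alignment unchanged", {
  n <- 1200
  y <- gauss_signal(n, c(300, 600, 900), c(50, 80, 40), c(6, 6, 6))
  ch <- chromatogram(y, 0.01, sample_id = "a")
  pk <- detect_peaks(ch)
  res <- precise_align(ch, pk, pk)
  expect_identical(res$subsegments$shift, rep(0L, 3))
  expect_equal(res$chromatogram$intensities, y, tolerance = 1e-9)
})

test_that("correlation improves monotonically through the two stages", {
  ok <- 0; runs <- 0
  for (seed in c(107, 109, 113)) {
    sim <- small_sim(seed)
    mats <- lapply(sim$dataset$chromatograms, function(c)
      correct_baseline(c)$corrected)
    pks <- lapply(mats, detect_peaks)
    for (s in c(2, 4)) {
      runs <- runs + 1
      prelim <- preliminary_align(mats[[1]], pks[[1]], mats[[s]], pks[[s]])
      prec <- precise_align(prelim, pks[[1]])
      r0 <- as.numeric(pearson(mats[[1]]$intensities, mats[[s]]$intensities))
      r1 <- as.numeric(pearson(mats[[1]]$intensities,
                               prelim$chromatogram$intensities))
      r2 <- as.numeric(pearson(mats[[1]]$intensities,
                               prec$chromatogram$intensities))
      if (r0 <= r1 + 1e-6 && r1 <= r2 + 5e-3) ok <- ok + 1
    }
  }
  expect_gte(ok / runs, 0.95 - 1e-9)
})
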
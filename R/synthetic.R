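# Ground-truth synthetic chromatograms. The generator emulates the data
# shape this package targets: a few dozen long GC-FID fingerprints with
# hundreds of peaks, slowly varying baseline drift, additive detector
# noise, and retention shifts that are constant over short elution
# regions but drift from region to region across a run sequence. Shift
# breakpoints are snapped to inter-peak gaps because a physical
# retention shift displaces whole peaks - it cannot tear one apart.

#' Specification of a synthetic chromatogram dataset
#'
#' Defaults mirror the scale this package is designed for: 62 samples of
#' 23,000 channels at 0.01 min/channel (230 min run), 220 peaks,
#' piecewise-constant integer-channel shifts over ~3-min regions
#' following a per-sample random walk bounded at 0.4 min, quadratic
#' baseline drift, and Gaussian noise of unit standard deviation.
#'
#' @param n_samples number of samples.
#' @param n_channels channels per chromatogram.
#' @param sampling_interval minutes per channel.
#' @param n_peaks number of peaks shared by all samples.
#' @param height_range peak-height range (log-uniform draw), intensity
#'   units; the noise floor is \code{noise_sd}, so the lower bound sets
#'   the minimum SNR.
#' @param sigma_range_min peak-width (Gaussian sigma) range, minutes. The
#'   default keeps every peak adequately sampled (>= 7 channels FWHM at
#'   the default 0.01 min/channel), as a detector run at this rate would.
#' @param tau_emg exponential tail constant for EMG peaks, minutes
#'   (0 = pure Gaussian).
#' @param frac_emg fraction of peaks given an exponential tail.
#' @param region_size_min nominal shift-region size, minutes.
#' @param shift_sd0,shift_walk_sd standard deviations (channels) of the
#'   first region's shift and of the region-to-region random-walk
#'   increments.
#' @param max_shift_min hard bound on |shift|, minutes.
#' @param zero_shift_sample index of a sample generated with zero shift
#'   everywhere (a run-sequence anchor); NA for none.
#' @param drift_amplitude peak-to-peak scale of the quadratic baseline
#'   drift, intensity units (0 disables drift).
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @return object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(n_samples = 62L, n_channels = 23000L,
                       sampling_interval = 0.01, n_peaks = 220L,
                       height_range = c(20, 2000),
                       sigma_range_min = c(0.03, 0.08),
                       tau_emg = 0.02, frac_emg = 0.3,
                       region_size_min = 3.0,
                       shift_sd0 = 15, shift_walk_sd = 3,
                       max_shift_min = 0.4,
                       zero_shift_sample = 1L,
                       drift_amplitude = 50, noise_sd = 1.0) {
  spec <- list(n_samples = as.integer(n_samples),
               n_channels = as.integer(n_channels),
               sampling_interval = sampling_interval, n_peaks = as.integer(n_peaks),
               height_range = height_range, sigma_range_min = sigma_range_min,
               tau_emg = tau_emg, frac_emg = frac_emg,
               region_size_min = region_size_min,
               shift_sd0 = shift_sd0, shift_walk_sd = shift_walk_sd,
               max_shift_min = max_shift_min,
               zero_shift_sample = zero_shift_sample,
               drift_amplitude = drift_amplitude, noise_sd = noise_sd)
  if (spec$n_samples < 1L || spec$n_channels < 100L || spec$n_peaks < 1L)
    stop_atsa("invalid synthetic spec")
  if (spec$max_shift_min > 0.5 + 1e-12)
    stop_atsa("default shift model is bounded at 0.5 min")
  class(spec) <- "synth_spec"
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec: %d samples x %d channels, %d peaks, |shift| <= %g min>\n",
              x$n_samples, x$n_channels, x$n_peaks, x$max_shift_min))
  invisible(x)
}

# Evaluate one peak (Gaussian or exponentially modified Gaussian) over a
# local window; returns list(idx, values) with idx 1-based.
eval_peak <- function(n, dt, rt, height, sigma_min, tau_min) {
  half <- ceiling((6 * sigma_min + 8 * tau_min) / dt)
  c0 <- round(rt / dt)
  idx <- max(0, c0 - half):min(n - 1, c0 + half)
  t <- idx * dt
  if (tau_min > 0) {
    # EMG via the exponential-Gaussian convolution closed form
    z <- (sigma_min^2 / tau_min - (t - rt)) / (sqrt(2) * sigma_min)
    v <- exp(sigma_min^2 / (2 * tau_min^2) - (t - rt) / tau_min) *
      0.5 * erfc_(z)
    v <- v / max(v) * height
  } else {
    v <- height * exp(-(t - rt)^2 / (2 * sigma_min^2))
  }
  list(idx = idx + 1L, values = v)
}

erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Generate a ground-truth synthetic dataset
#'
#' Each sample is the sum of the spec's peaks evaluated at shifted
#' retention times, plus per-sample polynomial drift and i.i.d. Gaussian
#' noise. Shifts are integer channels, constant within regions whose
#' breakpoints sit in inter-peak gaps.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param seed integer seed; the output is reproducible given the seed.
#' @return list with \code{dataset} (a \code{chrom_dataset}),
#'   \code{peaks} (true peak table: rt_min, height, sigma_min, tau_min,
#'   apex_channel, area_true), \code{shifts} (long data.frame: sample,
#'   region, start_min, end_min, shift_channels), \code{regions}, and
#'   \code{spec}.
#' @export
synth_generate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  n <- spec$n_channels; dt <- spec$sampling_interval
  t_max <- (n - 1) * dt
  margin <- spec$max_shift_min + 0.5
  # peak retention times with a minimal spacing so neighbouring peaks are
  # chromatographically resolved (resolution ~>= 1 at the widest widths):
  # ground-truth identity of every peak is needed for recovery scoring
  rts <- sort(stats::runif(spec$n_peaks * 3, margin, t_max - margin))
  min_gap <- max(0.2, 6 * max(spec$sigma_range_min))
  keep <- c(TRUE, diff(rts) > min_gap)
  rts <- rts[keep][seq_len(min(spec$n_peaks, sum(keep)))]
  np <- length(rts)
  heights <- exp(stats::runif(np, log(spec$height_range[1]),
                              log(spec$height_range[2])))
  sigmas <- stats::runif(np, spec$sigma_range_min[1], spec$sigma_range_min[2])
  taus <- ifelse(stats::runif(np) < spec$frac_emg, spec$tau_emg, 0)

  # shift regions: nominal breaks every region_size_min, snapped to the
  # widest inter-peak gap within +/- half a region
  nominal <- seq(spec$region_size_min, t_max - spec$region_size_min / 2,
                 by = spec$region_size_min)
  gaps_mid <- (rts[-np] + rts[-1]) / 2
  breaks <- unique(vapply(nominal, function(b)
    gaps_mid[which.min(abs(gaps_mid - b))], numeric(1)))
  region_start <- c(0, breaks)
  region_end <- c(breaks, t_max)
  nr <- length(region_start)
  peak_region <- findInterval(rts, region_start)

  max_ch <- round(spec$max_shift_min / dt)
  shift_tab <- vector("list", spec$n_samples)
  mat <- matrix(0, spec$n_samples, n)
  for (s in seq_len(spec$n_samples)) {
    if (!is.na(spec$zero_shift_sample) && s == spec$zero_shift_sample) {
      sh <- rep(0L, nr)
    } else {
      sh <- numeric(nr)
      sh[1] <- stats::rnorm(1, 0, spec$shift_sd0)
      for (r in seq_len(nr)[-1]) sh[r] <- sh[r - 1] + stats::rnorm(1, 0, spec$shift_walk_sd)
      sh <- as.integer(round_half_away(pmin(pmax(sh, -max_ch), max_ch)))
    }
    y <- numeric(n)
    for (p in seq_len(np)) {
      pk <- eval_peak(n, dt, rts[p] + sh[peak_region[p]] * dt,
                      heights[p], sigmas[p], taus[p])
      y[pk$idx] <- y[pk$idx] + pk$values
    }
    if (spec$drift_amplitude > 0) {
      a <- stats::runif(3, -1, 1)
      tt <- seq(0, 1, length.out = n)
      dr <- a[1] + a[2] * tt + a[3] * tt^2
      dr <- dr - min(dr)
      if (max(dr) > 0) dr <- dr / max(dr) * spec$drift_amplitude
      y <- y + dr
    }
    if (spec$noise_sd > 0) y <- y + stats::rnorm(n, 0, spec$noise_sd)
    mat[s, ] <- y
    shift_tab[[s]] <- data.frame(sample = s, region = seq_len(nr),
                                 start_min = region_start, end_min = region_end,
                                 shift_channels = as.integer(sh))
  }
  rownames(mat) <- sprintf("S%02d", seq_len(spec$n_samples))
  peaks <- data.frame(peak = seq_len(np), rt_min = rts, height = heights,
                      sigma_min = sigmas, tau_min = taus,
                      apex_channel = as.integer(round(rts / dt)),
                      area_true = heights * (sigmas / dt) * sqrt(2 * pi) *
                        ifelse(taus > 0, NA, 1))
  list(dataset = dataset_from_matrix(mat, dt),
       peaks = peaks,
       shifts = do.call(rbind, shift_tab),
       regions = data.frame(region = seq_len(nr), start_min = region_start,
                            end_min = region_end),
       spec = spec)
}

#' Adversarial dominant-peak segment pair
#'
#' Builds a reference/test segment pair in which the test carries one
#' dominant extra peak absent from the reference, placed so that the
#' plain-Pearson-optimal shift drags the small peaks out of register
#' while the TPC-optimal shift equals the true shift. Used to
#' demonstrate why the alignment criterion weights peaks rather than raw
#' points.
#'
#' @param seed integer seed.
#' @return list with \code{ref}, \code{test} (numeric vectors),
#'   \code{ref_peaks}, \code{test_peaks} (peak tables),
#'   \code{true_shift} (channels) and \code{window}.
#' @export
fig_dominant_peak_scenario <- function(seed = 1L) {
  set.seed(seed)
  n <- 800L
  true_shift <- sample(8:18, 1)
  rt_small <- sort(sample(seq(120L, 500L, by = 4L), 5))
  rt_small <- rt_small[c(TRUE, diff(rt_small) > 40)]
  while (length(rt_small) < 4) {
    extra <- sample(seq(120L, 500L, by = 4L), 1)
    if (all(abs(extra - rt_small) > 40)) rt_small <- sort(c(rt_small, extra))
  }
  h <- stats::runif(length(rt_small), 15, 40)
  sg <- stats::runif(length(rt_small), 3, 5)
  mk <- function(centers, heights, sigmas) {
    y <- numeric(n)
    for (i in seq_along(centers))
      y <- y + heights[i] * exp(-((0:(n - 1)) - centers[i])^2 / (2 * sigmas[i]^2))
    y
  }
  ref <- mk(rt_small, h, sg)
  # dominant extra peak in the test, offset from the largest reference
  # peak by a wrong-but-reachable shift so raw Pearson is tempted
  p_big <- rt_small[which.max(h)]
  wrong <- true_shift + 60L
  dom_pos <- p_big + wrong
  test <- mk(c(rt_small + true_shift, dom_pos), c(h, 600), c(sg, 4))
  tab <- function(centers, heights, sigmas, id) {
    o <- order(centers)
    centers <- centers[o]; heights <- heights[o]; sigmas <- sigmas[o]
    data.frame(sample_id = id, peak_id = paste0(id, "_p", seq_along(centers)),
               apex_channel = as.integer(centers), rt_min = centers,
               start_channel = as.integer(centers - round(3 * sigmas)),
               end_channel = as.integer(centers + round(3 * sigmas)),
               height = heights,
               area = heights * sigmas * sqrt(2 * pi),
               stringsAsFactors = FALSE)
  }
  list(ref = ref, test = test,
       ref_peaks = tab(rt_small, h, sg, "ref"),
       test_peaks = tab(c(rt_small + true_shift, dom_pos), c(h, 600), c(sg, 4), "test"),
       true_shift = as.integer(true_shift),
       wrong_shift = as.integer(wrong),
       window = c(0L, n - 1L))
}
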
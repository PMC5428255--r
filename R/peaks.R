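# Peak detection by multi-scale Gaussian smoothing and ridge-line
# persistence. A genuine chromatographic peak stays a local maximum as the
# smoothing scale grows, so maxima are linked across scales into ridge
# lines and short or low-SNR ridges are discarded as noise.

gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(rep(x[1], half), x, rep(x[n], half))
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Leftmost channels (0-based) of strict local-maximum runs.
local_maxima <- function(x) {
  r <- rle(x)
  m <- length(r$values)
  if (m < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-m]))
  v <- r$values
  idx <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1L
  starts[idx] - 1L
}

# Robust noise scale: MAD of first differences, scaled back to the
# per-sample standard deviation (differencing inflates sd by sqrt(2)).
noise_sd <- function(x) {
  d <- diff(x)
  mad_scaled(d) / sqrt(2)
}

#' Detect chromatographic peaks by multi-scale smoothing
#'
#' The baseline-corrected signal is smoothed with Gaussian kernels of
#' increasing width; local maxima are linked across adjacent scales into
#' ridge lines (position tolerance equal to the current sigma, one missing
#' scale tolerated). Ridges spanning at least \code{min_ridge_len} scales
#' whose apex signal-to-noise ratio reaches \code{snr_min} are reported as
#' peaks. The apex is the ridge position at its smallest scale, refined to
#' the local maximum of the raw corrected signal; elution bounds are the
#' local minima flanking the apex in the smallest-scale smoothed signal,
#' trimmed to the inter-apex valley when neighbouring peaks overlap.
#'
#' @param chrom baseline-corrected \code{chromatogram} (or numeric vector,
#'   in which case \code{sampling_interval} 1 and \code{start_time} 0 are
#'   assumed for the retention-time column).
#' @param scales increasing Gaussian sigmas, in channels.
#' @param min_ridge_len minimum number of scales a ridge must span.
#' @param snr_min minimum apex signal-to-noise ratio; the noise level is
#'   \code{1.483 * MAD(diff(signal)) / sqrt(2)}.
#' @return a peak table: \code{data.frame} with columns \code{sample_id},
#'   \code{peak_id}, \code{apex_channel}, \code{rt_min},
#'   \code{start_channel}, \code{end_channel}, \code{height}, \code{area}
#'   (channels 0-based; trapezoidal area in intensity x channel units).
#' @export
detect_peaks <- function(chrom, scales = c(1, 2, 3, 5, 8, 12, 16),
                         min_ridge_len = 3L, snr_min = 3) {
  x <- signal_of(chrom)
  sid <- if (inherits(chrom, "chromatogram")) chrom$sample_id else "sample"
  n <- length(x)
  empty <- data.frame(sample_id = character(0), peak_id = character(0),
                      apex_channel = integer(0), rt_min = numeric(0),
                      start_channel = integer(0), end_channel = integer(0),
                      height = numeric(0), area = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 5L || all(x == 0)) return(empty)
  stopifnot(!is.unsorted(scales), all(scales > 0))
  sm1 <- gauss_smooth(x, scales[1])
  maxima <- vector("list", length(scales))
  maxima[[1]] <- local_maxima(sm1)
  for (s in seq_along(scales)[-1])
    maxima[[s]] <- local_maxima(gauss_smooth(x, scales[s]))

  # ridge linking, smallest scale upward
  ridges <- data.frame(pos = maxima[[1]], pos0 = maxima[[1]],
                       len = 1L, gap = 0L, alive = TRUE)
  for (s in seq_along(scales)[-1]) {
    cand <- maxima[[s]]
    tol <- scales[s]
    claimed <- rep(FALSE, length(cand))
    live <- which(ridges$alive)
    matched <- rep(FALSE, length(live))
    if (length(cand) && length(live)) {
      # nearest candidate for each live ridge (candidates are sorted)
      near <- findInterval(ridges$pos[live], cand)
      best <- integer(length(live)); bd <- numeric(length(live))
      for (j in seq_along(live)) {
        ks <- unique(pmin(pmax(c(near[j], near[j] + 1L), 1L), length(cand)))
        dd <- abs(cand[ks] - ridges$pos[live[j]])
        w <- which.min(dd)  # tie -> lower channel (ks ascending)
        best[j] <- ks[w]; bd[j] <- dd[w]
      }
      # closest pairs claim first; each maximum extends one ridge
      for (j in order(bd, ridges$pos[live])) {
        if (bd[j] <= tol && !claimed[best[j]]) {
          claimed[best[j]] <- TRUE
          i <- live[j]
          ridges$pos[i] <- cand[best[j]]
          ridges$len[i] <- ridges$len[i] + 1L + ridges$gap[i]
          ridges$gap[i] <- 0L
          matched[j] <- TRUE
        }
      }
    }
    for (j in which(!matched)) {
      i <- live[j]
      ridges$gap[i] <- ridges$gap[i] + 1L
      if (ridges$gap[i] > 1L) ridges$alive[i] <- FALSE
    }
    new_pos <- cand[!claimed]
    if (length(new_pos))
      ridges <- rbind(ridges, data.frame(pos = new_pos, pos0 = new_pos,
                                         len = 1L, gap = 0L, alive = TRUE))
  }
  keep <- ridges[ridges$len >= min_ridge_len, , drop = FALSE]
  if (!nrow(keep)) return(empty)
  ns <- noise_sd(x)
  if (ns <= 0) ns <- .Machine$double.eps

  # apex refinement on the raw corrected signal
  ref_apex <- function(p) {
    lo <- max(0L, p - 2L); hi <- min(n - 1L, p + 2L)
    w <- ch_slice(x, lo, hi)
    lo + which.max(w) - 1L
  }
  apex <- vapply(keep$pos0, ref_apex, integer(1))
  o <- order(apex, -keep$len)
  apex <- apex[o]
  dup <- duplicated(apex)
  apex <- apex[!dup]
  # apex SNR on the smallest-scale smoothed signal: a real peak keeps its
  # amplitude there while white-noise excursions are already attenuated
  snr <- sm1[apex + 1L] / ns
  apex <- apex[snr >= snr_min & x[apex + 1L] > 0]
  if (!length(apex)) return(empty)

  # bounds from flanking minima of the smallest-scale smoothed signal;
  # every channel of a plateau minimum counts so bounds hug the peak
  nn <- length(sm1)
  mins <- c(0L, which(sm1[2:(nn - 1)] <= sm1[1:(nn - 2)] &
                      sm1[2:(nn - 1)] <= sm1[3:nn]), nn - 1L)
  mins <- sort(unique(mins))
  li <- findInterval(apex, mins)
  li[li < 1L] <- 1L
  start <- mins[li]
  ri <- pmin(li + 1L, length(mins))
  end <- mins[ri]
  bad <- !(start <= apex & apex <= end)
  if (any(bad)) { start[bad] <- pmax(apex[bad] - 2L, 0L); end[bad] <- pmin(apex[bad] + 2L, n - 1L) }

  # trim overlaps to the valley between successive apexes
  if (length(apex) > 1L) {
    for (i in seq_len(length(apex) - 1L)) {
      if (end[i] >= start[i + 1L]) {
        seg <- ch_slice(x, apex[i], apex[i + 1L])
        valley <- apex[i] + which.min(seg) - 1L
        end[i] <- valley
        start[i + 1L] <- valley
      }
    }
  }
  len <- end - start + 1L
  area <- vapply(seq_along(apex), function(i) peak_area(x, start[i], end[i]),
                 numeric(1))
  height <- x[apex + 1L]
  ok <- len >= 3L & area > 0 & height > 0
  apex <- apex[ok]; start <- start[ok]; end <- end[ok]
  area <- area[ok]; height <- height[ok]
  if (!length(apex)) return(empty)
  rt <- if (inherits(chrom, "chromatogram")) channel_time(chrom, apex) else apex
  data.frame(sample_id = sid,
             peak_id = paste0(sid, "_p", seq_along(apex)),
             apex_channel = as.integer(apex), rt_min = rt,
             start_channel = as.integer(start), end_channel = as.integer(end),
             height = height, area = area, stringsAsFactors = FALSE)
}

#' Trapezoidal peak area over an elution range
#'
#' @param chrom baseline-corrected chromatogram or numeric vector.
#' @param start,end inclusive 0-based channel bounds, \code{start <= end}.
#' @return trapezoidal integral of the signal over the range, floored at 0.
#' @examples
#' peak_area(rep(1, 10), 0, 4)  # 4
#' @export
peak_area <- function(chrom, start, end) {
  x <- signal_of(chrom)
  n <- length(x)
  if (start > end || start < 0L || end > n - 1L)
    stop_atsa("elution range [", start, ", ", end, "] out of bounds")
  if (start == end) return(0)
  y <- ch_slice(x, start, end)
  max(0, sum((y[-1] + y[-length(y)]) / 2))
}
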
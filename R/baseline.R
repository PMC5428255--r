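#' Local minimum channels of a chromatogram
#'
#' Returns every channel whose intensity is less than or equal to both
#' neighbours, plus the two endpoint channels (always included so that a
#' baseline interpolated through the minima is defined on the whole axis).
#' A plateau minimum (a run of equal values lower than both flanks)
#' contributes its leftmost channel only.
#'
#' @param chrom a \code{chromatogram} or bare numeric vector (length >= 3).
#' @return increasing 0-based integer channels.
#' @examples
#' local_minima(c(3, 1, 3, 1, 3))   # 0 1 3 4
#' @export
local_minima <- function(chrom) {
  x <- signal_of(chrom)
  n <- length(x)
  if (n < 3L) stop_atsa("need at least 3 channels")
  r <- rle(x)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))  # 1-based run starts
  v <- r$values
  m <- length(v)
  if (m == 1L) {
    message("constant signal: only endpoint anchors available")
    return(c(0L, n - 1L))
  }
  interior <- if (m >= 3L) which(v[2:(m - 1)] < v[1:(m - 2)] &
                                 v[2:(m - 1)] < v[3:m]) + 1L else integer(0)
  sort(unique(c(0L, starts[interior] - 1L, n - 1L)))
}

signal_of <- function(x) if (inherits(x, "chromatogram")) x$intensities else as.numeric(x)

#' Robust filtering of local minimum values
#'
#' Iteratively removes local-minimum anchors that belong to chromatographic
#' peaks (e.g. the saddle between two overlapping peaks) rather than to the
#' baseline. At each iteration every interior anchor is compared with the
#' straight line joining its two surviving neighbours; anchors whose
#' residual exceeds \code{z_cut} robust standard deviations
#' (\code{1.483 * MAD} of all interior residuals) are dropped. Iteration
#' stops when nothing is removed, the MAD collapses to zero, or
#' \code{max_iter} is reached. Endpoint anchors are never removed.
#'
#' @param chrom chromatogram or numeric vector.
#' @param lmv candidate anchor channels (0-based); endpoints are added if
#'   missing.
#' @param z_cut robust z-score threshold (default 2.5).
#' @param max_iter iteration cap.
#' @return surviving anchor channels, increasing, endpoints included.
#' @export
rsa_filter <- function(chrom, lmv, z_cut = 2.5, max_iter = 100L) {
  x <- signal_of(chrom)
  n <- length(x)
  if (!length(lmv)) stop_atsa("lmv must be nonempty")
  a <- sort(unique(as.integer(c(0L, lmv, n - 1L))))
  if (any(a < 0L | a > n - 1L)) stop_atsa("anchor channel out of range")
  for (it in seq_len(max_iter)) {
    m <- length(a)
    if (m <= 2L) break
    v <- x[a + 1L]
    i <- 2:(m - 1)
    base <- v[i - 1] + (v[i + 1] - v[i - 1]) * (a[i] - a[i - 1]) / (a[i + 1] - a[i - 1])
    resid <- v[i] - base
    mad <- mad_scaled(resid)
    if (mad == 0) break
    z <- resid / mad
    drop <- i[z > z_cut]
    if (!length(drop)) break
    a <- a[-drop]
  }
  a
}

#' Estimate and subtract baseline drift
#'
#' Baseline model: local minimum values are extracted, peak-borne minima
#' are removed by \code{\link{rsa_filter}}, and the drift is the linear
#' interpolation through the surviving anchors. The corrected signal is
#' zero at every surviving anchor by construction.
#'
#' @param chrom a \code{chromatogram}.
#' @param z_cut passed to \code{\link{rsa_filter}}.
#' @param max_iter passed to \code{\link{rsa_filter}}.
#' @return list with \code{corrected} (a chromatogram) and \code{model}
#'   (class \code{"baseline_model"}: \code{anchor_channels},
#'   \code{anchor_values}, \code{baseline}).
#' @export
correct_baseline <- function(chrom, z_cut = 2.5, max_iter = 100L) {
  x <- signal_of(chrom)
  n <- length(x)
  anchors <- rsa_filter(x, suppressMessages(local_minima(x)),
                        z_cut = z_cut, max_iter = max_iter)
  bl <- stats::approx(anchors, x[anchors + 1L], xout = 0:(n - 1))$y
  corrected <- x - bl
  out <- if (inherits(chrom, "chromatogram")) {
    c2 <- chrom; c2$intensities <- corrected; c2
  } else corrected
  list(corrected = out,
       model = structure(list(anchor_channels = anchors,
                              anchor_values = x[anchors + 1L],
                              baseline = bl),
                         class = "baseline_model"))
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model: %d anchors over %d channels>\n",
              length(x$anchor_channels), length(x$baseline)))
  invisible(x)
}
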
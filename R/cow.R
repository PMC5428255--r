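#' Correlation optimized warping (reference implementation)
#'
#' Classic segment-based COW used as a benchmarking baseline: the
#' reference axis is divided into segments of \code{segment_length}
#' channels (the last takes the remainder; both signal ends are fixed),
#' each interior segment boundary on the test side may deviate from its
#' nominal position by at most \code{slack} channels, and dynamic
#' programming picks the boundary placement maximising the summed Pearson
#' correlation between each reference segment and the linearly warped
#' test piece. The correlation of a constant piece is defined as 0.
#'
#' @param ref,test equal-length numeric vectors (baseline-corrected).
#' @param segment_length nominal segment length, channels
#'   (>= slack + 3).
#' @param slack maximal boundary displacement, channels (>= 1).
#' @return list with \code{aligned} (test warped to the reference axis),
#'   \code{benefit} (total correlation), \code{boundaries} (chosen test
#'   boundary channels, 0-based) and \code{n_segments}.
#' @export
cow_align <- function(ref, test, segment_length, slack) {
  ref <- signal_of(ref); test <- signal_of(test)
  n <- length(ref)
  if (length(test) != n) stop_atsa("ref and test must have equal length")
  if (slack < 1L) stop_atsa("slack must be >= 1")
  if (segment_length < slack + 3L) stop_atsa("segment_length must be >= slack + 3")
  nominal <- seq(0L, n - 1L, by = segment_length)
  if (nominal[length(nominal)] != n - 1L) nominal <- c(nominal, n - 1L)
  if (length(nominal) < 2L) stop_atsa("signal shorter than one segment")
  K <- length(nominal) - 1L  # number of segments
  offsets <- -slack:slack
  no <- length(offsets)

  # offset grids per boundary; ends fixed
  feas <- function(b) {
    if (b == 1L || b == K + 1L) 0L else offsets
  }
  # dp[j, o]: best benefit up to boundary j at offset index o
  seg_cor <- function(i, o1, o2) {
    a <- nominal[i] + o1; b <- nominal[i + 1] + o2
    if (b - a < 2L || a < 0L || b > n - 1L) return(-Inf)
    rseg <- ch_slice(ref, nominal[i], nominal[i + 1])
    piece <- ch_slice(test, a, b)
    cc <- pearson(rseg, warp_segment(piece, length(rseg)))
    if (isTRUE(attr(cc, "constant"))) 0 else as.numeric(cc)
  }
  offs <- lapply(seq_len(K + 1L), feas)
  dp <- lapply(seq_len(K + 1L), function(j) rep(-Inf, length(offs[[j]])))
  back <- lapply(seq_len(K + 1L), function(j) rep(NA_integer_, length(offs[[j]])))
  dp[[1]][1] <- 0
  for (i in seq_len(K)) {
    for (o2 in seq_along(offs[[i + 1]])) {
      best <- -Inf; arg <- NA_integer_
      for (o1 in seq_along(offs[[i]])) {
        if (!is.finite(dp[[i]][o1])) next
        v <- dp[[i]][o1] + seg_cor(i, offs[[i]][o1], offs[[i + 1]][o2])
        if (v > best) { best <- v; arg <- o1 }
      }
      dp[[i + 1]][o2] <- best
      back[[i + 1]][o2] <- arg
    }
  }
  endv <- dp[[K + 1L]][1]
  if (!is.finite(endv)) stop_atsa("infeasible slack/segment combination")
  # backtrack
  path <- integer(K + 1L)
  path[K + 1L] <- 1L
  for (i in rev(seq_len(K))) path[i] <- back[[i + 1L]][path[i + 1L]]
  bounds <- vapply(seq_len(K + 1L), function(j) nominal[j] + offs[[j]][path[j]],
                   numeric(1))
  aligned <- numeric(n)
  for (i in seq_len(K)) {
    tgt <- nominal[i]:nominal[i + 1]
    piece <- ch_slice(test, bounds[i], bounds[i + 1])
    aligned[tgt + 1L] <- warp_segment(piece, length(tgt))
  }
  list(aligned = aligned, benefit = endv,
       boundaries = as.integer(bounds), n_segments = K)
}
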
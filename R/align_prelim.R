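# Preliminary segment-wise alignment. The reference chromatogram is cut
# into segments of roughly 3 min each holding >= 3 peaks; each segment is
# shifted as a rigid block to the integer-channel offset maximising the
# total peak correlation (TPC) over candidate offsets generated by
# peak-to-peak matching of the segment's largest peak; segment shifts are
# screened for outliers with a scaled-MAD rule and repaired; boundary
# gaps/overlaps are resolved and each piece is warped back to the
# reference segment length by linear interpolation.

#' Select the reference chromatogram
#'
#' The sample with the highest mean Pearson correlation against all other
#' samples becomes the reference (ties broken by the lowest index).
#'
#' @param ds a \code{chrom_dataset} (or samples x channels matrix) with at
#'   least 2 samples.
#' @return 1-based index of the reference sample.
#' @export
select_reference <- function(ds) {
  m <- if (inherits(ds, "chrom_dataset")) as.matrix(ds) else as.matrix(ds)
  if (nrow(m) < 2L) stop_atsa("need at least 2 samples to select a reference")
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- NA
  means <- rowMeans(cm, na.rm = TRUE)
  which.max(means)  # first maximum -> lowest index on ties
}

#' Pearson correlation between two equal-length signal windows
#'
#' Direct implementation of the product-moment formula; if either vector
#' is constant the denominator vanishes and 0 is returned with attribute
#' \code{constant = TRUE}.
#'
#' @param r,x numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pearson <- function(r, x) {
  if (length(r) != length(x)) stop_atsa("length mismatch")
  if (length(r) < 2L) stop_atsa("need length >= 2")
  rc <- r - mean(r); xc <- x - mean(x)
  den <- sqrt(sum(rc * rc) * sum(xc * xc))
  if (den == 0) return(structure(0, constant = TRUE))
  sum(rc * xc) / den
}

#' Partition the reference peak table into alignment segments
#'
#' Greedy left-to-right grouping: a peak joins the current segment while
#' its retention time is within \code{init_size_min} minutes of the
#' segment's first peak. Segments with fewer than 3 peaks are merged into
#' whichever neighbour holds fewer peaks (ties to the left; terminal
#' segments into their only neighbour). Segment boundaries start as the
#' first peak's start / last peak's end channel; each interior junction is
#' then replaced by the average of the adjoining end and start so that
#' segments tile.
#'
#' @param ref_peaks reference peak table (see \code{\link{detect_peaks}}),
#'   ordered by apex.
#' @param init_size_min initial segment size, minutes (default 3).
#' @param axis_len optional axis length in channels; when given, the outer
#'   boundaries are extended to channels 0 and \code{axis_len - 1} so the
#'   segments tile the whole axis.
#' @return data.frame with columns \code{index}, \code{ref_start},
#'   \code{ref_end} (0-based channels), \code{peak_first}, \code{peak_last}
#'   (row indices into \code{ref_peaks}), \code{n_peaks}.
#' @export
partition_segments <- function(ref_peaks, init_size_min = 3.0, axis_len = NULL) {
  p <- ref_peaks[order(ref_peaks$apex_channel), , drop = FALSE]
  np <- nrow(p)
  if (np < 1L) stop_atsa("no peaks to partition")
  if (np < 3L) warning("fewer than 3 peaks: single segment")
  grp <- integer(np)
  g <- 1L; first_rt <- p$rt_min[1]; grp[1] <- 1L
  for (i in seq_len(np)[-1]) {
    if (p$rt_min[i] - first_rt < init_size_min) grp[i] <- g
    else { g <- g + 1L; first_rt <- p$rt_min[i]; grp[i] <- g }
  }
  counts <- tabulate(grp)
  # merge undersized segments into the smaller neighbour
  while (length(counts) > 1L && any(counts < 3L)) {
    i <- which(counts < 3L)[1]
    tgt <- if (i == 1L) 2L
      else if (i == length(counts)) i - 1L
      else if (counts[i + 1L] < counts[i - 1L]) i + 1L else i - 1L
    lo <- min(i, tgt)
    grp[grp >= lo + 1L] <- grp[grp >= lo + 1L] - 1L
    counts <- tabulate(grp)
  }
  k <- max(grp)
  first <- match(seq_len(k), grp)
  last <- np + 1L - match(seq_len(k), rev(grp))
  raw_start <- p$start_channel[first]
  raw_end <- p$end_channel[last]
  core_start <- raw_start
  core_end <- raw_end
  if (k > 1L) {
    b <- round_half_up((raw_end[-k] + raw_start[-1]) / 2)
    core_end[-k] <- b
    core_start[-1] <- b
  }
  # core bounds are the peak-bearing extent used for shift search; the
  # outer warp bounds are extended to the axis ends when axis_len is given
  ref_start <- core_start
  ref_end <- core_end
  if (!is.null(axis_len)) {
    ref_start[1] <- 0L
    ref_end[k] <- axis_len - 1L
  }
  data.frame(index = seq_len(k),
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             core_start = as.integer(core_start), core_end = as.integer(core_end),
             peak_first = first, peak_last = last,
             n_peaks = last - first + 1L)
}

#' Search window of a segment on the test side
#'
#' The reference segment's boundaries are widened by the pre-estimated
#' maximal time shift on both sides, so the window is
#' \code{2 * shift_estimate_min} longer than the reference segment (1 min
#' at the 0.5-min default), clipped to the axis.
#'
#' @param seg one row of \code{\link{partition_segments}} output (or any
#'   list with \code{ref_start}, \code{ref_end} channels).
#' @param shift_estimate_min pre-estimated maximal shift, minutes (> 0).
#' @param sampling_interval minutes per channel.
#' @param axis_len axis length in channels.
#' @return integer vector \code{c(start, end)}, 0-based channels.
#' @export
test_window <- function(seg, shift_estimate_min = 0.5, sampling_interval,
                        axis_len) {
  if (shift_estimate_min <= 0) stop_atsa("shift_estimate_min must be > 0")
  delta <- as.integer(round_half_up(shift_estimate_min / sampling_interval))
  c(max(0L, as.integer(seg$ref_start) - delta),
    min(axis_len - 1L, as.integer(seg$ref_end) + delta))
}

#' Total peak correlation of a candidate segment shift
#'
#' For each reference peak in the segment the peak's elution range is
#' displaced by \code{shift}; the peak is matched when some test-peak apex
#' falls inside the displaced range. For a matched peak the time shift is
#' corrected by applying the candidate shift: the test window is the
#' reference peak's elution range displaced by \code{shift} (identical
#' length), and the per-peak Pearson correlation c_i is computed between
#' the two windows, so residual within-segment misalignment lowers c_i
#' and the criterion discriminates between nearby shifts. With peak weights
#' w_i = PeakArea_i / PeakLength_i, TPC = (sum w_i c_i / sum w_i) * (I/N)
#' over the I matched peaks of N in the segment; an unmatched peak is
#' reported with correlation -1 as a diagnostic but only enters through
#' the I/N factor. TPC is -1 when no peak matches.
#'
#' @param ref_signal full reference signal (baseline-corrected).
#' @param ref_peaks_seg reference peaks of the segment (peak-table rows).
#' @param test_signal full test signal.
#' @param test_peaks test peak table (at least \code{apex_channel}).
#' @param shift candidate shift, integer channels.
#' @param include_unmatched if TRUE the -1 correlations of unmatched peaks
#'   also enter the weighted sum (alternative reading; default FALSE).
#' @return list with \code{tpc}, \code{matched} (I), \code{n} (N) and
#'   \code{per_peak} diagnostics.
#' @export
tpc <- function(ref_signal, ref_peaks_seg, test_signal, test_peaks, shift,
                include_unmatched = FALSE) {
  ref_signal <- signal_of(ref_signal); test_signal <- signal_of(test_signal)
  nT <- length(test_signal)
  N <- nrow(ref_peaks_seg)
  ta <- test_peaks$apex_channel
  ci <- rep(NA_real_, N); wi <- numeric(N); matched <- logical(N)
  for (i in seq_len(N)) {
    rs <- ref_peaks_seg$start_channel[i]
    re <- ref_peaks_seg$end_channel[i]
    ra <- ref_peaks_seg$apex_channel[i]
    wi[i] <- ref_peaks_seg$area[i] / (re - rs + 1)
    inr <- which(ta >= rs + shift & ta <= re + shift)
    if (!length(inr)) { ci[i] <- -1; next }
    if (rs + shift < 0L || re + shift > nT - 1L) { ci[i] <- -1; next }
    ci[i] <- pearson(ch_slice(ref_signal, rs, re),
                     ch_slice(test_signal, rs + shift, re + shift))
    matched[i] <- TRUE
  }
  I <- sum(matched)
  val <- if (I == 0L) -1
  else if (include_unmatched) (sum(wi * ci) / sum(wi)) * (I / N)
  else (sum(wi[matched] * ci[matched]) / sum(wi[matched])) * (I / N)
  list(tpc = val, matched = I, n = N,
       per_peak = data.frame(peak = seq_len(N), c = ci, w = wi,
                             matched = matched))
}

#' Candidate shifts from peak-to-peak matching
#'
#' Candidates are generated by aligning the apex of the segment's
#' largest-area reference peak with each test-peak apex in the search
#' window, then filtered so that the whole displaced reference segment
#' stays inside the window. The no-shift fallback 0 is always included.
#'
#' @param seg segment row (with \code{ref_start}, \code{ref_end}).
#' @param ref_peaks_seg reference peaks of the segment.
#' @param test_peaks_window test peaks whose apex lies in the window.
#' @param window integer \code{c(start, end)} search window.
#' @return increasing unique integer shifts.
#' @export
candidate_shifts <- function(seg, ref_peaks_seg, test_peaks_window, window) {
  if (!nrow(ref_peaks_seg)) stop_atsa("segment has no reference peaks")
  pstar <- ref_peaks_seg$apex_channel[which.max(ref_peaks_seg$area)]
  cand <- integer(0)
  if (nrow(test_peaks_window))
    cand <- as.integer(test_peaks_window$apex_channel - pstar)
  else warning("no test peaks in window; falling back to shift 0")
  feasible <- cand[seg$ref_start + cand >= window[1] &
                   seg$ref_end + cand <= window[2]]
  sort(unique(c(feasible, 0L)))
}

#' Align one segment by maximising TPC over candidate shifts
#'
#' @inheritParams tpc
#' @inheritParams candidate_shifts
#' @param seg segment row.
#' @param test_peaks full test peak table.
#' @param window test-side search window.
#' @return list with the winning \code{shift}, its \code{tpc}, and the
#'   per-candidate table \code{candidates}.
#' @export
align_segment <- function(ref_signal, seg, ref_peaks_seg, test_signal,
                          test_peaks, window) {
  inw <- test_peaks[test_peaks$apex_channel >= window[1] &
                    test_peaks$apex_channel <= window[2], , drop = FALSE]
  cand <- candidate_shifts(seg, ref_peaks_seg, inw, window)
  scores <- vapply(cand, function(s)
    tpc(ref_signal, ref_peaks_seg, test_signal, test_peaks, s)$tpc, numeric(1))
  # max TPC; ties -> smaller |shift|, then smaller shift
  best <- order(-scores, abs(cand), cand)[1]
  list(shift = cand[best], tpc = scores[best],
       candidates = data.frame(shift = cand, tpc = scores))
}

#' Robust outlier screening of segment shifts
#'
#' Computes the scaled-MAD spread sigma = 1.483 * median(|s_i - median(s)|)
#' and the robust scores d_k = |s_k - median(s)| / sigma; a segment is
#' flagged when d_k exceeds \code{threshold} strictly (d_k equal to the
#' threshold is not an outlier). When sigma is 0 all d_k are defined as 0
#' and nothing is flagged.
#'
#' @param shifts per-segment integer shifts (length >= 3 recommended).
#' @param threshold flagging threshold on d_k (default 2.5, ~99\% level).
#' @return object of class \code{"shift_diagnostics"}: list with
#'   \code{shifts}, \code{sigma}, \code{center} (median), \code{d_scores},
#'   \code{outlier_flags}.
#' @export
detect_outliers <- function(shifts, threshold = 2.5) {
  med <- stats::median(shifts)
  sigma <- mad_scaled(shifts)
  d <- if (sigma > 0) abs(shifts - med) / sigma else rep(0, length(shifts))
  structure(list(shifts = shifts, sigma = sigma, center = med,
                 d_scores = d, outlier_flags = d > threshold,
                 threshold = threshold),
            class = "shift_diagnostics")
}

#' @export
print.shift_diagnostics <- function(x, ...) {
  cat(sprintf("<shift_diagnostics: %d segments, median %g, sigma %.3f, %d outlier(s)>\n",
              length(x$shifts), x$center, x$sigma, sum(x$outlier_flags)))
  invisible(x)
}

#' Re-align an outlier segment by local correlation maxima
#'
#' The TPC criterion is abandoned for a flagged segment; the plain Pearson
#' correlation between the reference segment and the displaced test window
#' is evaluated at every integer shift within expected +/- ceil(2.5 sigma)
#' (clipped to feasibility), local maxima of the correlation-vs-shift
#' curve are located, and the local maximum closest to the expected shift
#' (the median of all segment shifts) wins; ties go to the smaller shift.
#' Only interior maxima qualify: a curve still rising at a window edge
#' points to an optimum outside the window, so when no interior maximum
#' exists \code{fallback} (by default the expected shift; the pipeline
#' passes the segment's original TPC shift) is returned unchanged.
#'
#' @param ref_signal,test_signal full signals.
#' @param seg segment row.
#' @param sigma robust spread of the segment shifts, channels.
#' @param expected_shift median segment shift, channels.
#' @param threshold half-width multiplier (2.5 by default).
#' @param fallback shift to keep when the window holds no local maximum.
#' @return the repaired integer shift.
#' @export
realign_outlier <- function(ref_signal, seg, test_signal, sigma,
                            expected_shift, threshold = 2.5,
                            fallback = expected_shift) {
  expected_int <- as.integer(round_half_away(expected_shift))
  if (sigma <= 0) return(expected_int)
  ref_signal <- signal_of(ref_signal); test_signal <- signal_of(test_signal)
  half <- as.integer(ceiling(threshold * sigma))
  n1 <- length(test_signal) - 1L
  lo <- max(expected_int - half, -seg$ref_start)
  hi <- min(expected_int + half, n1 - seg$ref_end)
  if (lo > hi) return(expected_int)
  shifts <- lo:hi
  rseg <- ch_slice(ref_signal, seg$ref_start, seg$ref_end)
  corr_at <- function(s)
    as.numeric(pearson(rseg, ch_slice(test_signal, seg$ref_start + s,
                                      seg$ref_end + s)))
  cc <- vapply(shifts, corr_at, numeric(1))
  m <- length(cc)
  fallback <- as.integer(round_half_away(fallback))
  if (m < 3L) return(fallback)
  is_max <- c(FALSE,
              cc[2:(m - 1)] >= cc[1:(m - 2)] & cc[2:(m - 1)] >= cc[3:m],
              FALSE)
  if (!any(is_max)) return(fallback)
  lm <- shifts[is_max]
  best <- lm[order(abs(lm - expected_shift), lm)][1]
  # a repair must not fit worse than the shift it replaces
  if (fallback >= -seg$ref_start && fallback <= n1 - seg$ref_end &&
      corr_at(best) < corr_at(fallback)) return(fallback)
  as.integer(best)
}

#' Resolve segment boundaries after shifting
#'
#' After each segment is displaced by its shift, neighbouring test-side
#' boundaries disconnect (gap) or overlap. Every junction is placed at the
#' half-up rounded average of the former segment's end and the latter
#' segment's start. For overlaps the rule additionally records which
#' segment's boundary was considered modified: if a test-peak END lies
#' nearer the middle of the overlapped zone than any peak START, the later
#' segment's start is the modified one (\code{"overlap_end"}); if a peak
#' START is nearer, the former segment's end (\code{"overlap_start"});
#' otherwise both (\code{"overlap_avg"}). Gap junctions are
#' \code{"gap"}; touching junctions \code{"touch"} keep their channel.
#'
#' @param segments segment data.frame with a \code{shift} column.
#' @param test_peaks test peak table (for the overlap rule).
#' @return data.frame with \code{junction}, \code{former_end},
#'   \code{latter_start}, \code{boundary}, \code{rule}. Boundaries are
#'   checked to be strictly increasing.
#' @export
resolve_boundaries <- function(segments, test_peaks = NULL) {
  k <- nrow(segments)
  if (k < 2L) return(data.frame(junction = integer(0), former_end = integer(0),
                                latter_start = integer(0), boundary = integer(0),
                                rule = character(0), stringsAsFactors = FALSE))
  fe <- segments$ref_end[-k] + segments$shift[-k]
  ls <- segments$ref_start[-1] + segments$shift[-1]
  boundary <- integer(k - 1L); rule <- character(k - 1L)
  for (j in seq_len(k - 1L)) {
    if (ls[j] == fe[j]) { boundary[j] <- fe[j]; rule[j] <- "touch"; next }
    b <- as.integer(round_half_up((fe[j] + ls[j]) / 2))
    if (ls[j] > fe[j]) { boundary[j] <- b; rule[j] <- "gap"; next }
    zone <- c(ls[j], fe[j]); mid <- mean(zone)
    de <- ds <- Inf
    if (!is.null(test_peaks) && nrow(test_peaks)) {
      ends <- test_peaks$end_channel[test_peaks$end_channel >= zone[1] &
                                     test_peaks$end_channel <= zone[2]]
      starts <- test_peaks$start_channel[test_peaks$start_channel >= zone[1] &
                                         test_peaks$start_channel <= zone[2]]
      if (length(ends)) de <- min(abs(ends - mid))
      if (length(starts)) ds <- min(abs(starts - mid))
    }
    boundary[j] <- b
    rule[j] <- if (is.finite(de) && de < ds) "overlap_end"
      else if (is.finite(ds) && ds < de) "overlap_start"
      else "overlap_avg"
  }
  if (any(diff(boundary) <= 0))
    stop_atsa("internal error: resolved boundaries are not strictly increasing")
  data.frame(junction = seq_len(k - 1L), former_end = fe, latter_start = ls,
             boundary = boundary, rule = rule, stringsAsFactors = FALSE)
}

#' Warp a signal piece to a target length by linear interpolation
#'
#' The source is evaluated at \code{target_length} equally spaced
#' positions spanning its first and last index, compressing long pieces
#' and stretching short ones; the endpoint values are preserved exactly.
#'
#' @param piece numeric vector (length >= 2).
#' @param target_length output length (>= 2).
#' @return numeric vector of length \code{target_length}.
#' @export
warp_segment <- function(piece, target_length) {
  n <- length(piece)
  if (n < 2L || target_length < 2L) stop_atsa("both lengths must be >= 2")
  if (n == target_length) return(piece)
  stats::approx(seq_len(n), piece,
                xout = seq(1, n, length.out = target_length))$y
}

#' Preliminary segment-wise alignment of one test chromatogram
#'
#' Runs the full preliminary stage: segment partition of the reference
#' peak table, test-window construction, peak-to-peak candidate search,
#' TPC shift selection, robust outlier repair, boundary resolution, and
#' per-segment warping back to the reference segment lengths. The output
#' chromatogram has exactly the reference's length, and test peak
#' channels are remapped through the piecewise-linear warp.
#'
#' @param ref reference \code{chromatogram} (baseline-corrected).
#' @param ref_peaks reference peak table.
#' @param test test \code{chromatogram} (same axis).
#' @param test_peaks test peak table.
#' @param init_size_min initial segment size, minutes.
#' @param shift_estimate_min pre-estimated maximal shift, minutes.
#' @param outlier_threshold robust flagging threshold (2.5).
#' @param segments optional precomputed segment table (so a dataset-level
#'   run partitions the reference once).
#' @return object of class \code{"alignment_result"}: list with
#'   \code{chromatogram} (aligned), \code{peaks} (remapped test peaks),
#'   \code{segments} (with shift, tpc, d-score, outlier flag),
#'   \code{junctions}, \code{diagnostics}, \code{map} (warp knots),
#'   \code{stage = "preliminary"}.
#' @export
preliminary_align <- function(ref, ref_peaks, test, test_peaks,
                              init_size_min = 3.0, shift_estimate_min = 0.5,
                              outlier_threshold = 2.5, segments = NULL) {
  n <- length(ref$intensities)
  if (length(test$intensities) != n ||
      abs(test$sampling_interval - ref$sampling_interval) > 1e-12)
    stop_atsa("reference and test must share the time axis")
  if (is.null(segments))
    segments <- partition_segments(ref_peaks, init_size_min, axis_len = n)
  k <- nrow(segments)
  if (is.null(segments$core_start)) {
    segments$core_start <- segments$ref_start
    segments$core_end <- segments$ref_end
  }
  shifts <- integer(k); tpcs <- numeric(k)
  for (i in seq_len(k)) {
    seg <- segments[i, ]
    core <- list(ref_start = seg$core_start, ref_end = seg$core_end)
    win <- test_window(core, shift_estimate_min, ref$sampling_interval, n)
    pk <- ref_peaks[seg$peak_first:seg$peak_last, , drop = FALSE]
    fit <- align_segment(ref$intensities, core, pk, test$intensities,
                         test_peaks, win)
    shifts[i] <- fit$shift; tpcs[i] <- fit$tpc
  }
  diag <- detect_outliers(shifts, outlier_threshold)
  if (any(diag$outlier_flags)) {
    for (i in which(diag$outlier_flags)) {
      core <- list(ref_start = segments$core_start[i],
                   ref_end = segments$core_end[i])
      shifts[i] <- realign_outlier(ref$intensities, core,
                                   test$intensities, diag$sigma, diag$center,
                                   outlier_threshold, fallback = shifts[i])
      tpcs[i] <- NA_real_  # repaired by correlation, not TPC
    }
  }
  segments$shift <- shifts
  segments$tpc <- tpcs
  segments$d_score <- diag$d_scores
  segments$outlier <- diag$outlier_flags

  junctions <- resolve_boundaries(segments, test_peaks)
  # test-side knots (resolved junction channels plus the ideal outer ends)
  # map onto reference-side knots (the reference junction channels); outer
  # knots may fall outside the axis, in which case the missing source
  # channels are taken from the nearest edge so terminal segments are
  # translated, not smeared
  t0 <- segments$ref_start[1] + shifts[1]
  tK <- segments$ref_end[k] + shifts[k]
  t_knots <- c(t0, junctions$boundary, tK)
  r_knots <- c(segments$ref_start[1], segments$ref_end[-k], segments$ref_end[k])
  if (any(diff(t_knots) <= 0))
    stop_atsa("internal error: warp knots are not strictly increasing")
  aligned <- numeric(n)
  for (i in seq_len(k)) {
    idx <- t_knots[i]:t_knots[i + 1]
    src <- test$intensities[pmin(pmax(idx, 0L), n - 1L) + 1L]
    tgt_len <- r_knots[i + 1] - r_knots[i] + 1L
    aligned[(r_knots[i]:r_knots[i + 1]) + 1L] <- warp_segment(src, tgt_len)
  }
  out <- test; out$intensities <- aligned

  peaks <- remap_peaks(test_peaks, t_knots, r_knots, out)
  structure(list(chromatogram = out, peaks = peaks, segments = segments,
                 junctions = junctions, diagnostics = diag,
                 map = list(from = t_knots, to = r_knots),
                 stage = "preliminary"),
            class = "alignment_result")
}

# Remap peak channels through the piecewise-linear warp defined by knot
# pairs (from -> to). Peaks whose apex falls outside the mapped span are
# dropped; colliding rounded apexes keep the larger-area peak.
remap_peaks <- function(peaks, from, to, chrom) {
  if (!nrow(peaks)) return(peaks)
  mapf <- function(v) stats::approx(from, to, xout = v, rule = 2)$y
  inside <- peaks$apex_channel >= from[1] & peaks$apex_channel <= from[length(from)]
  p <- peaks[inside, , drop = FALSE]
  if (!nrow(p)) return(p)
  p$apex_channel <- as.integer(round_half_up(mapf(p$apex_channel)))
  p$start_channel <- as.integer(round_half_up(mapf(p$start_channel)))
  p$end_channel <- as.integer(round_half_up(mapf(p$end_channel)))
  p$start_channel <- pmin(p$start_channel, p$apex_channel)
  p$end_channel <- pmax(p$end_channel, p$apex_channel)
  p$rt_min <- channel_time(chrom, p$apex_channel)
  # order preserved by monotone map; drop duplicate apexes (keep larger area)
  p <- p[order(p$apex_channel, -p$area), , drop = FALSE]
  p <- p[!duplicated(p$apex_channel), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result (%s): %d channels, %d segments%s>\n",
              x$stage, length(x$chromatogram$intensities),
              nrow(x$segments),
              if (!is.null(x$diagnostics))
                sprintf(", %d outlier(s) repaired", sum(x$diagnostics$outlier_flags))
              else ""))
  invisible(x)
}
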
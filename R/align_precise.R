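# Precise, peak-anchored alignment. After the preliminary stage each
# test peak may still sit a few channels off its reference counterpart.
# The aligned test chromatogram is partitioned into one sub-segment per
# peak, each sub-segment is displaced to the nearest reference peak whose
# apex elutes within the test peak's range (unmatched sub-segments borrow
# the mean shift of their matched neighbours), and the two halves of each
# sub-segment are warped independently so the apex lands exactly on the
# reference apex channel.

#' Partition a region into per-peak sub-segments
#'
#' One sub-segment per test peak; the interior boundary between peaks i
#' and i+1 is the half-up rounded average of peak i's end and peak i+1's
#' start, so successive sub-segments connect. The first sub-segment
#' starts at the region start and the last ends at the region end.
#'
#' @param test_peaks test peak table (rows ordered by apex).
#' @param region integer \code{c(start, end)} channels to cover.
#' @return data.frame with \code{index}, \code{start}, \code{end},
#'   \code{peak_row}, \code{apex_channel} (peak_row NA for the peak-free
#'   passthrough case).
#' @export
partition_subsegments <- function(test_peaks, region) {
  p <- test_peaks[test_peaks$apex_channel >= region[1] &
                  test_peaks$apex_channel <= region[2], , drop = FALSE]
  p <- p[order(p$apex_channel), , drop = FALSE]
  np <- nrow(p)
  if (!np)
    return(data.frame(index = 1L, start = region[1], end = region[2],
                      peak_row = NA_integer_, apex_channel = NA_integer_))
  b <- if (np > 1L)
    as.integer(round_half_up((p$end_channel[-np] + p$start_channel[-1]) / 2))
  else integer(0)
  b <- pmin(pmax(b, region[1] + 1L), region[2] - 1L)
  start <- c(region[1], b)
  end <- c(b, region[2])
  data.frame(index = seq_len(np), start = start, end = end,
             peak_row = as.integer(rownames(p)),
             apex_channel = p$apex_channel)
}

#' Shift of one sub-segment towards its reference peak
#'
#' Among reference peaks whose apex elutes within the test peak's elution
#' range, the nearest in retention time is chosen and the shift is
#' (reference apex - test apex). With no qualifying reference peak the
#' sub-segment is marked for imputation.
#'
#' @param test_peak one test peak (row of a peak table).
#' @param ref_peaks reference peak table.
#' @return list with \code{shift} (integer or NA) and \code{source}
#'   (\code{"matched"} or \code{"imputed"}).
#' @export
precise_shift <- function(test_peak, ref_peaks) {
  ra <- ref_peaks$apex_channel
  inr <- which(ra >= test_peak$start_channel & ra <= test_peak$end_channel)
  if (!length(inr)) return(list(shift = NA_integer_, source = "imputed"))
  d <- ra[inr] - test_peak$apex_channel
  pick <- inr[order(abs(d), d)][1]
  list(shift = as.integer(ra[pick] - test_peak$apex_channel),
       source = "matched")
}

#' Impute shifts for sub-segments without a reference peak
#'
#' Each unmatched sub-segment receives the mean of the shifts of its
#' nearest matched neighbours on each side, rounded half away from zero;
#' a terminal unmatched sub-segment copies its single available
#' neighbour. With no matched sub-segment at all every shift is 0 and a
#' warning is issued.
#'
#' @param subs data.frame with columns \code{shift} (NA where unmatched)
#'   and \code{source}.
#' @return the same data.frame with all shifts filled in.
#' @export
impute_shifts <- function(subs) {
  matched <- which(subs$source == "matched")
  todo <- which(subs$source != "matched")
  if (!length(todo)) return(subs)
  if (!length(matched)) {
    warning("no matched sub-segment; all shifts set to 0")
    subs$shift <- 0L
    return(subs)
  }
  for (i in todo) {
    left <- matched[matched < i]
    right <- matched[matched > i]
    l <- if (length(left)) subs$shift[max(left)] else NA_integer_
    r <- if (length(right)) subs$shift[min(right)] else NA_integer_
    subs$shift[i] <- if (is.na(l)) r
      else if (is.na(r)) l
      else as.integer(round_half_away((l + r) / 2))
  }
  subs
}

#' Warp a sub-segment in two halves about its apex
#'
#' The piece is split at the apex; the left part is linearly interpolated
#' onto [start, apex + shift] and the right part onto [apex + shift, end]
#' independently, so the apex value is preserved exactly at its new
#' position and the boundary values stay fixed. A shift that would push
#' the apex onto (or past) a boundary is clipped to leave at least one
#' channel on each side, with a warning.
#'
#' @param piece numeric vector (the sub-segment's signal).
#' @param apex_index 1-based apex position within \code{piece}.
#' @param shift integer displacement of the apex, channels.
#' @return numeric vector of the same length with the apex moved.
#' @export
warp_subsegment <- function(piece, apex_index, shift) {
  n <- length(piece)
  if (n < 3L) return(piece)
  if (apex_index < 2L || apex_index > n - 1L)
    stop_atsa("apex must be interior to the piece")
  new_apex <- apex_index + shift
  if (new_apex < 2L || new_apex > n - 1L) {
    new_apex <- min(max(new_apex, 2L), n - 1L)
    warning("shift clipped to keep the apex inside the sub-segment")
  }
  c(warp_segment(piece[1:apex_index], new_apex),
    warp_segment(piece[apex_index:n], n - new_apex + 1L)[-1])
}

#' Precise peak-anchored alignment
#'
#' Takes a preliminarily aligned chromatogram (an
#' \code{\link{preliminary_align}} result, or a chromatogram plus its
#' peak table) and rebuilds it from per-peak sub-segments so that every
#' matched test peak apex coincides exactly with its reference peak apex.
#' Sub-segment boundary conflicts after shifting are resolved by plain
#' averaging of the displaced boundaries.
#'
#' @param prelim an \code{alignment_result} from
#'   \code{\link{preliminary_align}}, or a \code{chromatogram}.
#' @param ref_peaks reference peak table.
#' @param test_peaks required when \code{prelim} is a bare chromatogram.
#' @return an \code{alignment_result} with \code{stage = "precise"} and a
#'   \code{subsegments} table (start, end, shift, source).
#' @export
precise_align <- function(prelim, ref_peaks, test_peaks = NULL) {
  if (inherits(prelim, "alignment_result")) {
    chrom <- prelim$chromatogram
    peaks <- prelim$peaks
  } else {
    chrom <- prelim
    peaks <- test_peaks
    if (is.null(peaks)) stop_atsa("test_peaks required")
  }
  x <- chrom$intensities
  n <- length(x)
  rownames(peaks) <- seq_len(nrow(peaks))
  subs <- partition_subsegments(peaks, c(0L, n - 1L))
  if (all(is.na(subs$peak_row))) {
    out <- structure(list(chromatogram = chrom, peaks = peaks,
                          subsegments = subs, stage = "precise"),
                     class = "alignment_result")
    return(out)
  }
  fits <- lapply(subs$peak_row, function(r) precise_shift(peaks[r, ], ref_peaks))
  subs$shift <- vapply(fits, function(f) as.integer(f$shift), integer(1))
  subs$source <- vapply(fits, `[[`, character(1), "source")
  subs <- impute_shifts(subs)
  m <- nrow(subs)

  # resolve displaced sub-segment junctions by averaging
  nb <- subs$start  # new boundaries; nb[1] stays at region start
  new_start <- subs$start; new_end <- subs$end
  if (m > 1L) {
    fe <- subs$end[-m] + subs$shift[-m]
    ls <- subs$start[-1] + subs$shift[-1]
    b <- as.integer(round_half_up((fe + ls) / 2))
    # keep each displaced apex strictly inside its sub-segment
    na_new <- subs$apex_channel + subs$shift
    b <- pmax(b, na_new[-m] + 1L)
    b <- pmin(b, na_new[-1] - 1L)
    b <- pmin(pmax(b, 1L), n - 2L)
    b <- cummax(b)
    new_end[-m] <- b
    new_start[-1] <- b
  }
  new_start[1] <- 0L; new_end[m] <- n - 1L
  subs$new_start <- new_start; subs$new_end <- new_end

  aligned <- numeric(n)
  new_peaks <- peaks
  for (i in seq_len(m)) {
    os <- subs$start[i]; oe <- subs$end[i]
    ns <- subs$new_start[i]; ne <- subs$new_end[i]
    apex <- subs$apex_channel[i]
    na <- apex + subs$shift[i]
    if (na <= ns) na <- ns + 1L
    if (na >= ne) na <- ne - 1L
    if (ne - ns < 2L || apex <= os || apex >= oe) {
      # degenerate piece: plain single-part warp, no apex anchoring
      aligned[(ns:ne) + 1L] <- warp_segment(ch_slice(x, os, oe), ne - ns + 1L)
      na <- apex
    } else {
      piece_l <- ch_slice(x, os, apex)
      piece_r <- ch_slice(x, apex, oe)
      aligned[(ns:na) + 1L] <- warp_segment(piece_l, na - ns + 1L)
      aligned[(na:ne) + 1L] <- warp_segment(piece_r, ne - na + 1L)
    }
    # remap this sub-segment's peak through the two-part linear map
    r <- subs$peak_row[i]
    mapf <- function(v) stats::approx(c(os, apex, oe), c(ns, na, ne),
                                      xout = v, rule = 2)$y
    new_peaks$apex_channel[r] <- as.integer(na)
    new_peaks$start_channel[r] <- as.integer(round_half_up(mapf(peaks$start_channel[r])))
    new_peaks$end_channel[r] <- as.integer(round_half_up(mapf(peaks$end_channel[r])))
    new_peaks$rt_min[r] <- channel_time(chrom, na)
  }
  out_chrom <- chrom; out_chrom$intensities <- aligned
  new_peaks <- new_peaks[order(new_peaks$apex_channel), , drop = FALSE]
  rownames(new_peaks) <- NULL
  structure(list(chromatogram = out_chrom, peaks = new_peaks,
                 subsegments = subs,
                 segments = if (inherits(prelim, "alignment_result"))
                   prelim$segments else NULL,
                 junctions = if (inherits(prelim, "alignment_result"))
                   prelim$junctions else NULL,
                 diagnostics = if (inherits(prelim, "alignment_result"))
                   prelim$diagnostics else NULL,
                 stage = "precise"),
            class = "alignment_result")
}
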
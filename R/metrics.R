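# Quality-control metrics: per-sample correlation to the reference,
# per-peak relative area deviation after warping, and parameter
# sensitivity sweeps.

#' Per-sample correlation report
#'
#' Pearson correlation of every sample against the reference sample,
#' with a pass flag at \code{threshold} (0.95 by default, the usual
#' fingerprint-similarity cut).
#'
#' @param ds \code{chrom_dataset} or samples x channels matrix.
#' @param ref_index 1-based reference sample index.
#' @param threshold pass threshold.
#' @return data.frame with \code{sample_id}, \code{r}, \code{pass}.
#' @export
correlation_report <- function(ds, ref_index, threshold = 0.95) {
  m <- as.matrix(ds)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(m)))
  r <- apply(m, 1, function(x) as.numeric(pearson(m[ref_index, ], x)))
  data.frame(sample_id = ids, r = r, pass = r >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Peak-area preservation report
#'
#' Relative area deviation RD\% = (area_aligned - area_original) /
#' area_original x 100 for every peak tracked (by \code{sample_id} +
#' \code{peak_id}) through the warps, with the fraction of peaks and of
#' total area within |RD\%| <= 5, 7, 10.
#'
#' @param original_peaks peak table before alignment.
#' @param aligned_peaks peak table after alignment (same identifiers).
#' @return list with \code{per_peak} (sample_id, peak_id, area_original,
#'   area_aligned, rd_pct) and \code{summary} (threshold, frac_peaks,
#'   frac_area). Peaks with non-positive original area are excluded with
#'   a note in \code{n_excluded}.
#' @export
area_rd_report <- function(original_peaks, aligned_peaks) {
  key <- function(p) paste(p$sample_id, p$peak_id, sep = "\r")
  i <- match(key(aligned_peaks), key(original_peaks))
  ok <- !is.na(i)
  a1 <- original_peaks$area[i[ok]]
  a2 <- aligned_peaks$area[ok]
  sid <- aligned_peaks$sample_id[ok]
  pid <- aligned_peaks$peak_id[ok]
  pos <- a1 > 0
  per <- data.frame(sample_id = sid[pos], peak_id = pid[pos],
                    area_original = a1[pos], area_aligned = a2[pos],
                    rd_pct = (a2[pos] - a1[pos]) / a1[pos] * 100,
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c(5, 7, 10), function(x) {
    inx <- abs(per$rd_pct) <= x
    data.frame(threshold = x, frac_peaks = mean(inx),
               frac_area = sum(per$area_original[inx]) / sum(per$area_original))
  }))
  list(per_peak = per, summary = summ, n_excluded = sum(!pos))
}

#' Sensitivity sweep over segment size and shift estimate
#'
#' Re-runs the full alignment for each initial segment size and each
#' pre-estimated shift value and tabulates the number of segments, the
#' mean post-alignment correlation to the reference, and the wall time.
#'
#' @param ds \code{chrom_dataset} (raw signals).
#' @param segment_sizes initial segment sizes to try, minutes.
#' @param shift_estimates pre-estimated shift values to try, minutes.
#' @param ... passed on to \code{\link{atsa}}.
#' @return list of two data.frames, \code{by_segment_size} and
#'   \code{by_shift_estimate} (parameter, n_segments, mean_r, seconds).
#' @export
sensitivity_sweep <- function(ds, segment_sizes = c(1, 3, 5, 10),
                              shift_estimates = c(0.25, 0.5, 1.0), ...) {
  run <- function(seg, sh) {
    t0 <- proc.time()[["elapsed"]]
    fit <- atsa(ds, segment_min = seg, shift_min = sh, ...)
    el <- proc.time()[["elapsed"]] - t0
    cr <- correlation_report(fit$aligned, fit$reference)
    c(n_segments = nrow(fit$segments), mean_r = mean(cr$r), seconds = el)
  }
  a <- t(vapply(segment_sizes, function(s) run(s, 0.5), numeric(3)))
  b <- t(vapply(shift_estimates, function(s) run(3.0, s), numeric(3)))
  list(by_segment_size = data.frame(segment_min = segment_sizes, a),
       by_shift_estimate = data.frame(shift_min = shift_estimates, b))
}
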
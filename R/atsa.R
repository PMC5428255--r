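#' Automatic time-shift alignment of a chromatogram dataset
#'
#' Runs the full pipeline on a set of uniformly sampled one-dimensional
#' chromatograms: per-sample baseline correction (robustly filtered
#' local-minimum interpolation), multi-scale peak detection, automatic
#' reference selection (highest mean correlation to the other samples),
#' preliminary segment-wise alignment under the total-peak-correlation
#' criterion with robust repair of misaligned segments, and - unless
#' disabled - peak-anchored precise alignment that lands every matched
#' test peak apex exactly on its reference apex channel.
#'
#' @param x a \code{\link{chrom_dataset}} or a samples x channels numeric
#'   matrix (then \code{sampling_interval} is required).
#' @param segment_min initial segment size, minutes (default 3).
#' @param shift_min pre-estimated maximal time shift, minutes (default
#'   0.5; covers most GC drift).
#' @param reference \code{"auto"} or a 1-based sample index.
#' @param precise run the precise stage (default TRUE).
#' @param baseline correct baseline drift first (default TRUE).
#' @param z_cut robust z threshold of the baseline anchor filter.
#' @param outlier_threshold robust d-score threshold for segment repair.
#' @param scales,min_ridge_len,snr_min peak-detection settings, see
#'   \code{\link{detect_peaks}}.
#' @param sampling_interval minutes per channel (matrix input only).
#' @return An object of class \code{"atsa"}: list with \code{aligned}
#'   (a \code{chrom_dataset}), \code{corrected} (baseline-corrected
#'   input), \code{reference} (index), \code{segments} (reference
#'   segment table), \code{sample_segments} (per-sample shift/TPC/outlier
#'   table), \code{peaks_original}, \code{peaks_aligned},
#'   \code{results} (per-sample \code{alignment_result}s),
#'   \code{params}, \code{call}.
#' @seealso \code{\link{summary.atsa}}, \code{\link{coef.atsa}},
#'   \code{\link{plot.atsa}}, \code{\link{correlation_report}},
#'   \code{\link{area_rd_report}}
#' @examples
#' sim <- synth_generate(synth_spec(n_samples = 4, n_channels = 3000,
#'                                  n_peaks = 30, drift_amplitude = 10),
#'                       seed = 7)
#' fit <- atsa(sim$dataset)
#' fit
#' head(coef(fit))
#' @export
atsa <- function(x, segment_min = 3.0, shift_min = 0.5,
                 reference = "auto", precise = TRUE, baseline = TRUE,
                 z_cut = 2.5, outlier_threshold = 2.5,
                 scales = c(1, 2, 3, 5, 8, 12, 16), min_ridge_len = 3L,
                 snr_min = 3, sampling_interval = NULL) {
  cl <- match.call()
  ds <- if (inherits(x, "chrom_dataset")) x else {
    if (is.null(sampling_interval))
      stop_atsa("sampling_interval required for matrix input")
    dataset_from_matrix(x, sampling_interval)
  }
  ns <- length(ds$chromatograms)
  if (ns < 2L) stop_atsa("need at least 2 samples")

  corrected <- ds
  if (baseline)
    corrected$chromatograms <- lapply(ds$chromatograms, function(ch)
      correct_baseline(ch, z_cut = z_cut)$corrected)

  peak_tabs <- lapply(corrected$chromatograms, detect_peaks, scales = scales,
                      min_ridge_len = min_ridge_len, snr_min = snr_min)

  ref_idx <- if (identical(reference, "auto")) select_reference(corrected)
             else as.integer(reference)
  ref <- corrected$chromatograms[[ref_idx]]
  ref_peaks <- peak_tabs[[ref_idx]]
  if (nrow(ref_peaks) < 3L) stop_atsa("reference has fewer than 3 peaks")
  n <- length(ref$intensities)
  segments <- partition_segments(ref_peaks, segment_min, axis_len = n)

  results <- vector("list", ns)
  aligned <- corrected
  for (s in seq_len(ns)) {
    if (s == ref_idx) next
    res <- preliminary_align(ref, ref_peaks, corrected$chromatograms[[s]],
                             peak_tabs[[s]], init_size_min = segment_min,
                             shift_estimate_min = shift_min,
                             outlier_threshold = outlier_threshold,
                             segments = segments)
    if (precise) res <- precise_align(res, ref_peaks)
    results[[s]] <- res
    aligned$chromatograms[[s]] <- res$chromatogram
  }
  aligned$reference <- ref_idx

  ids <- sample_ids(ds)
  seg_tabs <- lapply(seq_len(ns), function(s) {
    if (s == ref_idx) return(NULL)
    st <- results[[s]]$segments
    cbind(sample_id = ids[s], st[, c("index", "shift", "tpc", "d_score", "outlier")])
  })
  peaks_aligned <- lapply(seq_len(ns), function(s)
    if (s == ref_idx) peak_tabs[[s]] else results[[s]]$peaks)

  structure(list(aligned = aligned, corrected = corrected,
                 reference = ref_idx, segments = segments,
                 sample_segments = do.call(rbind, seg_tabs),
                 peaks_original = do.call(rbind, peak_tabs),
                 peaks_aligned = do.call(rbind, peaks_aligned),
                 results = results,
                 params = list(segment_min = segment_min, shift_min = shift_min,
                               precise = precise, baseline = baseline,
                               z_cut = z_cut,
                               outlier_threshold = outlier_threshold,
                               scales = scales, min_ridge_len = min_ridge_len,
                               snr_min = snr_min),
                 call = cl),
            class = "atsa")
}

#' @export
print.atsa <- function(x, ...) {
  ns <- length(x$aligned$chromatograms)
  cat("Automatic time-shift alignment\n")
  cat(sprintf("  %d samples x %d channels; reference: sample %d ('%s')\n",
              ns, length(x$aligned$chromatograms[[1]]$intensities),
              x$reference, x$aligned$chromatograms[[x$reference]]$sample_id))
  cat(sprintf("  %d reference segments (init %g min, shift window %g min)\n",
              nrow(x$segments), x$params$segment_min, x$params$shift_min))
  if (!is.null(x$sample_segments))
    cat(sprintf("  segment shifts: median %g, range [%d, %d] channels; %d outlier repair(s)\n",
                stats::median(x$sample_segments$shift),
                min(x$sample_segments$shift), max(x$sample_segments$shift),
                sum(x$sample_segments$outlier)))
  cat(sprintf("  stages: baseline %s, preliminary, precise %s\n",
              if (x$params$baseline) "on" else "off",
              if (x$params$precise) "on" else "off"))
  invisible(x)
}

#' Summarise an ATSA fit
#'
#' @param object an \code{"atsa"} fit.
#' @param threshold pass threshold on the correlation to the reference.
#' @param ... unused.
#' @return object of class \code{"summary.atsa"} with before/after
#'   correlation tables and the RD\% area-preservation summary.
#' @export
summary.atsa <- function(object, threshold = 0.95, ...) {
  before <- correlation_report(object$corrected, object$reference, threshold)
  after <- correlation_report(object$aligned, object$reference, threshold)
  rd <- area_rd_report(object$peaks_original, object$peaks_aligned)
  structure(list(before = before, after = after, rd = rd,
                 reference = object$reference, threshold = threshold),
            class = "summary.atsa")
}

#' @export
print.summary.atsa <- function(x, ...) {
  other <- setdiff(seq_len(nrow(x$before)), x$reference)
  cat("ATSA alignment summary\n")
  cat(sprintf("  correlation to reference (n = %d test samples):\n", length(other)))
  cat(sprintf("    before: median %.4f (min %.4f), %d below %.2f\n",
              stats::median(x$before$r[other]), min(x$before$r[other]),
              sum(!x$before$pass[other]), x$threshold))
  cat(sprintf("    after : median %.4f (min %.4f), %d below %.2f\n",
              stats::median(x$after$r[other]), min(x$after$r[other]),
              sum(!x$after$pass[other]), x$threshold))
  s <- x$rd$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  |RD%%| <= %2d: %5.1f%% of peaks, %5.1f%% of total area\n",
                s$threshold[i], 100 * s$frac_peaks[i], 100 * s$frac_area[i]))
  invisible(x)
}

#' Segment shifts of an ATSA fit
#'
#' @param object an \code{"atsa"} fit.
#' @param ... unused.
#' @return samples x segments integer matrix of preliminary segment
#'   shifts, in elution channels (reference row omitted).
#' @export
coef.atsa <- function(object, ...) {
  ss <- object$sample_segments
  if (is.null(ss)) return(NULL)
  ids <- unique(ss$sample_id)
  k <- max(ss$index)
  m <- matrix(NA_integer_, length(ids), k,
              dimnames = list(ids, paste0("seg", seq_len(k))))
  m[cbind(match(ss$sample_id, ids), ss$index)] <- ss$shift
  m
}

#' Overlay plot of an elution window before and after alignment
#'
#' @param x an \code{"atsa"} fit.
#' @param from,to elution window to draw, minutes (defaults to a window
#'   around the densest peak region).
#' @param ... passed to \code{matplot}.
#' @export
plot.atsa <- function(x, from = NULL, to = NULL, ...) {
  ref <- x$aligned$chromatograms[[x$reference]]
  n <- length(ref$intensities)
  if (is.null(from)) {
    mid <- channel_time(ref, x$segments$ref_start[ceiling(nrow(x$segments) / 2)])
    from <- mid; to <- mid + 2
  }
  c1 <- max(0L, time_channel(ref, from)); c2 <- min(n - 1L, time_channel(ref, to))
  tt <- channel_time(ref, c1:c2)
  mb <- t(vapply(x$corrected$chromatograms,
                 function(ch) ch_slice(ch$intensities, c1, c2),
                 numeric(c2 - c1 + 1L)))
  ma <- t(vapply(x$aligned$chromatograms,
                 function(ch) ch_slice(ch$intensities, c1, c2),
                 numeric(c2 - c1 + 1L)))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tt, t(mb), type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    xlab = "retention time (min)", ylab = "intensity",
                    main = "before alignment", ...)
  graphics::matplot(tt, t(ma), type = "l", lty = 1,
                    col = grDevices::adjustcolor("firebrick", 0.5),
                    xlab = "retention time (min)", ylab = "intensity",
                    main = "after alignment", ...)
  invisible(x)
}
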
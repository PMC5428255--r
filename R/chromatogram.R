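#' Construct a chromatogram
#'
#' A chromatogram is a uniformly sampled one-dimensional detector trace
#' (e.g. GC-FID or a single HPLC channel). Elution channels are 0-based
#' integers; channel \code{k} elutes at
#' \code{start_time + k * sampling_interval} minutes.
#'
#' @param intensities numeric vector of detector intensities (length >= 2).
#' @param sampling_interval minutes per elution channel (> 0).
#' @param start_time retention time of channel 0, minutes.
#' @param sample_id sample label.
#' @return An object of class \code{"chromatogram"}.
#' @examples
#' ch <- chromatogram(dnorm(seq(-4, 4, length.out = 101)),
#'                    sampling_interval = 0.01, sample_id = "s1")
#' channel_time(ch, 50)
#' @export
chromatogram <- function(intensities, sampling_interval, start_time = 0,
                         sample_id = "sample") {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 2L)
    stop_atsa("a chromatogram needs at least 2 channels")
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    stop_atsa("sampling_interval must be > 0")
  structure(list(intensities = intensities,
                 start_time = as.numeric(start_time),
                 sampling_interval = as.numeric(sampling_interval),
                 sample_id = as.character(sample_id)),
            class = "chromatogram")
}

#' @export
length.chromatogram <- function(x) length(x$intensities)

#' Convert elution channels to retention times (minutes)
#'
#' @param chrom a \code{chromatogram}.
#' @param channel 0-based channel index (vectorised).
#' @return retention times in minutes.
#' @export
channel_time <- function(chrom, channel) {
  chrom$start_time + channel * chrom$sampling_interval
}

#' Convert retention times (minutes) to the nearest elution channel
#'
#' @param chrom a \code{chromatogram}.
#' @param time retention time in minutes (vectorised).
#' @return 0-based integer channel indices.
#' @export
time_channel <- function(chrom, time) {
  as.integer(round_half_up((time - chrom$start_time) / chrom$sampling_interval))
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram '%s': %d channels, %.4g-%.4g min, dt = %.4g min>\n",
              x$sample_id, length(x$intensities), x$start_time,
              channel_time(x, length(x$intensities) - 1L), x$sampling_interval))
  invisible(x)
}

#' Bundle chromatograms sharing one time axis
#'
#' @param chromatograms list of \code{chromatogram} objects with identical
#'   length, start time and sampling interval.
#' @param reference optional 1-based index of the reference sample.
#' @return An object of class \code{"chrom_dataset"}.
#' @export
chrom_dataset <- function(chromatograms, reference = NA_integer_) {
  if (!length(chromatograms)) stop_atsa("empty dataset")
  ok <- vapply(chromatograms, inherits, logical(1), "chromatogram")
  if (!all(ok)) stop_atsa("all members must be chromatograms")
  n <- vapply(chromatograms, function(c) length(c$intensities), integer(1))
  t0 <- vapply(chromatograms, `[[`, numeric(1), "start_time")
  dt <- vapply(chromatograms, `[[`, numeric(1), "sampling_interval")
  if (length(unique(n)) != 1L || diff(range(t0)) > 1e-9 || diff(range(dt)) > 1e-12)
    stop_atsa("all chromatograms must share length, start_time and sampling_interval")
  structure(list(chromatograms = chromatograms,
                 reference = as.integer(reference)),
            class = "chrom_dataset")
}

#' @export
length.chrom_dataset <- function(x) length(x$chromatograms)

#' @export
print.chrom_dataset <- function(x, ...) {
  cat(sprintf("<chrom_dataset: %d samples x %d channels%s>\n",
              length(x$chromatograms), length(x$chromatograms[[1]]$intensities),
              if (is.na(x$reference)) "" else sprintf(", reference = %d", x$reference)))
  invisible(x)
}

#' @export
as.matrix.chrom_dataset <- function(x, ...) {
  m <- do.call(rbind, lapply(x$chromatograms, `[[`, "intensities"))
  rownames(m) <- vapply(x$chromatograms, `[[`, character(1), "sample_id")
  m
}

#' Build a dataset from an intensity matrix
#'
#' @param m numeric matrix, one row per sample, one column per channel.
#' @param sampling_interval minutes per channel.
#' @param start_time retention time of channel 0, minutes.
#' @param sample_ids row labels; defaults to rownames or S1..Sn.
#' @return a \code{chrom_dataset}.
#' @export
dataset_from_matrix <- function(m, sampling_interval, start_time = 0,
                                sample_ids = NULL) {
  m <- as.matrix(m)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(m)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  }
  chrom_dataset(lapply(seq_len(nrow(m)), function(i)
    chromatogram(m[i, ], sampling_interval, start_time, sample_ids[i])))
}

sample_ids <- function(ds) vapply(ds$chromatograms, `[[`, character(1), "sample_id")
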
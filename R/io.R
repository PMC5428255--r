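#' Read chromatograms from a plain-text matrix file
#'
#' Two dialects are supported. \code{"wide"}: a CSV whose first column is
#' \code{sample_id} and whose remaining column headers are retention times
#' in minutes, one row per sample. \code{"long"}: a CSV with columns
#' \code{sample_id,time_min,intensity}, samples stacked.
#'
#' Time axes are required to be monotone increasing. A non-uniform axis is
#' resampled by linear interpolation onto a uniform grid spanning the same
#' range with the same number of points, with a warning.
#'
#' @param path file to read.
#' @param dialect \code{"wide"} or \code{"long"}.
#' @return a \code{\link{chrom_dataset}}.
#' @export
read_chromatograms <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_atsa("file not found: ", path)
  if (dialect == "wide") read_wide(path) else read_long(path)
}

uniform_axis <- function(times, what) {
  n <- length(times)
  if (n < 2L) stop_atsa(what, ": need at least 2 time points")
  d <- diff(times)
  if (any(d <= 0)) stop_atsa(what, ": time axis is not strictly increasing")
  dt <- (times[n] - times[1]) / (n - 1)
  if (max(abs(d - dt)) <= 1e-6 * max(dt, 1e-12))
    return(list(grid = times, dt = dt, resampled = FALSE))
  list(grid = seq(times[1], times[n], length.out = n), dt = dt, resampled = TRUE)
}

read_wide <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_atsa("wide matrix needs a header and >= 1 sample row")
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  times <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(times)) stop_atsa("wide header must contain numeric times after sample_id")
  ax <- uniform_axis(times, "wide matrix header")
  if (ax$resampled) warning("non-uniform time axis; resampling onto a uniform grid")
  n <- length(times)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(rows) != n + 1L)
  if (length(bad))
    stop_atsa("ragged row(s) in wide matrix: line ", bad[1] + 1L)
  chroms <- lapply(rows, function(r) {
    y <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(y)) stop_atsa("non-numeric intensity in wide matrix")
    if (ax$resampled) y <- stats::approx(times, y, xout = ax$grid)$y
    chromatogram(y, sampling_interval = ax$dt, start_time = ax$grid[1],
                 sample_id = r[1])
  })
  chrom_dataset(chroms)
}

read_long <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_min", "intensity")
  if (!all(need %in% names(d)))
    stop_atsa("long format needs columns sample_id,time_min,intensity")
  ids <- unique(d$sample_id)
  parts <- split(d, factor(d$sample_id, levels = ids))
  nper <- unique(vapply(parts, nrow, integer(1)))
  if (length(nper) != 1L)
    stop_atsa("all samples in a long file must have the same number of points")
  # common grid taken from the pooled time range
  t1 <- max(vapply(parts, function(p) p$time_min[1], numeric(1)))
  t2 <- min(vapply(parts, function(p) p$time_min[nper], numeric(1)))
  any_res <- FALSE
  grids <- lapply(parts, function(p) uniform_axis(p$time_min, "long time column"))
  any_res <- any(vapply(grids, `[[`, logical(1), "resampled"))
  grid <- seq(t1, t2, length.out = nper)
  uniform_all <- !any_res &&
    all(vapply(parts, function(p) max(abs(p$time_min - grid)) <= 1e-9, logical(1)))
  if (!uniform_all && (any_res ||
      any(vapply(parts, function(p) max(abs(p$time_min - grid)) > 1e-9, logical(1)))))
    warning("non-uniform or non-shared time axis; resampling onto a uniform grid")
  chroms <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    y <- if (uniform_all) p$intensity else
      stats::approx(p$time_min, p$intensity, xout = grid, rule = 2)$y
    chromatogram(y, sampling_interval = grid[2] - grid[1], start_time = grid[1],
                 sample_id = ids[i])
  })
  chrom_dataset(chroms)
}

#' Write chromatograms to a plain-text matrix file
#'
#' Inverse of \code{\link{read_chromatograms}}; round-trips intensities to
#' near machine precision.
#'
#' @param ds a \code{chrom_dataset}.
#' @param path output file.
#' @param dialect \code{"wide"} or \code{"long"}.
#' @export
write_chromatograms <- function(ds, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!inherits(ds, "chrom_dataset")) stop_atsa("ds must be a chrom_dataset")
  c1 <- ds$chromatograms[[1]]
  times <- channel_time(c1, seq_len(length(c1$intensities)) - 1L)
  ids <- sample_ids(ds)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_atsa("cannot open for writing: ", path)
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  if (dialect == "wide") {
    writeLines(paste(c("sample_id", fmt(times)), collapse = ","), con)
    for (i in seq_along(ds$chromatograms))
      writeLines(paste(c(ids[i], fmt(ds$chromatograms[[i]]$intensities)),
                       collapse = ","), con)
  } else {
    writeLines("sample_id,time_min,intensity", con)
    for (i in seq_along(ds$chromatograms))
      writeLines(paste(ids[i], fmt(times),
                       fmt(ds$chromatograms[[i]]$intensities), sep = ","), con)
  }
  invisible(path)
}
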
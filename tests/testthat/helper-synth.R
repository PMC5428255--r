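# Shared fixtures built in code.

# Sum-of-Gaussians signal on a 0-based channel axis.
gauss_signal <- function(n, centers, heights, sigmas) {
  y <- numeric(n)
  k <- 0:(n - 1)
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(k - centers[i])^2 / (2 * sigmas[i]^2))
  y
}

# Hand-built peak table from known apex/width (channels).
peak_tab <- function(centers, heights, sigmas, id = "s",
                     sampling_interval = 0.01) {
  o <- order(centers)
  centers <- centers[o]; heights <- heights[o]; sigmas <- sigmas[o]
  data.frame(sample_id = id, peak_id = paste0(id, "_p", seq_along(centers)),
             apex_channel = as.integer(centers),
             rt_min = centers * sampling_interval,
             start_channel = as.integer(centers - round(3 * sigmas)),
             end_channel = as.integer(centers + round(3 * sigmas)),
             height = heights, area = heights * sigmas * sqrt(2 * pi),
             stringsAsFactors = FALSE)
}

# Small-but-structured synthetic study used by several files:
# 6 samples x 4000 channels, 35 peaks, modest drift/noise.
small_sim <- function(seed = 11) {
  synth_generate(synth_spec(n_samples = 6, n_channels = 4000, n_peaks = 35,
                            drift_amplitude = 15, height_range = c(30, 800)),
                 seed = seed)
}
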
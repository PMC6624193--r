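# Shared fixtures: small, fast study configurations and analytic traces.
# Everything is generated in code; no stored data.

# Compact crawl recording: 3 segments, one full posterior->anterior wave.
small_crawl_config <- function(...) {
  defaults <- list(mode = "crawl", n_segments = 3, rest_segment_length = 50,
                   duration = 5, wave_start = 1, wave_period = 20,
                   cell_types = "ddaE", noise_sd = 0,
                   intensity_modulation_amplitude = 0, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

render_crawl <- function(cfg) {
  truth <- simulate_calcium(simulate_crawl_kinematics(cfg), cfg)
  list(truth = truth, movie = render_movie(truth, cfg))
}

# Analytic distance trace: resting plateau, one symmetric Gaussian dip.
gaussian_dip_trace <- function(rest = 100, depth = 30, sigma = 0.5,
                               rate = 10, duration = 10, center = 5) {
  tt <- seq(0, duration, by = 1 / rate)
  d <- rest - depth * exp(-(tt - center)^2 / (2 * sigma^2))
  distance_trace(tt, d, pair_id = "gauss", resting_length_um = rest)
}

# Triangular dip 100 -> 60 -> 100 um over 2 s, embedded in a plateau.
triangle_dip_trace <- function(rate = 10) {
  tt <- seq(0, 8, by = 1 / rate)
  d <- rep(100, length(tt))
  ramp <- seq(100, 60, length.out = 11)            # 1 s down at 10 VPS
  i0 <- which(tt == 3)
  d[i0:(i0 + 10)] <- ramp
  d[(i0 + 10):(i0 + 20)] <- rev(ramp)
  distance_trace(tt, d, pair_id = "triangle", resting_length_um = 100)
}

# Minimal activity trace in the ratio_trace contract (for event alignment
# without the imaging stages).
activity_trace <- function(time_s, dRR0) {
  out <- data.frame(time_s = time_s, dRR0 = dRR0, defined = TRUE)
  class(out) <- c("ratio_trace", "data.frame")
  out
}

# Aligned-event stub on the standard grid (for phase/half-max unit tests).
aligned_stub <- function(dRR0, grid_au = seq(-3, 3, by = 0.05)) {
  structure(list(grid_au = grid_au, distance_um = rep(100, length(grid_au)),
                 dRR0 = dRR0, dRR0_norm = dRR0 / max(dRR0),
                 fwhm_s = 1, t_max_contraction_s = 0, pair_id = "stub",
                 truncated = FALSE),
            class = "aligned_event")
}
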
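#' Simulation configuration for synthetic larvae
#'
#' Collects every knob of the ground-truthed generator. Defaults describe
#' the imaging and physiology regime the pipeline is built for: 10 volumes/s
#' sampling, a fast indicator decay (~0.4 s, GCaMP6f-like), segment rest
#' length of order 80 um in a second-instar larva, a posterior-to-anterior
#' peristaltic wave whose per-segment contraction transient has a FWHM
#' (2.355 * `wave_sigma` = 0.94 s) inside the observed 0.7-2.5 s range, and
#' a ~10% motion-induced intensity modulation common to both channels.
#'
#' @param mode `"crawl"` (peristaltic wave) or `"explore"` (head turning +
#'   retraction).
#' @param n_segments number of body segments simulated.
#' @param rest_segment_length segment rest length L0, micrometers.
#' @param halfwidth half body width p (left/right cells at y-axis +/- p),
#'   micrometers.
#' @param wave_amplitude peak fractional shortening A of a segment in
#'   `[0, 1)`.
#' @param wave_sigma temporal sigma of the per-segment Gaussian contraction
#'   transient, seconds.
#' @param wave_period time between successive peristaltic waves, seconds.
#' @param wave_speed wave propagation speed, segments per second (onset
#'   times advance anteriorly by `1/wave_speed`).
#' @param wave_start onset time of the most posterior segment's first
#'   contraction, seconds.
#' @param volume_rate volumetric sampling rate, volumes per second.
#' @param calcium_decay_tau indicator decay time constant, seconds.
#' @param calcium_gain dimensionless gain from fractional deformation drive
#'   to calcium.
#' @param cell_radius Gaussian sd of a rendered soma, micrometers.
#' @param red_brightness peak red (static) intensity of a soma, a.u.
#' @param green_baseline peak green intensity at zero calcium, a.u.
#' @param noise_sd additive Gaussian read-noise sd, a.u.
#' @param intensity_modulation_amplitude amplitude of the common sinusoidal
#'   intensity modulation (fraction of 1).
#' @param modulation_freq frequency of that modulation, Hz.
#' @param voxel_spacing voxel spacing `(z, y, x)`, micrometers.
#' @param duration recording length, seconds.
#' @param seed integer root seed; identical config + seed gives
#'   bit-identical outputs.
#' @param cell_types cell types placed in every hemisegment (crawl mode);
#'   any of `"vpda"`, `"ddaD"`, `"ddaE"`, `"dbd"`, `"vbd"`, `"dmd1"`,
#'   `"generic"`. `"dbd"` is stretch-sensing, all others contraction-sensing.
#' @param type_delays named numeric, per-type activation onset delay in
#'   seconds (emulates sequential activation; default none).
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise with
#'   variance equal to the noise-free intensity, scaled to `noise_sd` at the
#'   red soma peak).
#' @param explore_theta_max_deg peak turning angle, degrees (explore mode).
#' @param explore_theta_periods two sinusoid periods composing theta(t), s.
#' @param explore_s0 resting midpoint separation S0, micrometers.
#' @param explore_s_amplitude fractional depth of retraction in `[0, 1)`.
#' @param explore_s_period retraction period, seconds.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(mode = c("crawl", "explore"),
                       n_segments = 6,
                       rest_segment_length = 80,
                       halfwidth = 25,
                       wave_amplitude = 0.35,
                       wave_sigma = 0.4,
                       wave_period = 12,
                       wave_speed = 1,
                       wave_start = 1.5,
                       volume_rate = 10,
                       calcium_decay_tau = 0.4,
                       calcium_gain = 5,
                       cell_radius = 4,
                       red_brightness = 100,
                       green_baseline = 50,
                       noise_sd = 5,
                       intensity_modulation_amplitude = 0.1,
                       modulation_freq = 0.5,
                       voxel_spacing = c(2, 2, 2),
                       duration = 10,
                       seed = 1,
                       cell_types = "ddaE",
                       type_delays = NULL,
                       noise_model = c("gaussian", "poisson"),
                       explore_theta_max_deg = 25,
                       explore_theta_periods = c(4, 2.7),
                       explore_s0 = 100,
                       explore_s_amplitude = 0.3,
                       explore_s_period = 5) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  cfg <- list(mode = mode, n_segments = as.integer(n_segments),
              rest_segment_length = rest_segment_length,
              halfwidth = halfwidth, wave_amplitude = wave_amplitude,
              wave_sigma = wave_sigma, wave_period = wave_period,
              wave_speed = wave_speed, wave_start = wave_start,
              volume_rate = volume_rate,
              calcium_decay_tau = calcium_decay_tau,
              calcium_gain = calcium_gain, cell_radius = cell_radius,
              red_brightness = red_brightness,
              green_baseline = green_baseline, noise_sd = noise_sd,
              intensity_modulation_amplitude = intensity_modulation_amplitude,
              modulation_freq = modulation_freq,
              voxel_spacing = as.numeric(voxel_spacing),
              duration = duration, seed = as.integer(seed),
              cell_types = cell_types, type_delays = type_delays,
              noise_model = noise_model,
              explore_theta_max_deg = explore_theta_max_deg,
              explore_theta_periods = explore_theta_periods,
              explore_s0 = explore_s0,
              explore_s_amplitude = explore_s_amplitude,
              explore_s_period = explore_s_period)
  if (cfg$wave_amplitude < 0 || cfg$wave_amplitude >= 1)
    stop("`wave_amplitude` must lie in [0, 1)")
  pos_fields <- c("n_segments", "rest_segment_length", "halfwidth",
                  "wave_sigma", "wave_period", "wave_speed", "volume_rate",
                  "calcium_decay_tau", "cell_radius", "red_brightness",
                  "green_baseline", "duration", "explore_s0",
                  "explore_s_period")
  for (f in pos_fields)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
      stop("`", f, "` must be strictly positive")
  if (any(cfg$voxel_spacing <= 0)) stop("`voxel_spacing` must be positive")
  if (cfg$noise_sd < 0 || cfg$calcium_gain < 0)
    stop("`noise_sd` and `calcium_gain` must be >= 0")
  if (cfg$intensity_modulation_amplitude < 0 ||
      cfg$intensity_modulation_amplitude >= 1)
    stop("`intensity_modulation_amplitude` must lie in [0, 1)")
  if (cfg$explore_s_amplitude < 0 || cfg$explore_s_amplitude >= 1)
    stop("`explore_s_amplitude` must lie in [0, 1)")
  known <- c("vpda", "ddaD", "ddaE", "dbd", "vbd", "dmd1", "generic")
  if (!all(cfg$cell_types %in% known))
    stop("unknown cell type(s): ",
         paste(setdiff(cfg$cell_types, known), collapse = ", "))
  structure(cfg, class = "sim_config")
}

# Spatial offsets (dz, dy) um distinguishing co-segmental cell types so that
# rendered somata do not overlap; ddaD sits anterior to ddaE, dmd1/dbd deeper.
type_offsets <- function(type) {
  switch(type,
         ddaE = c(0, 0), ddaD = c(0, 12), dmd1 = c(10, 4), dbd = c(10, -6),
         vbd = c(-10, 4), vpda = c(-10, -6), generic = c(0, 0),
         stop("unknown type ", type))
}

is_stretch_sensing <- function(type) type == "dbd"

sim_times <- function(config) {
  seq(0, config$duration, by = 1 / config$volume_rate)
}

modulation_factor <- function(config, time_s) {
  1 + config$intensity_modulation_amplitude *
    sin(2 * pi * config$modulation_freq * time_s)
}

# margin (um) between any cell center and the rendered volume edge
render_margin <- function(config) 4 * config$cell_radius + 2

#' Simulate crawl-mode kinematics
#'
#' Generates a posterior-to-anterior peristaltic wave over a chain of
#' segments. Segment `i` (1 = most posterior) has length
#' `L_i(t) = L0 * (1 - A * sum_k exp(-(t - t_ik)^2 / (2 sigma^2)))` with
#' onset times advancing anteriorly by `1/wave_speed` and repeating every
#' `wave_period`. Cell y positions are cumulative sums of segment lengths
#' from the fixed posterior end, so the inter-cell distance between a cell
#' and its posterior homolog equals its segment length exactly. Homologous
#' left/right cells sit at the body axis +/- `halfwidth`.
#'
#' @param config a [sim_config()] with `mode = "crawl"`.
#' @return An object of class `larva_truth`: list with `config`, `time_s`,
#'   `cells` (data.frame `cell_id`, `cell_type`, `segment`, `side`),
#'   `positions` (`n_cells x n_time x 3` array, x/y/z um),
#'   `segment_lengths` (`n_segments x n_time`, um), `modulation`
#'   (per-timepoint common intensity factor), `calcium` (`NULL` until
#'   [simulate_calcium()]), and `pose` (`NULL` in crawl mode).
#' @export
simulate_crawl_kinematics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "crawl") stop("config mode must be 'crawl'")
  tt <- sim_times(config)
  nt <- length(tt)
  ns <- config$n_segments
  L0 <- config$rest_segment_length
  A <- config$wave_amplitude
  sig <- config$wave_sigma

  onsets0 <- config$wave_start + (seq_len(ns) - 1) / config$wave_speed
  n_waves <- max(1L, ceiling((config$duration + 6 * sig) / config$wave_period))
  seg_len <- matrix(L0, ns, nt)
  for (i in seq_len(ns)) {
    dip <- rep(0, nt)
    for (w in seq_len(n_waves) - 1L) {
      t0 <- onsets0[i] + w * config$wave_period
      dip <- dip + exp(-(tt - t0)^2 / (2 * sig^2))
    }
    seg_len[i, ] <- L0 * (1 - A * dip)
  }
  if (any(seg_len <= 0))
    stop("wave parameters imply non-positive segment lengths ",
         "(overlapping waves); reduce wave_amplitude or spread onsets")

  margin <- render_margin(config)
  y_tail <- margin
  bounds <- apply(seg_len, 2, cumsum)           # ns x nt, anterior boundaries
  if (ns == 1L) bounds <- matrix(bounds, 1, nt)
  x_mid <- margin + config$halfwidth
  z_mid <- margin + 12                          # head-room for type z offsets

  cells <- expand.grid(cell_type = config$cell_types,
                       segment = seq_len(ns),
                       side = c("L", "R"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$segment, cells$cell_type, cells$side), ]
  cells$cell_id <- sprintf("%s_S%d_%s", cells$cell_type, cells$segment,
                           cells$side)
  cells <- cells[, c("cell_id", "cell_type", "segment", "side")]
  rownames(cells) <- NULL

  pos <- array(NA_real_, dim = c(nrow(cells), nt, 3),
               dimnames = list(cells$cell_id, NULL, c("x", "y", "z")))
  for (j in seq_len(nrow(cells))) {
    off <- type_offsets(cells$cell_type[j])
    pos[j, , 1] <- x_mid + if (cells$side[j] == "L") -config$halfwidth else
      config$halfwidth
    pos[j, , 2] <- y_tail + bounds[cells$segment[j], ] + off[2]
    pos[j, , 3] <- z_mid + off[1]
  }

  structure(list(config = config, time_s = tt, cells = cells,
                 positions = pos, segment_lengths = seg_len,
                 modulation = modulation_factor(config, tt),
                 calcium = NULL, pose = NULL),
            class = "larva_truth")
}

#' Simulate explore-mode kinematics
#'
#' Generates smooth turning `theta(t)` (sum of two low-frequency sinusoids
#' with seeded phases, peak `explore_theta_max_deg`) and a smooth, strictly
#' positive retraction trace `S(t)`, and emits the four corner cells D1L,
#' D1R, D2L, D2R of the two-bar model via [pose_to_positions()] at every
#' timepoint, embedded in the volume's x-y plane at mid depth.
#'
#' @param config a [sim_config()] with `mode = "explore"`.
#' @return A `larva_truth` whose `pose` field is a data.frame
#'   `(time_s, S_um, theta_rad)`; `segment_lengths` is `NULL`.
#' @export
simulate_explore_kinematics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "explore") stop("config mode must be 'explore'")
  tt <- sim_times(config)
  nt <- length(tt)
  set.seed(config$seed + 1L)
  ph <- stats::runif(3, 0, 2 * pi)
  th_max <- config$explore_theta_max_deg * pi / 180
  theta <- th_max * (0.7 * sin(2 * pi * tt / config$explore_theta_periods[1] + ph[1]) +
                     0.3 * sin(2 * pi * tt / config$explore_theta_periods[2] + ph[2]))
  S <- config$explore_s0 *
    (1 - config$explore_s_amplitude *
       (0.5 + 0.5 * sin(2 * pi * tt / config$explore_s_period + ph[3])))
  if (any(S <= 0)) stop("retraction parameters drive S(t) <= 0")

  margin <- render_margin(config)
  p <- config$halfwidth
  ext <- config$explore_s0 + p       # generous in-plane extent of the head
  x_mid <- margin + ext
  y_mid <- margin + ext
  z_mid <- margin

  cells <- data.frame(cell_id = c("D1L", "D1R", "D2L", "D2R"),
                      cell_type = "ddaD",
                      segment = c(1L, 1L, 2L, 2L),
                      side = c("L", "R", "L", "R"),
                      stringsAsFactors = FALSE)
  pos <- array(NA_real_, dim = c(4, nt, 3),
               dimnames = list(cells$cell_id, NULL, c("x", "y", "z")))
  for (k in seq_len(nt)) {
    pose <- pose_to_positions(p, S[k], theta[k])
    pos[, k, 1] <- x_mid + pose$corners[, "x"]
    pos[, k, 2] <- y_mid + pose$corners[, "y"]
    pos[, k, 3] <- z_mid
  }
  # translate so the rendered volume is snug: min position = margin per axis
  for (ax in 1:3) pos[, , ax] <- pos[, , ax] - min(pos[, , ax]) + margin
  structure(list(config = config, time_s = tt, cells = cells,
                 positions = pos, segment_lengths = NULL,
                 modulation = modulation_factor(config, tt),
                 calcium = NULL,
                 pose = data.frame(time_s = tt, S_um = S, theta_rad = theta)),
            class = "larva_truth")
}

#' Simulate deformation-driven calcium dynamics
#'
#' Each cell's calcium follows first-order kinetics
#' `dc/dt = gain * u(t) - c / tau`, integrated exactly under a
#' zero-order-hold of the drive at the volume rate, so the homogeneous
#' decay and step-response closed forms hold to machine precision at the
#' sample times. The drive `u` is the rectified fractional deformation of
#' the cell's segment: `max(0, (L_rest - L)/L_rest)` for
#' contraction-sensing types and `max(0, (L - L_rest)/L_rest)` for the
#' stretch-sensing type (dbd). In explore mode the drive is the rectified
#' fractional shortening of the cell's ipsilateral D1-D2 distance relative
#' to the resting separation. Per-type onset delays (`type_delays`) shift
#' the drive in time to emulate sequential activation.
#'
#' @param truth a `larva_truth` from one of the kinematics simulators.
#' @param config the same [sim_config()].
#' @return The `larva_truth` with a `calcium` matrix
#'   (`n_cells x n_time`, dimensionless, >= 0) filled in.
#' @export
simulate_calcium <- function(truth, config) {
  stopifnot(inherits(truth, "larva_truth"))
  if (is.null(truth$positions)) stop("kinematics missing")
  tt <- truth$time_s
  nt <- length(tt)
  dt <- 1 / config$volume_rate
  tau <- config$calcium_decay_tau
  decay <- exp(-dt / tau)
  gain <- config$calcium_gain

  drive_of <- function(L, L_rest, stretch) {
    if (stretch) pmax(0, (L - L_rest) / L_rest) else
      pmax(0, (L_rest - L) / L_rest)
  }
  ca <- matrix(0, nrow(truth$cells), nt,
               dimnames = list(truth$cells$cell_id, NULL))
  for (j in seq_len(nrow(truth$cells))) {
    type <- truth$cells$cell_type[j]
    if (config$mode == "crawl") {
      L <- truth$segment_lengths[truth$cells$segment[j], ]
      L_rest <- config$rest_segment_length
    } else {
      side <- truth$cells$side[j]
      iD1 <- match(paste0("D1", side), truth$cells$cell_id)
      iD2 <- match(paste0("D2", side), truth$cells$cell_id)
      L <- sqrt(rowSums((truth$positions[iD1, , ] -
                         truth$positions[iD2, , ])^2))
      L_rest <- config$explore_s0
    }
    u <- drive_of(L, L_rest, is_stretch_sensing(type))
    delay <- 0
    if (!is.null(config$type_delays) && type %in% names(config$type_delays))
      delay <- config$type_delays[[type]]
    if (delay != 0)
      u <- stats::approx(tt, u, xout = tt - delay, rule = 2)$y
    cvec <- numeric(nt)
    for (k in seq_len(nt - 1))
      cvec[k + 1] <- cvec[k] * decay + gain * u[k] * tau * (1 - decay)
    ca[j, ] <- cvec
  }
  truth$calcium <- ca
  truth
}

#' Render a ground-truthed two-channel movie
#'
#' Renders each cell as an isotropic 3D Gaussian of sd `cell_radius` sampled
#' at voxel centers. Red intensity peaks at `red_brightness` (static); green
#' peaks at `green_baseline * (1 + calcium)`. Both channels are multiplied
#' by the common motion-induced modulation
#' `m(t) = 1 + intensity_modulation_amplitude * sin(2 pi f t)`, then
#' Gaussian read noise of sd `noise_sd` is added (or Poisson shot noise if
#' configured) and intensities are clipped at 0.
#'
#' @param truth a `larva_truth` with calcium present (run
#'   [simulate_calcium()] first; for a calcium-free render set
#'   `calcium_gain = 0`).
#' @param config the same [sim_config()].
#' @param dims optional volume shape `(z, y, x)` in voxels; defaults to the
#'   smallest box containing all cell positions plus a 4-sigma margin.
#'   An explicit `dims` too small to contain the cells is an error.
#' @return A `two_channel_movie`; attribute `modulation` carries the
#'   per-timepoint common factor.
#' @export
render_movie <- function(truth, config, dims = NULL) {
  stopifnot(inherits(truth, "larva_truth"))
  if (is.null(truth$calcium)) stop("calcium missing: run simulate_calcium()")
  sp <- config$voxel_spacing                      # (z, y, x)
  pos <- truth$positions                          # (cell, t, xyz)
  margin <- render_margin(config)
  if (is.null(dims)) {
    maxs <- apply(pos, 3, max)                    # x, y, z um
    dims <- c(floor((maxs[3] + margin) / sp[1]) + 1,
              floor((maxs[2] + margin) / sp[2]) + 1,
              floor((maxs[1] + margin) / sp[3]) + 1)
  }
  dims <- as.integer(dims)
  extent <- (dims - 1) * sp                       # (z, y, x) um
  if (max(pos[, , 1]) > extent[3] || max(pos[, , 2]) > extent[2] ||
      max(pos[, , 3]) > extent[1] || min(pos) < 0)
    stop("volume too small to contain cell positions")

  nt <- length(truth$time_s)
  nc_cells <- nrow(truth$cells)
  r <- config$cell_radius
  half_w <- 4 * r
  zc <- (seq_len(dims[1]) - 1) * sp[1]
  yc <- (seq_len(dims[2]) - 1) * sp[2]
  xc <- (seq_len(dims[3]) - 1) * sp[3]
  data <- array(0, dim = c(nt, 2L, dims))

  for (k in seq_len(nt)) {
    green <- array(0, dim = dims)
    red <- array(0, dim = dims)
    for (j in seq_len(nc_cells)) {
      cx <- pos[j, k, 1]; cy <- pos[j, k, 2]; cz <- pos[j, k, 3]
      iz <- which(abs(zc - cz) <= half_w)
      iy <- which(abs(yc - cy) <= half_w)
      ix <- which(abs(xc - cx) <= half_w)
      if (!length(iz) || !length(iy) || !length(ix)) next
      gz <- exp(-(zc[iz] - cz)^2 / (2 * r^2))
      gy <- exp(-(yc[iy] - cy)^2 / (2 * r^2))
      gx <- exp(-(xc[ix] - cx)^2 / (2 * r^2))
      blob <- outer(gz, outer(gy, gx))            # (z, y, x) window
      red[iz, iy, ix] <- red[iz, iy, ix] + config$red_brightness * blob
      green[iz, iy, ix] <- green[iz, iy, ix] +
        config$green_baseline * (1 + truth$calcium[j, k]) * blob
    }
    m <- truth$modulation[k]
    data[k, 1, , , ] <- green * m
    data[k, 2, , , ] <- red * m
  }
  if (config$noise_sd > 0) {
    set.seed(config$seed + 3L)
    if (config$noise_model == "gaussian") {
      data <- data + stats::rnorm(length(data), 0, config$noise_sd)
    } else {
      # shot noise scaled so the red soma peak has sd = noise_sd
      g <- config$noise_sd^2 / config$red_brightness
      data <- array(stats::rpois(length(data), pmax(data, 0) / g) * g,
                    dim = dim(data))
    }
    data[data < 0] <- 0
  }
  movie <- two_channel_movie(data, spacing_um = sp,
                             volume_rate = config$volume_rate)
  attr(movie, "modulation") <- truth$modulation
  movie
}

#' Ground-truth positions as error-free cell tracks
#'
#' Wraps the generator's exact positions in a `cell_tracks` object, for
#' running the event and exploration analyses on noiseless kinematics
#' without the render/track stages.
#'
#' @param truth a `larva_truth`.
#' @return A `cell_tracks` with confidence `"auto"` everywhere.
#' @export
tracks_from_truth <- function(truth) {
  stopifnot(inherits(truth, "larva_truth"))
  n <- nrow(truth$cells)
  nt <- length(truth$time_s)
  conf <- matrix("auto", n, nt, dimnames = list(truth$cells$cell_id, NULL))
  new_cell_tracks(truth$cells, truth$time_s, truth$positions, conf,
                  params = list(cell_radius_um = truth$config$cell_radius,
                                t0 = 1L))
}

#' Ground-truth positions as a seeds/tracks table
#'
#' Convenience accessor: the generator's cell table with positions at one
#' timepoint, in the CSV column convention shared with the tracker.
#'
#' @param truth a `larva_truth`.
#' @param t_index 1-based volume index (default 1).
#' @return data.frame `cell_id`, `cell_type`, `segment`, `side`, `x_um`,
#'   `y_um`, `z_um`.
#' @export
truth_seeds <- function(truth, t_index = 1L) {
  data.frame(truth$cells,
             x_um = truth$positions[, t_index, 1],
             y_um = truth$positions[, t_index, 2],
             z_um = truth$positions[, t_index, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}
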
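#' Per-volume dark-floor background estimate
#'
#' The ratio R must be formed from background-subtracted intensities so that
#' the motion-induced modulation common to both channels cancels. The
#' default estimator is the mean of the voxels at or below the channel's
#' 5th percentile in that volume (a dark-region estimate robust to cell
#' motion); alternatively a user-supplied static box is averaged.
#'
#' @param movie a `two_channel_movie`.
#' @param channel `"green"` or `"red"`.
#' @param t 1-based volume index.
#' @param method `"percentile"` (default) or `"box"`.
#' @param percentile dark-voxel quantile for the percentile method.
#' @param box for `method = "box"`: list of index ranges
#'   `list(z = , y = , x = )` (1-based) averaged as background.
#' @return Scalar background, a.u.
#' @export
estimate_background <- function(movie, channel = c("green", "red"), t,
                                method = c("percentile", "box"),
                                percentile = 0.05, box = NULL) {
  stopifnot(inherits(movie, "two_channel_movie"))
  method <- match.arg(method)
  ci <- channel_index(movie, match.arg(channel))
  vol <- movie$data[t, ci, , , ]
  if (method == "box") {
    if (is.null(box)) stop("method 'box' needs `box` index ranges")
    return(mean(vol[box$z, box$y, box$x]))
  }
  rng <- range(vol)
  if (rng[1] == rng[2]) {
    warning("constant volume: background equals the constant")
    return(rng[1])
  }
  thr <- stats::quantile(vol, percentile, names = FALSE)
  mean(vol[vol <= thr])
}

#' ROI mean intensities along a track
#'
#' The ROI is the smallest axis-aligned 3D box around the tracked position
#' that encompasses the whole cell body: half-width `cell_radius_um +
#' margin_um` on every axis. Per-channel means over the ROI voxels are
#' returned for every valid timepoint; ROIs clipped by the volume boundary
#' are computed on the intersection and flagged.
#'
#' @param movie a `two_channel_movie`.
#' @param tracks a `cell_tracks`.
#' @param cell_id which track.
#' @param cell_radius_um soma radius, micrometers.
#' @param margin_um extra half-width beyond the radius (default 1 um).
#' @return data.frame `time_s`, `t_index`, `green_raw`, `red_raw`,
#'   `clipped`.
#' @export
extract_roi_means <- function(movie, tracks, cell_id, cell_radius_um = 4,
                              margin_um = 1) {
  stopifnot(inherits(movie, "two_channel_movie"),
            inherits(tracks, "cell_tracks"))
  j <- match(cell_id, tracks$cells$cell_id)
  if (is.na(j)) stop("unknown cell_id: ", cell_id)
  gi <- channel_index(movie, "green")
  ri <- channel_index(movie, "red")
  sp <- movie$spacing_um                          # z, y, x
  d <- dim(movie$data)[3:5]
  h <- cell_radius_um + margin_um
  ok <- which(!is.na(tracks$positions[j, , 1]))
  out <- data.frame(time_s = tracks$time_s[ok], t_index = ok,
                    green_raw = NA_real_, red_raw = NA_real_,
                    clipped = FALSE)
  for (r in seq_along(ok)) {
    t <- ok[r]
    p <- tracks$positions[j, t, ]                 # x, y, z um
    lo <- c(floor((p[3] - h) / sp[1]), floor((p[2] - h) / sp[2]),
            floor((p[1] - h) / sp[3])) + 1        # 1-based z, y, x
    hi <- c(ceiling((p[3] + h) / sp[1]), ceiling((p[2] + h) / sp[2]),
            ceiling((p[1] + h) / sp[3])) + 1
    clo <- pmax(lo, 1L); chi <- pmin(hi, d)
    if (any(clo > chi)) stop("ROI entirely outside volume for ", cell_id)
    out$clipped[r] <- any(clo != lo) || any(chi != hi)
    iz <- clo[1]:chi[1]; iy <- clo[2]:chi[2]; ix <- clo[3]:chi[3]
    out$green_raw[r] <- mean(movie$data[t, gi, iz, iy, ix])
    out$red_raw[r] <- mean(movie$data[t, ri, iz, iy, ix])
  }
  out
}

#' Ratiometric activity trace
#'
#' Forms the background-subtracted green/red ratio
#' `R = (green - bg_g) / (red - bg_r)`, the baseline `R0` as the mean of
#' the lowest `ceiling(lowest_fraction * N)` defined ratio values over the
#' track, and the activity `dR/R0 = (R - R0) / R0`. Timepoints where the
#' red signal does not exceed its background leave R undefined there
#' (excluded from the baseline and flagged), never clamped.
#'
#' @param green_raw,red_raw ROI mean intensities per timepoint.
#' @param bg_green,bg_red background estimates (scalar or per-timepoint).
#' @param time_s timepoints, seconds.
#' @param lowest_fraction fraction of lowest ratio values averaged into the
#'   baseline (default 0.10, at least one sample).
#' @param cell_id optional label stored in the result.
#' @return data.frame of class `ratio_trace` with columns `time_s`,
#'   `green_raw`, `red_raw`, `bg_green`, `bg_red`, `ratio`, `baseline`,
#'   `dRR0`, `defined`.
#' @export
compute_ratio_trace <- function(green_raw, red_raw, bg_green, bg_red,
                                time_s = seq_along(green_raw) - 1,
                                lowest_fraction = 0.10, cell_id = NA) {
  n <- length(green_raw)
  stopifnot(length(red_raw) == n, length(time_s) == n)
  bg_green <- rep_len(bg_green, n)
  bg_red <- rep_len(bg_red, n)
  denom <- red_raw - bg_red
  defined <- is.finite(denom) & denom > 0
  if (sum(defined) < 10L)
    stop("need at least 10 defined ratio samples, have ", sum(defined))
  ratio <- ifelse(defined, (green_raw - bg_green) / denom, NA_real_)
  rv <- sort(ratio[defined])
  n0 <- max(1L, ceiling(lowest_fraction * sum(defined)))
  R0 <- mean(rv[seq_len(n0)])
  if (!is.finite(R0) || R0 <= 0)
    stop("baseline R0 is not positive; green signal at or below background")
  out <- data.frame(time_s = time_s, green_raw = green_raw,
                    red_raw = red_raw, bg_green = bg_green, bg_red = bg_red,
                    ratio = ratio, baseline = R0,
                    dRR0 = (ratio - R0) / R0, defined = defined)
  attr(out, "cell_id") <- cell_id
  attr(out, "lowest_fraction") <- lowest_fraction
  class(out) <- c("ratio_trace", "data.frame")
  out
}

#' Extract ratiometric traces for tracked cells
#'
#' Convenience wrapper: per-volume dark-floor backgrounds, ROI means along
#' each track, then [compute_ratio_trace()].
#'
#' @param movie a `two_channel_movie`.
#' @param tracks a `cell_tracks`.
#' @param cell_ids which cells (default all).
#' @param cell_radius_um,margin_um ROI geometry, see [extract_roi_means()].
#' @param lowest_fraction baseline fraction, see [compute_ratio_trace()].
#' @param background `"percentile"` per-volume estimate (default) or a list
#'   `list(green = , red = )` of fixed scalars.
#' @return Named list of `ratio_trace` objects keyed by `cell_id`.
#' @export
extract_traces <- function(movie, tracks, cell_ids = NULL,
                           cell_radius_um = 4, margin_um = 1,
                           lowest_fraction = 0.10,
                           background = "percentile") {
  stopifnot(inherits(movie, "two_channel_movie"))
  if (is.null(cell_ids)) cell_ids <- tracks$cells$cell_id
  nt <- dim(movie$data)[1]
  if (identical(background, "percentile")) {
    bg_g <- vapply(seq_len(nt), function(t)
      estimate_background(movie, "green", t), numeric(1))
    bg_r <- vapply(seq_len(nt), function(t)
      estimate_background(movie, "red", t), numeric(1))
  } else {
    bg_g <- rep_len(background$green, nt)
    bg_r <- rep_len(background$red, nt)
  }
  out <- lapply(cell_ids, function(id) {
    roi <- extract_roi_means(movie, tracks, id, cell_radius_um, margin_um)
    compute_ratio_trace(roi$green_raw, roi$red_raw,
                        bg_g[roi$t_index], bg_r[roi$t_index],
                        time_s = roi$time_s,
                        lowest_fraction = lowest_fraction, cell_id = id)
  })
  names(out) <- cell_ids
  out
}

#' Static-marker (GFP) control summary
#'
#' For a calcium-insensitive green marker the ratiometric correction should
#' leave essentially no activity; this returns the magnitude summary used
#' to verify that.
#'
#' @param trace a `ratio_trace`.
#' @return List with `max_abs` (max |dR/R0| over defined timepoints) and
#'   `sd`.
#' @export
static_marker_control <- function(trace) {
  stopifnot(inherits(trace, "ratio_trace"))
  v <- trace$dRR0[trace$defined]
  list(max_abs = max(abs(v)), sd = stats::sd(v))
}

#' Traces as one long data.frame / CSV
#' @param traces named list of `ratio_trace` (from [extract_traces()]).
#' @return data.frame with a `cell_id` column prepended.
#' @export
traces_to_df <- function(traces) {
  out <- do.call(rbind, lapply(names(traces), function(id)
    data.frame(cell_id = id, traces[[id]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @rdname traces_to_df
#' @param path CSV destination.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces_to_df(traces), path, row.names = FALSE)
  invisible(path)
}
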
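#' Inter-cell distance trace
#'
#' Euclidean 3D distance between a measured neuron and a homologous neuron
#' in the adjacent segment, the proxy for segment contraction and
#' extension. The resting length is estimated as the 90th percentile of the
#' distance over the trace (robust to contraction dwell time).
#'
#' @param tracks a `cell_tracks`.
#' @param measured_id,homolog_id `cell_id`s of the pair.
#' @param direction `"posterior"` or `"anterior"` homolog (recorded only).
#' @return data.frame of class `distance_trace` with `time_s`,
#'   `distance_um`; attributes `pair_id`, `resting_length_um`, `direction`.
#' @export
inter_cell_distance <- function(tracks, measured_id, homolog_id,
                                direction = c("posterior", "anterior")) {
  stopifnot(inherits(tracks, "cell_tracks"))
  direction <- match.arg(direction)
  i <- match(measured_id, tracks$cells$cell_id)
  j <- match(homolog_id, tracks$cells$cell_id)
  if (is.na(i) || is.na(j)) stop("cell not found in tracks")
  ok <- !is.na(tracks$positions[i, , 1]) & !is.na(tracks$positions[j, , 1])
  if (!any(ok)) stop("no overlapping valid timepoints")
  tt <- which(ok)
  P1 <- matrix(tracks$positions[i, tt, ], ncol = 3)
  P2 <- matrix(tracks$positions[j, tt, ], ncol = 3)
  d <- sqrt(rowSums((P1 - P2)^2))
  if (stats::median(d) < 1e-9)
    stop("degenerate pairing: inter-cell distance is ~0 ",
         "(measured and homolog coincide)")
  out <- data.frame(time_s = tracks$time_s[tt], distance_um = d)
  attr(out, "pair_id") <- paste(measured_id, homolog_id, direction,
                                sep = "|")
  attr(out, "resting_length_um") <- stats::quantile(d, 0.9, names = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("distance_trace", "data.frame")
  out
}

#' Build a distance trace from raw vectors
#'
#' Escape hatch for analytically constructed traces (tests, worked
#' examples) and externally computed distances.
#'
#' @param time_s,distance_um numeric vectors.
#' @param pair_id label.
#' @param resting_length_um override; default 90th percentile of distance.
#' @return A `distance_trace`.
#' @export
distance_trace <- function(time_s, distance_um, pair_id = "pair",
                           resting_length_um = NULL) {
  stopifnot(length(time_s) == length(distance_um), all(distance_um > 0))
  out <- data.frame(time_s = time_s, distance_um = distance_um)
  attr(out, "pair_id") <- pair_id
  attr(out, "resting_length_um") <-
    if (is.null(resting_length_um))
      stats::quantile(distance_um, 0.9, names = FALSE) else resting_length_um
  attr(out, "direction") <- "posterior"
  class(out) <- c("distance_trace", "data.frame")
  out
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear-interpolated time where `series` crosses `level`, scanning from
# index `from` in direction `dir` (+1/-1); NA if never crossed
cross_time <- function(time_s, series, level, from, dir) {
  n <- length(series)
  i <- from
  while (i + dir >= 1L && i + dir <= n) {
    j <- i + dir
    if ((series[i] - level) * (series[j] - level) <= 0 &&
        series[i] != series[j]) {
      f <- (level - series[i]) / (series[j] - series[i])
      return(time_s[i] + f * (time_s[j] - time_s[i]))
    }
    if (series[j] == level && series[i] == level) return(time_s[j])
    i <- j
  }
  NA_real_
}

#' Detect contraction events in a distance trace
#'
#' The distance is smoothed with a centered moving average (default 0.3 s,
#' which suppresses frame noise at 10 volumes/s without distorting 0.7-2.5 s
#' contractions; set `smoothing_s = 0` for analytic traces), then local
#' minima whose depth (resting length minus minimum) reaches
#' `min_depth_frac` of the resting length become events. The time of
#' maximal contraction is the argmin; the FWHM is the width over which the
#' excursion `resting - d` exceeds half its peak, with sub-sample linear
#' interpolation of both crossings. Events whose half-maximum crossings run
#' off the recording are excluded with reason `"edge"`.
#'
#' @param dtrace a `distance_trace`.
#' @param smoothing_s moving-average window, seconds.
#' @param min_depth_frac detection threshold as a fraction of resting
#'   length (default 0.15).
#' @return data.frame of class `contraction_events`: `pair_id`,
#'   `t_max_contraction_s`, `fwhm_s`, `depth_um`, `idx_min`, `included`,
#'   `reason`. Zero qualifying minima give zero rows (not an error).
#' @export
detect_contractions <- function(dtrace, smoothing_s = 0.3,
                                min_depth_frac = 0.15) {
  stopifnot(inherits(dtrace, "distance_trace"))
  tt <- dtrace$time_s
  d <- dtrace$distance_um
  n <- length(d)
  dt <- stats::median(diff(tt))
  if (smoothing_s > 0 && n <= ceiling(smoothing_s / dt))
    stop("trace shorter than the smoothing window")
  k <- if (smoothing_s > 0) max(1L, round(smoothing_s / dt)) else 1L
  if (k %% 2L == 0L) k <- k + 1L
  ds <- moving_average(d, k)
  rest <- attr(dtrace, "resting_length_um")

  is_min <- logical(n)
  for (i in 2:(n - 1))
    is_min[i] <- ds[i] < ds[i - 1] && ds[i] <= ds[i + 1]
  cand <- which(is_min & (rest - ds) >= min_depth_frac * rest)

  rows <- lapply(cand, function(i) {
    depth <- rest - ds[i]
    half <- rest - depth / 2                     # d-level at half excursion
    t_left <- cross_time(tt, ds, half, i, -1L)
    t_right <- cross_time(tt, ds, half, i, +1L)
    edge <- is.na(t_left) || is.na(t_right)
    data.frame(pair_id = attr(dtrace, "pair_id"),
               t_max_contraction_s = tt[i],
               fwhm_s = if (edge) NA_real_ else t_right - t_left,
               depth_um = depth, idx_min = i,
               included = !edge,
               reason = if (edge) "edge" else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), t_max_contraction_s = numeric(),
               fwhm_s = numeric(), depth_um = numeric(),
               idx_min = integer(), included = logical(),
               reason = character(), stringsAsFactors = FALSE)
  attr(out, "resting_length_um") <- rest
  attr(out, "smoothed") <- ds
  class(out) <- c("contraction_events", "data.frame")
  out
}

#' Apply the event exclusion rules
#'
#' Two rules govern which events enter averaging: (1) an event is excluded
#' (reason `"no-return"`) if the inter-cell distance does not re-attain at
#' least `(1 - return_tolerance)` of the resting length before the next
#' event (or, for the last event, before the end of the recording); (2) at
#' most the first `max_events` surviving events per neuron pair are kept
#' (reason `"max-two-per-neuron"` beyond that).
#'
#' @param events a `contraction_events`.
#' @param dtrace the `distance_trace` the events came from.
#' @param return_tolerance fractional shortfall tolerated (default 0.05).
#' @param max_events per-pair cap (default 2).
#' @return The events with `included`/`reason` updated.
#' @export
apply_exclusion_rules <- function(events, dtrace, return_tolerance = 0.05,
                                  max_events = 2L) {
  stopifnot(inherits(events, "contraction_events"))
  if (nrow(events) == 0L) return(events)
  rest <- attr(events, "resting_length_um")
  thr <- (1 - return_tolerance) * rest
  ds <- attr(events, "smoothed")
  tt <- dtrace$time_s
  ord <- order(events$t_max_contraction_s)
  events <- events[ord, ]
  n <- nrow(events)
  for (e in seq_len(n)) {
    if (!events$included[e]) next
    i0 <- events$idx_min[e]
    i1 <- if (e < n) events$idx_min[e + 1] else length(ds)
    if (max(ds[i0:i1]) < thr) {
      events$included[e] <- FALSE
      events$reason[e] <- "no-return"
    }
  }
  kept <- which(events$included)
  if (length(kept) > max_events) {
    drop <- kept[-seq_len(max_events)]
    events$included[drop] <- FALSE
    events$reason[drop] <- "max-two-per-neuron"
  }
  rownames(events) <- NULL
  attr(events, "smoothed") <- ds
  attr(events, "resting_length_um") <- rest
  events
}

#' Time-normalize one event onto the common A.U. grid
#'
#' Maps time to `(t - t_max_contraction) / FWHM` so that 1 A.U. equals one
#' FWHM and 0 A.U. is maximal contraction, then linearly interpolates the
#' distance and (optionally) the activity trace onto a fixed grid. The
#' activity is additionally amplitude-normalized to a peak of 1 within the
#' grid (the unnormalized trace is retained). Grid points outside the
#' recording are `NA` and the event is flagged truncated.
#'
#' @param event one row of a `contraction_events`.
#' @param dtrace the `distance_trace`.
#' @param rtrace optional `ratio_trace` of the measured neuron.
#' @param grid_au normalized time grid (default `seq(-3, 3, 0.05)`).
#' @return List of class `aligned_event`: `grid_au`, `distance_um`, `dRR0`,
#'   `dRR0_norm`, `fwhm_s`, `t_max_contraction_s`, `pair_id`, `truncated`.
#' @export
normalize_event <- function(event, dtrace, rtrace = NULL,
                            grid_au = seq(-3, 3, by = 0.05)) {
  stopifnot(nrow(event) == 1L)
  if (!isTRUE(event$included)) stop("event is excluded: ", event$reason)
  t_abs <- event$t_max_contraction_s + grid_au * event$fwhm_s
  d_i <- stats::approx(dtrace$time_s, dtrace$distance_um, xout = t_abs,
                       rule = 1)$y
  dr <- dr_n <- NULL
  if (!is.null(rtrace)) {
    def <- rtrace$defined
    dr <- stats::approx(rtrace$time_s[def], rtrace$dRR0[def], xout = t_abs,
                        rule = 1)$y
    mx <- suppressWarnings(max(dr, na.rm = TRUE))
    dr_n <- if (is.finite(mx) && mx > 0) dr / mx else rep(NA_real_, length(dr))
  }
  structure(list(grid_au = grid_au, distance_um = d_i, dRR0 = dr,
                 dRR0_norm = dr_n, fwhm_s = event$fwhm_s,
                 t_max_contraction_s = event$t_max_contraction_s,
                 pair_id = event$pair_id,
                 truncated = anyNA(d_i)),
            class = "aligned_event")
}

#' Average aligned events
#'
#' Pointwise mean and sd over events on the common normalized grid, with
#' the per-gridpoint n reported (truncated events contribute where
#' defined).
#'
#' @param aligned list of `aligned_event`s (>= 2) on identical grids.
#' @param signal which field to average: `"dRR0_norm"` (default, the
#'   amplitude-normalized activity), `"dRR0"`, or `"distance_um"`.
#' @return data.frame `grid_au`, `mean`, `sd`, `n`.
#' @export
average_events <- function(aligned, signal = c("dRR0_norm", "dRR0",
                                               "distance_um")) {
  signal <- match.arg(signal)
  if (length(aligned) < 2L) stop("need at least 2 aligned events")
  grid <- aligned[[1]]$grid_au
  for (a in aligned)
    if (!isTRUE(all.equal(a$grid_au, grid)))
      stop("aligned events are on different grids")
  M <- vapply(aligned, function(a) {
    v <- a[[signal]]
    if (is.null(v)) stop("signal not present in aligned event: ", signal)
    v
  }, numeric(length(grid)))
  n <- rowSums(!is.na(M))
  data.frame(grid_au = grid,
             mean = ifelse(n > 0, rowMeans(M, na.rm = TRUE), NA_real_),
             sd = apply(M, 1, function(v) if (sum(!is.na(v)) > 1)
               stats::sd(v, na.rm = TRUE) else NA_real_),
             n = n)
}

#' Resting- and contraction-phase statistics of one event
#'
#' The contraction phase is the 2 x FWHM window centered at maximal
#' contraction (`[-1, +1]` A.U.) and the resting phase the 0.5 x FWHM
#' window immediately prior (`[-1.5, -1]` A.U.). Returns the mean activity
#' over the resting window and the maximum over the contraction window.
#'
#' @param aligned an `aligned_event` carrying activity.
#' @param normalized use the amplitude-normalized trace? Default `FALSE`.
#' @return List `resting_value`, `contraction_value`,
#'   `resting_complete`, `contraction_complete` (window fully covered?).
#'   A window with no defined samples yields `NA` and `FALSE`.
#' @export
phase_statistics <- function(aligned, normalized = FALSE) {
  stopifnot(inherits(aligned, "aligned_event"))
  v <- if (normalized) aligned$dRR0_norm else aligned$dRR0
  if (is.null(v)) stop("aligned event has no activity trace")
  g <- aligned$grid_au
  rest_w <- g >= -1.5 & g <= -1
  cont_w <- g >= -1 & g <= 1
  val <- function(w, f) {
    x <- v[w]
    if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  }
  list(resting_value = val(rest_w, mean),
       contraction_value = val(cont_w, max),
       resting_complete = !anyNA(v[rest_w]),
       contraction_complete = !anyNA(v[cont_w]))
}

#' Time at half-maximum activity (normalized axis)
#'
#' First rising crossing of 50% of the within-grid maximum activity, with
#' sub-sample linear interpolation, reported in A.U. Used to compare
#' activation timing between cell types.
#'
#' @param aligned an `aligned_event` carrying activity.
#' @param normalized use the amplitude-normalized trace? Default `FALSE`
#'   (the crossing time is identical either way when the peak is positive).
#' @return Time in A.U., or `NA` (flagged via attribute `reason`) when the
#'   maximum is not positive or no rising crossing exists.
#' @export
half_max_time <- function(aligned, normalized = FALSE) {
  stopifnot(inherits(aligned, "aligned_event"))
  v <- if (normalized) aligned$dRR0_norm else aligned$dRR0
  if (is.null(v)) stop("aligned event has no activity trace")
  g <- aligned$grid_au
  ok <- !is.na(v)
  if (!any(ok)) return(structure(NA_real_, reason = "empty"))
  mx <- max(v[ok])
  if (mx <= 0) return(structure(NA_real_, reason = "non-positive-max"))
  half <- mx / 2
  idx <- which(ok)
  for (r in seq_along(idx)[-1]) {
    i <- idx[r - 1]; j <- idx[r]
    if (v[i] < half && v[j] >= half) {
      f <- (half - v[i]) / (v[j] - v[i])
      return(g[i] + f * (g[j] - g[i]))
    }
  }
  if (v[idx[1]] >= half) return(g[idx[1]])       # starts above half
  structure(NA_real_, reason = "no-rising-crossing")
}

#' One-tailed paired lag test
#'
#' Tests whether cell type B activates later than type A by a one-tailed
#' paired t-test on the per-pair half-maximum times (alpha is up to the
#' caller; df = n - 1, exact t distribution via [stats::t.test()]).
#'
#' @param half_max_a,half_max_b paired half-maximum times (same length,
#'   >= 2, paired within segment and event).
#' @param b_later test direction: `TRUE` (default) tests B later than A.
#' @return List `mean_lag`, `t`, `df`, `p`, `n`.
#' @export
paired_lag_test <- function(half_max_a, half_max_b, b_later = TRUE) {
  stopifnot(length(half_max_a) == length(half_max_b))
  keep <- !is.na(half_max_a) & !is.na(half_max_b)
  a <- half_max_a[keep]; b <- half_max_b[keep]
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- b - a
  if (stats::sd(d) == 0)
    stop("degenerate variance: paired differences are constant")
  ht <- stats::t.test(d, mu = 0,
                      alternative = if (b_later) "greater" else "less")
  list(mean_lag = mean(d), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, n = n)
}

#' Events to JSON
#' @param events a `contraction_events`.
#' @param path JSON destination.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(
    events[, c("pair_id", "t_max_contraction_s", "fwhm_s", "depth_um",
               "included", "reason")],
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
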
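#' Cell tracks container
#'
#' Per-cell time series of 3D soma positions with identity labels and
#' per-timepoint confidence. Built by [seed_cells()] and filled by
#' [track_cells()]. Positions are in micrometers in the movie's physical
#' frame; timepoints outside a track's valid range are `NA` with
#' confidence `"lost"`.
#'
#' @name cell_tracks
#' @keywords internal
NULL

new_cell_tracks <- function(cells, time_s, positions, confidence, params) {
  structure(list(cells = cells, time_s = time_s, positions = positions,
                 confidence = confidence, params = params),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat("cell_tracks:", nrow(x$cells), "cells x", length(x$time_s),
      "timepoints\n")
  nlost <- sum(x$confidence == "lost", na.rm = TRUE)
  cat("  lost cell-timepoints:", nlost, "| low-confidence:",
      sum(x$confidence == "low", na.rm = TRUE), "\n")
  invisible(x)
}

#' First/last tracked timepoint per cell
#' @param tracks a `cell_tracks`.
#' @return data.frame `cell_id`, `first`, `last` (1-based volume indices).
#' @export
valid_range <- function(tracks) {
  ok <- !is.na(tracks$positions[, , 1, drop = FALSE])[, , 1]
  if (is.null(dim(ok))) ok <- matrix(ok, nrow = nrow(tracks$cells))
  data.frame(cell_id = tracks$cells$cell_id,
             first = apply(ok, 1, function(v) if (any(v)) which(v)[1] else NA),
             last = apply(ok, 1, function(v) if (any(v)) max(which(v)) else NA),
             row.names = NULL)
}

movie_extent_um <- function(movie) {
  d <- dim(movie$data)[3:5]                      # z, y, x voxels
  (d - 1) * movie$spacing_um                     # z, y, x um
}

#' Initialize tracks from labeled seed points
#'
#' One track per manually identified soma at the first tracked volume.
#' Labels (`cell_type`, `segment`, `side`) are carried through unchanged.
#'
#' @param movie a `two_channel_movie`.
#' @param seeds data.frame with columns `cell_id`, `cell_type`, `segment`,
#'   `side`, `x_um`, `y_um`, `z_um`; positions must lie inside the volume.
#' @param cell_radius_um soma radius used for the minimum-separation
#'   invariant (no two seeds closer than one cell radius).
#' @param t0 1-based index of the seeding volume.
#' @return A `cell_tracks` with positions set at `t0` only.
#' @export
seed_cells <- function(movie, seeds, cell_radius_um = 4, t0 = 1L) {
  stopifnot(inherits(movie, "two_channel_movie"))
  req <- c("cell_id", "cell_type", "segment", "side", "x_um", "y_um", "z_um")
  if (!all(req %in% names(seeds)))
    stop("seeds must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(seeds$cell_id))
    stop("duplicate cell labels in seeds")
  ext <- movie_extent_um(movie)                  # z, y, x
  inside <- seeds$x_um >= 0 & seeds$x_um <= ext[3] &
    seeds$y_um >= 0 & seeds$y_um <= ext[2] &
    seeds$z_um >= 0 & seeds$z_um <= ext[1]
  if (!all(inside))
    stop("seed outside volume: ",
         paste(seeds$cell_id[!inside], collapse = ", "))
  P <- as.matrix(seeds[, c("x_um", "y_um", "z_um")])
  if (nrow(P) > 1) {
    dmat <- as.matrix(stats::dist(P))
    diag(dmat) <- Inf
    if (any(dmat < cell_radius_um))
      stop("duplicate position: seeds closer than one cell radius")
  }
  nt <- dim(movie$data)[1]
  n <- nrow(seeds)
  pos <- array(NA_real_, dim = c(n, nt, 3),
               dimnames = list(seeds$cell_id, NULL, c("x", "y", "z")))
  conf <- matrix("lost", n, nt, dimnames = list(seeds$cell_id, NULL))
  pos[, t0, ] <- P
  conf[, t0] <- "auto"
  cells <- seeds[, c("cell_id", "cell_type", "segment", "side")]
  rownames(cells) <- NULL
  new_cell_tracks(cells, movie_times(movie), pos, conf,
                  params = list(cell_radius_um = cell_radius_um, t0 = t0))
}

# Mean-shift centroid refinement of one cell at one volume (red channel).
# Returns list(pos, confidence) or NULL when the window holds no signal
# above background (track lost; no extrapolation).
track_step <- function(red_vol, spacing_um, pos_um, search_radius_um,
                       background, max_iter = 20L) {
  d <- dim(red_vol)                              # z, y, x
  zc <- (seq_len(d[1]) - 1) * spacing_um[1]
  yc <- (seq_len(d[2]) - 1) * spacing_um[2]
  xc <- (seq_len(d[3]) - 1) * spacing_um[3]
  start <- pos_um
  cur <- pos_um
  tol <- 0.1 * min(spacing_um)
  peak <- NA_real_
  for (it in seq_len(max_iter)) {
    iz <- which(abs(zc - cur[3]) <= search_radius_um)
    iy <- which(abs(yc - cur[2]) <= search_radius_um)
    ix <- which(abs(xc - cur[1]) <= search_radius_um)
    if (!length(iz) || !length(iy) || !length(ix)) return(NULL)
    w <- red_vol[iz, iy, ix, drop = FALSE]
    # spherical mask inside the box
    dz2 <- (zc[iz] - cur[3])^2
    dy2 <- (yc[iy] - cur[2])^2
    dx2 <- (xc[ix] - cur[1])^2
    sph <- outer(dz2, outer(dy2, dx2, `+`), `+`) <= search_radius_um^2
    vals <- w * sph
    peak <- max(vals)
    if (peak <= background) return(NULL)         # window below background
    thr <- 0.5 * peak
    # weight by the intensity in excess of the threshold: the estimator is
    # continuous in the data, which removes the grid bias and noise jitter
    # a hard cutoff produces
    wts <- pmax(vals - thr, 0)
    tot <- sum(wts)
    gz <- apply(wts, 1, sum); gy <- apply(wts, 2, sum); gx <- apply(wts, 3, sum)
    new <- c(sum(xc[ix] * gx), sum(yc[iy] * gy), sum(zc[iz] * gz)) / tot
    if (sqrt(sum((new - cur)^2)) < tol) { cur <- new; break }
    cur <- new
  }
  disp <- sqrt(sum((cur - start)^2))
  conf <- if (peak < 2 * max(background, .Machine$double.eps) ||
              disp > search_radius_um) "low" else "auto"
  list(pos = cur, confidence = conf)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    rest <- setdiff(seq_len(n), i)
    for (s in sub) out[[length(out) + 1L]] <- c(i, rest[s])
  }
  out
}

# Re-assign candidate positions among tracks whose candidates converged
# within one cell radius: minimal total displacement over the conflicting
# cluster, deterministic tie-break by cell_id order (clusters are processed
# and permutations enumerated in cell_id order; first minimum wins).
resolve_conflicts <- function(prev_pos, cand_pos, cell_ids, cell_radius_um) {
  n <- nrow(cand_pos)
  flagged <- rep(FALSE, n)
  if (n < 2) return(list(pos = cand_pos, flagged = flagged))
  live <- which(!is.na(cand_pos[, 1]))
  if (length(live) < 2) return(list(pos = cand_pos, flagged = flagged))
  dmat <- as.matrix(stats::dist(cand_pos[live, , drop = FALSE]))
  adj <- dmat < cell_radius_um
  diag(adj) <- FALSE
  # connected components
  comp <- rep(NA_integer_, length(live))
  cid <- 0L
  for (s in seq_along(live)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  pos_out <- cand_pos
  for (g in seq_len(cid)) {
    members <- live[comp == g]
    if (length(members) < 2) next
    members <- members[order(cell_ids[members])]
    if (length(members) > 7L) {                  # pathological pile-up
      flagged[members] <- TRUE
      next
    }
    cands <- cand_pos[members, , drop = FALSE]
    best <- NULL; best_cost <- Inf
    for (perm in all_permutations(length(members))) {
      cost <- sum(sqrt(rowSums((prev_pos[members, , drop = FALSE] -
                                cands[perm, , drop = FALSE])^2)))
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- perm }
    }
    pos_out[members, ] <- cands[best, , drop = FALSE]
    flagged[members] <- TRUE
  }
  list(pos = pos_out, flagged = flagged)
}

#' Track seeded cells through a movie
#'
#' Frame-to-frame tracking on the static red channel: from each cell's
#' position at `t`, the centroid of red-channel intensity in excess of an
#' adaptive threshold (half the window maximum) inside a sphere of
#' `search_radius_um` is iterated to convergence (< 0.1 voxel displacement
#' or 20 iterations). A window entirely at or below the per-volume
#' background marks the track lost at that timepoint (truncated, never
#' extrapolated). When candidates of neighboring tracks converge within one
#' cell radius, identities are re-assigned by minimal total displacement
#' over the conflicting cluster and the cluster is flagged low-confidence
#' for supervision. Tracking is deterministic and invariant to positive
#' rescaling of the movie.
#'
#' @param movie a `two_channel_movie`.
#' @param tracks a `cell_tracks` from [seed_cells()] (or with corrections
#'   applied).
#' @param search_radius_um search sphere radius; the default 15 um covers
#'   inter-frame soma motion at 10 volumes/s for observed crawl speeds.
#' @param from_t 1-based volume index to start stepping from (default the
#'   seed volume).
#' @return The `cell_tracks` with positions and confidence filled forward.
#' @export
track_cells <- function(movie, tracks, search_radius_um = 15,
                        from_t = NULL) {
  stopifnot(inherits(movie, "two_channel_movie"),
            inherits(tracks, "cell_tracks"))
  nt <- dim(movie$data)[1]
  red_i <- channel_index(movie, "red")
  cell_radius_um <- tracks$params$cell_radius_um
  if (is.null(from_t)) from_t <- tracks$params$t0
  n <- nrow(tracks$cells)
  tracks$params$search_radius_um <- search_radius_um
  for (t in seq(from_t, nt - 1L)) {
    red_vol <- movie$data[t + 1L, red_i, , , ]
    bg <- estimate_background(movie, "red", t + 1L)
    cand <- matrix(NA_real_, n, 3)
    conf <- rep(NA_character_, n)
    for (j in seq_len(n)) {
      p <- tracks$positions[j, t, ]
      if (anyNA(p)) next                         # lost or not yet seeded
      st <- track_step(red_vol, movie$spacing_um, p, search_radius_um, bg)
      if (is.null(st)) {
        conf[j] <- "lost"
      } else {
        cand[j, ] <- st$pos
        conf[j] <- st$confidence
      }
    }
    prev <- matrix(tracks$positions[, t, ], nrow = n)
    rc <- resolve_conflicts(prev, cand, tracks$cells$cell_id, cell_radius_um)
    for (j in seq_len(n)) {
      if (is.na(conf[j])) next
      if (conf[j] == "lost") {
        tracks$confidence[j, t + 1L] <- "lost"
      } else {
        tracks$positions[j, t + 1L, ] <- rc$pos[j, ]
        tracks$confidence[j, t + 1L] <-
          if (rc$flagged[j]) "low" else conf[j]
      }
    }
  }
  tracks
}

#' Apply manual corrections and re-track forward
#'
#' Overwrites the given positions (confidence `"corrected"`) and re-runs
#' forward tracking from the earliest corrected timepoint, so a correction
#' at `t = k` can only change positions at `t >= k`. Correcting a lost
#' track at (or adjacent to) its loss timepoint resumes tracking there.
#'
#' @param movie the movie the tracks came from.
#' @param tracks a `cell_tracks`.
#' @param corrections data.frame with columns `cell_id`, `t_index`
#'   (1-based), `x_um`, `y_um`, `z_um`.
#' @param search_radius_um as in [track_cells()].
#' @return Updated `cell_tracks`.
#' @export
apply_corrections <- function(movie, tracks, corrections,
                              search_radius_um = 15) {
  stopifnot(inherits(tracks, "cell_tracks"))
  if (nrow(corrections) == 0L) return(tracks)
  req <- c("cell_id", "t_index", "x_um", "y_um", "z_um")
  if (!all(req %in% names(corrections)))
    stop("corrections must have columns: ", paste(req, collapse = ", "))
  ext <- movie_extent_um(movie)
  vr <- valid_range(tracks)
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    j <- match(cr$cell_id, tracks$cells$cell_id)
    if (is.na(j)) stop("unknown cell_id in corrections: ", cr$cell_id)
    if (cr$x_um < 0 || cr$x_um > ext[3] || cr$y_um < 0 || cr$y_um > ext[2] ||
        cr$z_um < 0 || cr$z_um > ext[1])
      stop("correction outside volume for ", cr$cell_id)
    rng <- vr[vr$cell_id == cr$cell_id, ]
    if (!is.na(rng$first) &&
        (cr$t_index < rng$first - 1L || cr$t_index > rng$last + 1L))
      stop("correction for ", cr$cell_id, " at t = ", cr$t_index,
           " is not inside or adjacent to the tracked range [",
           rng$first, ", ", rng$last, "]")
    tracks$positions[j, cr$t_index, ] <- c(cr$x_um, cr$y_um, cr$z_um)
    tracks$confidence[j, cr$t_index] <- "corrected"
  }
  t_min <- min(corrections$t_index)
  nt <- length(tracks$time_s)
  if (t_min < nt)
    tracks <- track_cells(movie, tracks, search_radius_um, from_t = t_min)
  # restore the corrected flags (track_cells only writes t+1 onward, but a
  # later correction may itself be overwritten by the forward pass)
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    j <- match(cr$cell_id, tracks$cells$cell_id)
    tracks$positions[j, cr$t_index, ] <- c(cr$x_um, cr$y_um, cr$z_um)
    tracks$confidence[j, cr$t_index] <- "corrected"
  }
  tracks
}

#' Tracks as a long data.frame / CSV
#'
#' @param tracks a `cell_tracks`.
#' @return data.frame `time_s`, `cell_id`, `cell_type`, `segment`, `side`,
#'   `x_um`, `y_um`, `z_um`, `confidence` (lost timepoints omitted).
#' @export
tracks_to_df <- function(tracks) {
  stopifnot(inherits(tracks, "cell_tracks"))
  n <- nrow(tracks$cells)
  out <- do.call(rbind, lapply(seq_len(n), function(j) {
    ok <- which(!is.na(tracks$positions[j, , 1]))
    if (!length(ok)) return(NULL)
    data.frame(time_s = tracks$time_s[ok],
               cell_id = tracks$cells$cell_id[j],
               cell_type = tracks$cells$cell_type[j],
               segment = tracks$cells$segment[j],
               side = tracks$cells$side[j],
               x_um = tracks$positions[j, ok, 1],
               y_um = tracks$positions[j, ok, 2],
               z_um = tracks$positions[j, ok, 3],
               confidence = tracks$confidence[j, ok],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname tracks_to_df
#' @param path CSV destination.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks_to_df(tracks), path, row.names = FALSE)
  invisible(path)
}
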
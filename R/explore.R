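#' Two-bar pose of the exploring larva
#'
#' Planar kinematic abstraction of the anterior larva used to decompose
#' exploration behavior: the left and right dorsal cells of a segment sit at
#' the ends of a rigid bar of length `2p`. The posterior bar (cells D2L,
#' D2R) is the reference frame, fixed with its midpoint at the origin and
#' lying along x. Head retraction is the distance `S(t)` between the bar
#' midpoints, and turning is a rigid rotation `theta(t)` of the anterior bar
#' (cells D1L, D1R) about the posterior midpoint.
#'
#' Sign convention: `theta` is counterclockwise in the (x = left-right,
#' y = anterior) plane, i.e. positive `theta` swings the head toward the
#' left side of the body, shortening the left inter-cell distance `r_L` and
#' lengthening `r_R`.
#'
#' @param p half bar length, micrometers (> 0).
#' @param S midpoint separation, micrometers (> 0).
#' @param theta turning angle in radians, `|theta| < pi/2`.
#' @return An object of class `two_bar_pose` with fields `p`, `S`, `theta`
#'   and a 4 x 2 matrix `corners` with rows `D1L`, `D1R`, `D2L`, `D2R`
#'   (columns x, y in micrometers).
#' @export
pose_to_positions <- function(p, S, theta) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(S), length(S) == 1L,
            is.numeric(theta), length(theta) == 1L)
  if (p <= 0) stop("`p` must be > 0")
  if (S <= 0) stop("`S` must be > 0")
  if (abs(theta) >= pi / 2) stop("|theta| must be < pi/2")
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  d1l <- drop(rot %*% c(-p, S))
  d1r <- drop(rot %*% c(p, S))
  corners <- rbind(D1L = d1l, D1R = d1r, D2L = c(-p, 0), D2R = c(p, 0))
  colnames(corners) <- c("x", "y")
  structure(list(p = p, S = S, theta = theta, corners = corners),
            class = "two_bar_pose")
}

#' Exact inter-cell distances of a two-bar pose
#'
#' Euclidean distances between the ipsilateral corner pairs, computed from
#' the explicit corner coordinates of [pose_to_positions()]. The coordinate
#' construction is the authoritative definition of the exact model; it is
#' algebraically identical to
#' `sqrt((p - p*cos(theta))^2 + (S -/+ p*sin(theta))^2)`.
#'
#' @param pose a `two_bar_pose`.
#' @return Named numeric vector `c(r_L, r_R)` in micrometers.
#' @export
exact_distances <- function(pose) {
  stopifnot(inherits(pose, "two_bar_pose"))
  co <- pose$corners
  c(r_L = sqrt(sum((co["D1L", ] - co["D2L", ])^2)),
    r_R = sqrt(sum((co["D1R", ] - co["D2R", ])^2)))
}

#' Linearized inter-cell distances
#'
#' The linear two-bar model: `r_R = S + p*sin(theta)`,
#' `r_L = S - p*sin(theta)`. Under this model the difference
#' `r_R - r_L = 2p*sin(theta)` is a pure function of turning and the sum
#' `r_L + r_R = 2S` a pure function of retraction ("common mode
#' rejection").
#'
#' @param p half bar length, micrometers.
#' @param S midpoint separation, micrometers.
#' @param theta turning angle, radians. `p`, `S`, `theta` are recycled.
#' @return Named list with numeric components `r_L` and `r_R`.
#' @export
approx_distances <- function(p, S, theta) {
  list(r_L = S - p * sin(theta), r_R = S + p * sin(theta))
}

#' Maximum relative error of the linearized two-bar model
#'
#' Evaluates `|exact - approx| / exact * 100` for both sides on the full
#' grid `S_um x theta_rad` and reports the maximum per side and overall.
#'
#' @param p_um half bar length, micrometers.
#' @param S_um numeric vector of midpoint separations, micrometers.
#' @param theta_rad numeric vector of turning angles, radians.
#' @return List with `max_pct` (overall max, percent), `max_pct_left`,
#'   `max_pct_right`, `n_grid`, and `argmax` (S, theta at the overall max).
#' @export
approximation_error <- function(p_um, S_um, theta_rad) {
  if (length(S_um) < 1L || length(theta_rad) < 1L) stop("degenerate grid")
  g <- expand.grid(S = S_um, theta = theta_rad)
  err <- matrix(NA_real_, nrow(g), 2)
  for (i in seq_len(nrow(g))) {
    pose <- pose_to_positions(p_um, g$S[i], g$theta[i])
    ex <- exact_distances(pose)
    ap <- approx_distances(p_um, g$S[i], g$theta[i])
    err[i, 1] <- abs(ex["r_L"] - ap$r_L) / ex["r_L"] * 100
    err[i, 2] <- abs(ex["r_R"] - ap$r_R) / ex["r_R"] * 100
  }
  i_max <- which.max(pmax(err[, 1], err[, 2]))
  list(max_pct = max(err),
       max_pct_left = max(err[, 1]),
       max_pct_right = max(err[, 2]),
       n_grid = nrow(g),
       argmax = c(S_um = g$S[i_max], theta_rad = g$theta[i_max]))
}

# Least-squares plane through 3D points (rows of `pts`): returns centroid and
# an orthonormal in-plane basis (columns e1, e2) from the top singular vectors.
fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(center = ctr, basis = sv$v[, 1:2, drop = FALSE])
}

#' Decompose tracked positions into turning and retraction metrics
#'
#' Implements the two-bar decomposition on real (3D, tracked) positions of
#' the four cells D1L, D1R, D2L, D2R. The 3D tracks are projected onto the
#' least-squares body plane fitted to all four cells over the whole window,
#' then per timepoint the left/right inter-cell distances are combined into
#' a turning metric `r_L - r_R` (cancels symmetric retraction) and a
#' retraction metric `r_L + r_R` (cancels antisymmetric turning). The
#' half bar length `p_hat` is estimated as half the mean D2L-D2R distance.
#'
#' Two angle estimates are returned: `theta_est_rad`, the linear-model
#' inversion `asin((r_L - r_R) / (-2 p_hat))` (clamped and flagged when the
#' argument leaves `[-1, 1]`), and `theta_exact_rad`, the signed in-plane
#' angle of the anterior bar relative to the posterior bar, which inverts
#' the coordinate model exactly. Likewise `retraction_metric_um / 2` is the
#' linear-model retraction estimate while `s_exact_um` (distance between the
#' bar midpoints) is exact.
#'
#' If `traces` are supplied, the same common-mode logic is applied to the
#' calcium signals: `ca_diff_D1 = dR/R0(D1L) - dR/R0(D1R)` etc., and the
#' sums `ca_sum_*`.
#'
#' @param tracks a `cell_tracks` object containing the four cells.
#' @param cells named character vector mapping roles `D1L`, `D1R`, `D2L`,
#'   `D2R` to `cell_id`s in `tracks`.
#' @param traces optional named list of `ratio_trace` objects keyed by
#'   `cell_id` (see [extract_traces()]).
#' @return A data.frame of class `exploration_metrics` with columns
#'   `time_s`, `r_L_um`, `r_R_um`, `turning_metric_um`,
#'   `retraction_metric_um`, `theta_est_rad`, `theta_exact_rad`,
#'   `s_exact_um`, `clamped`, and, when traces are given, `ca_diff_D1`,
#'   `ca_sum_D1`, `ca_diff_D2`, `ca_sum_D2`. Attribute `p_hat_um` holds the
#'   estimated half bar length.
#' @export
decompose_behavior <- function(tracks, cells, traces = NULL) {
  stopifnot(inherits(tracks, "cell_tracks"))
  roles <- c("D1L", "D1R", "D2L", "D2R")
  if (!all(roles %in% names(cells)))
    stop("`cells` must name all of: ", paste(roles, collapse = ", "))
  idx <- match(cells[roles], tracks$cells$cell_id)
  if (anyNA(idx)) stop("missing side: cell not found in tracks: ",
                       paste(cells[roles][is.na(idx)], collapse = ", "))
  ok <- rep(TRUE, length(tracks$time_s))
  for (i in idx) ok <- ok & !is.na(tracks$positions[i, , 1])
  if (!any(ok)) stop("no common valid timepoints for the four cells")
  tt <- which(ok)

  pts <- do.call(rbind, lapply(idx, function(i) tracks$positions[i, tt, , drop = FALSE][1, , ]))
  if (length(tt) == 1L)
    pts <- do.call(rbind, lapply(idx, function(i) matrix(tracks$positions[i, tt, ], 1)))
  pl <- fit_plane(pts)

  proj <- function(i) {
    q <- matrix(tracks$positions[i, tt, ], ncol = 3)
    sweep(q, 2, pl$center) %*% pl$basis
  }
  P <- lapply(idx, proj)
  names(P) <- roles

  # orient the in-plane basis: e_ap along posterior->anterior, e_lr toward R
  ap <- colMeans((P$D1L + P$D1R) / 2 - (P$D2L + P$D2R) / 2)
  lr <- colMeans(P$D2R - P$D2L)
  if (sum(ap^2) > 0 && sum(lr^2) > 0) {
    # handedness so that counterclockwise (toward left) angles are positive
    handed <- lr[1] * ap[2] - lr[2] * ap[1]
    if (handed < 0) {
      P <- lapply(P, function(m) m %*% diag(c(1, -1)))
    }
  }

  dist2 <- function(a, b) sqrt(rowSums((a - b)^2))
  r_L <- dist2(P$D1L, P$D2L)
  r_R <- dist2(P$D1R, P$D2R)
  p_hat <- mean(dist2(P$D2L, P$D2R)) / 2
  turning <- r_L - r_R
  retraction <- r_L + r_R
  arg <- turning / (-2 * p_hat)
  clamped <- abs(arg) > 1
  theta_est <- asin(pmin(1, pmax(-1, arg)))

  u2 <- P$D2R - P$D2L
  u1 <- P$D1R - P$D1L
  theta_exact <- atan2(u2[, 1] * u1[, 2] - u2[, 2] * u1[, 1],
                       rowSums(u2 * u1))
  s_exact <- dist2((P$D1L + P$D1R) / 2, (P$D2L + P$D2R) / 2)

  out <- data.frame(time_s = tracks$time_s[tt],
                    r_L_um = r_L, r_R_um = r_R,
                    turning_metric_um = turning,
                    retraction_metric_um = retraction,
                    theta_est_rad = theta_est,
                    theta_exact_rad = theta_exact,
                    s_exact_um = s_exact,
                    clamped = clamped)
  if (!is.null(traces)) {
    get_tr <- function(role) {
      tr <- traces[[cells[[role]]]]
      if (is.null(tr)) stop("missing trace for ", cells[[role]])
      stats::approx(tr$time_s, tr$dRR0, xout = out$time_s, rule = 1)$y
    }
    for (bar in c("D1", "D2")) {
      l <- get_tr(paste0(bar, "L")); r <- get_tr(paste0(bar, "R"))
      out[[paste0("ca_diff_", bar)]] <- l - r
      out[[paste0("ca_sum_", bar)]] <- l + r
    }
  }
  attr(out, "p_hat_um") <- p_hat
  class(out) <- c("exploration_metrics", "data.frame")
  out
}

#' Lagged correlations of calcium metrics with motion metrics
#'
#' Pearson correlation of the left-right calcium difference against the
#' turning metric and of the calcium sum against the retraction metric, at
#' zero lag and at the delay in `[0, max_lag_s]` that maximizes the absolute
#' correlation. Only positive delays of calcium relative to movement are
#' searched (deformation precedes the indicator transient); the lag grid is
#' one volume period.
#'
#' @param metrics an `exploration_metrics` data.frame with `ca_*` columns.
#' @param max_lag_s maximum calcium delay searched, seconds.
#' @return data.frame with columns `pair`, `lag_s`, `pearson_r`, `n`,
#'   `which` (`"lag0"` or `"best"`); constant series yield `NA` correlations
#'   with `flagged = TRUE`.
#' @export
metric_correlations <- function(metrics, max_lag_s = 2) {
  stopifnot(inherits(metrics, "exploration_metrics"))
  dt <- stats::median(diff(metrics$time_s))
  max_k <- max(0L, floor(max_lag_s / dt))
  ca_cols <- grep("^ca_(diff|sum)_", names(metrics), value = TRUE)
  if (length(ca_cols) == 0L) stop("metrics carry no calcium columns")
  rows <- list()
  for (col in ca_cols) {
    target <- if (grepl("^ca_diff", col)) "turning_metric_um" else
      "retraction_metric_um"
    ca <- metrics[[col]]; mo <- metrics[[target]]
    lag_cor <- function(k) {
      n <- length(ca) - k
      a <- ca[(1 + k):length(ca)]; b <- mo[1:n]
      keep <- !is.na(a) & !is.na(b)
      if (sum(keep) < 3L || stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0)
        return(c(NA_real_, sum(keep)))
      c(stats::cor(a[keep], b[keep]), sum(keep))
    }
    r0 <- lag_cor(0L)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(col, "vs", target), lag_s = 0, pearson_r = r0[1],
      n = r0[2], which = "lag0", flagged = is.na(r0[1]))
    all_r <- vapply(0:max_k, function(k) lag_cor(k)[1], numeric(1))
    if (all(is.na(all_r))) {
      best <- NA_integer_
    } else best <- which.max(abs(all_r)) - 1L
    rb <- if (is.na(best)) c(NA_real_, NA_real_) else lag_cor(best)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(col, "vs", target),
      lag_s = if (is.na(best)) NA_real_ else best * dt,
      pearson_r = rb[1], n = rb[2], which = "best", flagged = is.na(rb[1]))
  }
  do.call(rbind, rows)
}
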
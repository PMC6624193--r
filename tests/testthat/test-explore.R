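# Two-bar model: corner geometry, exact vs linearized distances, the
# common-mode rejection identities, decomposition and lagged correlations.

test_that("pose corners follow the rotation-matrix construction", {
  # no rotation: a 2p x S rectangle with r_L = r_R = S
  p0 <- pose_to_positions(25, 100, 0)
  expect_equal(unname(p0$corners["D1L", ]), c(-25, 100))
  expect_equal(unname(p0$corners["D1R", ]), c(25, 100))
  expect_equal(unname(exact_distances(p0)), c(100, 100))
  # rigid bars: both bar lengths are exactly 2p for any pose
  pr <- pose_to_positions(25, 100, 30 * pi / 180)
  expect_equal(sqrt(sum((pr$corners["D1R", ] - pr$corners["D1L", ])^2)), 50)
  expect_equal(sqrt(sum((pr$corners["D2R", ] - pr$corners["D2L", ])^2)), 50)
  # worked corner: rotate (+25, 100) by 30 degrees
  expect_equal(unname(pr$corners["D1R", ]),
               c(25 * cos(pi / 6) - 100 * sin(pi / 6),
                 25 * sin(pi / 6) + 100 * cos(pi / 6)))
  expect_equal(unname(pr$corners["D1R", ]), c(-28.349, 99.103),
               tolerance = 1e-4)
  # rotating by theta then -theta returns the rectangle
  back <- pose_to_positions(25, 100, 0)
  rot <- matrix(c(cos(-pi / 6), sin(-pi / 6), -sin(-pi / 6), cos(-pi / 6)),
                2, 2)
  expect_equal(t(rot %*% t(pr$corners[1:2, ])), back$corners[1:2, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(pose_to_positions(-1, 100, 0), "p")
  expect_error(pose_to_positions(25, 100, pi / 2), "theta")
})

test_that("exact distances match the hand-computed worked example", {
  pr <- pose_to_positions(25, 100, 30 * pi / 180)
  ex <- exact_distances(pr)
  # r_R = |D1R - D2R| with D1R = (-28.349, 99.103), D2R = (25, 0)
  expect_equal(unname(ex["r_R"]), sqrt(53.349^2 + 99.103^2), tolerance = 1e-4)
  expect_equal(unname(ex["r_R"]), 112.55, tolerance = 1e-4)
  # mirror symmetry: r_L(theta) = r_R(-theta)
  for (th in c(0.1, 0.3, -0.25)) {
    a <- exact_distances(pose_to_positions(25, 100, th))
    b <- exact_distances(pose_to_positions(25, 100, -th))
    expect_equal(unname(a["r_L"]), unname(b["r_R"]), tolerance = 1e-12)
  }
})

test_that("linearized distances satisfy the turning identity", {
  ap <- approx_distances(25, 100, 30 * pi / 180)
  expect_equal(ap$r_R, 112.5)
  expect_equal(ap$r_L, 87.5)
  th <- seq(-0.5, 0.5, 0.05)
  ap2 <- approx_distances(25, 100, th)
  expect_equal((ap2$r_R - ap2$r_L) / (2 * 25), sin(th))
  expect_equal(approx_distances(25, 100, 0)$r_L, 100)
})

test_that("common-mode rejection holds exactly under the linear model", {
  # retraction metric r_L + r_R = 2S has zero dependence on theta;
  # turning metric r_L - r_R = -2p sin(theta) has zero dependence on S
  S_grid <- seq(75, 125, 5)
  th_grid <- seq(-0.5, 0.5, 0.05)
  for (S in S_grid) {
    ap <- approx_distances(25, S, th_grid)
    expect_lt(max(abs((ap$r_L + ap$r_R) - 2 * S)), 1e-12 * 2 * S)
  }
  for (th in th_grid) {
    ap <- approx_distances(25, S_grid, th)
    expect_lt(max(abs((ap$r_L - ap$r_R) + 2 * 25 * sin(th))), 1e-12 * 50)
  }
})

test_that("approximation error is zero at zero turning and even in theta", {
  e0 <- approximation_error(25, seq(75, 125, length.out = 5), 0)
  expect_equal(e0$max_pct, 0)
  th <- seq(5, 30, 5) * pi / 180
  e_pos <- approximation_error(25, 100, th)
  e_neg <- approximation_error(25, 100, -th)
  expect_equal(e_pos$max_pct, e_neg$max_pct, tolerance = 1e-12)
  expect_error(approximation_error(25, numeric(0), th), "degenerate")
})

test_that("approximation error matches the independent closed form", {
  # independent oracle: exact r = sqrt((p(1-cos t))^2 + (S -/+ p sin t)^2),
  # derived by hand from the corner coordinates
  p <- 25
  oracle <- function(S, th) {
    a <- p * (1 - cos(th))
    rL <- sqrt(a^2 + (S - p * sin(th))^2)
    rR <- sqrt(a^2 + (S + p * sin(th))^2)
    max(abs(rL - (S - p * sin(th))) / rL,
        abs(rR - (S + p * sin(th))) / rR) * 100
  }
  for (case in list(c(75, 30), c(100, 30), c(125, -20), c(90, 10))) {
    th <- case[2] * pi / 180
    got <- approximation_error(p, case[1], th)$max_pct
    expect_equal(got, oracle(case[1], th), tolerance = 1e-12)
  }
  # frozen worst corner of the physiological grid, from the closed form:
  # S = 75, |theta| = 30 deg -> 0.1433%
  worst <- approximation_error(p, 75, 30 * pi / 180)$max_pct
  expect_equal(worst, 0.143285, tolerance = 1e-4)
})

test_that("decomposition inverts noise-free poses to machine precision", {
  cfg <- sim_config("explore", duration = 4, seed = 3,
                    explore_theta_max_deg = 25, explore_s0 = 100)
  truth <- simulate_explore_kinematics(cfg)
  tk <- tracks_from_truth(truth)
  met <- decompose_behavior(tk, c(D1L = "D1L", D1R = "D1R",
                                  D2L = "D2L", D2R = "D2R"))
  # exact inversions: theta from the anterior-bar direction, S from the
  # inter-bar midpoint distance
  expect_lt(max(abs(met$theta_exact_rad - truth$pose$theta_rad)), 1e-9)
  expect_lt(max(abs(met$s_exact_um - truth$pose$S_um) / truth$pose$S_um),
            1e-9)
  # p_hat recovers the rigid half width
  expect_equal(attr(met, "p_hat_um"), cfg$halfwidth, tolerance = 1e-9)
  # linear-model estimates agree within the linearization error
  expect_lt(max(abs(met$theta_est_rad - truth$pose$theta_rad)), 0.01)
  expect_lt(max(abs(met$retraction_metric_um / 2 - truth$pose$S_um)), 0.3)
  # turning metric equals the exact r_L - r_R, tracking -2p sin(theta)
  expect_lt(max(abs(met$turning_metric_um -
                    (-2 * cfg$halfwidth * sin(truth$pose$theta_rad)))), 0.3)
})

test_that("pure retraction and pure turning separate cleanly", {
  # theta = 0: turning metric is identically zero, retraction = 2 S(t)
  cfg0 <- sim_config("explore", duration = 3, seed = 5,
                     explore_theta_max_deg = 0)
  tr0 <- simulate_explore_kinematics(cfg0)
  m0 <- decompose_behavior(tracks_from_truth(tr0),
                           c(D1L = "D1L", D1R = "D1R",
                             D2L = "D2L", D2R = "D2R"))
  expect_lt(max(abs(m0$turning_metric_um)), 1e-9)
  expect_equal(m0$retraction_metric_um, 2 * tr0$pose$S_um, tolerance = 1e-9)
  # S constant: retraction metric constant to within the linearization
  # bound while the turning metric sweeps with theta
  cfgS <- sim_config("explore", duration = 3, seed = 5,
                     explore_s_amplitude = 0, explore_theta_max_deg = 25)
  trS <- simulate_explore_kinematics(cfgS)
  mS <- decompose_behavior(tracks_from_truth(trS),
                           c(D1L = "D1L", D1R = "D1R",
                             D2L = "D2L", D2R = "D2R"))
  spread <- diff(range(mS$retraction_metric_um)) / (2 * cfgS$explore_s0)
  expect_lt(spread, 0.0012)
  expect_gt(diff(range(mS$turning_metric_um)), 10)
})

test_that("lagged correlations find constructed proportionality and delay", {
  cfg <- sim_config("explore", duration = 6, seed = 9)
  truth <- simulate_explore_kinematics(cfg)
  met <- decompose_behavior(tracks_from_truth(truth),
                            c(D1L = "D1L", D1R = "D1R",
                              D2L = "D2L", D2R = "D2R"))
  n <- nrow(met)
  # proportional series: r = 1 at lag 0
  met$ca_diff_D1 <- 0.01 * met$turning_metric_um
  met$ca_sum_D1 <- 0.02 * met$retraction_metric_um + 1
  tab <- metric_correlations(met, max_lag_s = 1)
  lag0 <- tab[tab$which == "lag0", ]
  expect_equal(lag0$pearson_r, c(1, 1), tolerance = 1e-9)
  # calcium delayed by 3 volumes: best-lag correlation 1 at lag 3 periods
  met$ca_diff_D1 <- c(rep(NA, 3),
                      0.01 * met$turning_metric_um[seq_len(n - 3)])
  tab2 <- metric_correlations(met, max_lag_s = 1)
  best <- tab2[tab2$which == "best" & grepl("ca_diff", tab2$pair), ]
  expect_equal(best$lag_s, 0.3)
  expect_equal(best$pearson_r, 1, tolerance = 1e-9)
  # independent white noise: |r| < 0.2 in seeded replicates (n = 200)
  set.seed(77)
  hits <- 0L
  for (rep in 1:20) {
    metN <- met[rep(seq_len(n), length.out = 200), ]
    metN$time_s <- seq(0, by = 0.1, length.out = 200)
    metN$turning_metric_um <- rnorm(200)
    metN$retraction_metric_um <- rnorm(200)
    metN$ca_diff_D1 <- rnorm(200)
    metN$ca_sum_D1 <- rnorm(200)
    class(metN) <- class(met)
    t0 <- metric_correlations(metN, max_lag_s = 0)
    if (max(abs(t0$pearson_r[t0$which == "lag0"])) < 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("missing cells and degenerate series are flagged", {
  cfg <- sim_config("explore", duration = 2, seed = 3)
  tk <- tracks_from_truth(simulate_explore_kinematics(cfg))
  expect_error(decompose_behavior(tk, c(D1L = "D1L", D1R = "nope",
                                        D2L = "D2L", D2R = "D2R")),
               "missing side")
  met <- decompose_behavior(tk, c(D1L = "D1L", D1R = "D1R",
                                  D2L = "D2L", D2R = "D2R"))
  met$ca_diff_D1 <- 0                            # constant series
  met$ca_sum_D1 <- seq_len(nrow(met))
  tab <- metric_correlations(met, max_lag_s = 0.5)
  expect_true(all(tab$flagged[grepl("ca_diff", tab$pair)]))
})
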
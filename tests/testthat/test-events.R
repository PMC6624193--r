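# Contraction-event machinery: distances, detection geometry, FWHM,
# exclusion rules, normalization, phase windows, half-max timing, lag test.

test_that("inter-cell distance reproduces static and generator geometry", {
  cfg <- small_crawl_config()
  truth <- simulate_crawl_kinematics(cfg)
  tk <- tracks_from_truth(truth)
  # crawl pair: min distance matches ground-truth min segment length < 1 um
  dt <- inter_cell_distance(tk, "ddaE_S2_L", "ddaE_S1_L", "posterior")
  expect_lt(abs(min(dt$distance_um) - min(truth$segment_lengths[2, ])), 1)
  # static pair 80 um apart
  tk2 <- tk
  tk2$positions[1, , ] <- matrix(rep(c(10, 10, 10), each = length(tk$time_s)),
                                 ncol = 3)
  tk2$positions[2, , ] <- matrix(rep(c(10, 90, 10), each = length(tk$time_s)),
                                 ncol = 3)
  d2 <- inter_cell_distance(tk2, tk$cells$cell_id[1], tk$cells$cell_id[2])
  expect_true(all(d2$distance_um == 80))
  # identical tracks are a degenerate pairing
  tk3 <- tk
  tk3$positions[2, , ] <- tk3$positions[1, , ]
  expect_error(inter_cell_distance(tk3, tk$cells$cell_id[1],
                                   tk$cells$cell_id[2]), "degenerate")
})

test_that("triangular dip yields depth 40 um and FWHM 1.0 s exactly", {
  dtr <- triangle_dip_trace()
  ev <- detect_contractions(dtr, smoothing_s = 0, min_depth_frac = 0.15)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$depth_um, 40)
  expect_equal(ev$fwhm_s, 1.0)
  expect_equal(ev$t_max_contraction_s, 4)        # apex of the dip
})

test_that("constant traces yield no events; identical dips match", {
  tt <- seq(0, 5, 0.1)
  flat <- distance_trace(tt, rep(100, length(tt)), resting_length_um = 100)
  expect_equal(nrow(detect_contractions(flat, smoothing_s = 0)), 0)
  # two congruent dips: equal depth and FWHM (translation invariance)
  tt2 <- seq(0, 20, 0.1)
  d <- 100 - 30 * (exp(-(tt2 - 5)^2 / 0.5) + exp(-(tt2 - 13)^2 / 0.5))
  ev <- detect_contractions(distance_trace(tt2, d, resting_length_um = 100),
                            smoothing_s = 0)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$depth_um[1], ev$depth_um[2], tolerance = 1e-6)
  expect_equal(ev$fwhm_s[1], ev$fwhm_s[2], tolerance = 1e-3)
})

test_that("FWHM of Gaussian dips matches 2.355 sigma within one period", {
  for (sigma in c(0.3, 0.5, 0.8)) {
    dtr <- gaussian_dip_trace(sigma = sigma)
    ev <- detect_contractions(dtr, smoothing_s = 0)
    expect_equal(nrow(ev), 1)
    expect_lt(abs(ev$fwhm_s - 2.3548 * sigma), 0.1)
  }
})

test_that("event statistics are invariant to uniform time translation", {
  dtr <- gaussian_dip_trace(sigma = 0.5)
  shifted <- distance_trace(dtr$time_s + 37.3, dtr$distance_um,
                            resting_length_um = attr(dtr, "resting_length_um"))
  e1 <- detect_contractions(dtr, smoothing_s = 0)
  e2 <- detect_contractions(shifted, smoothing_s = 0)
  expect_equal(e2$t_max_contraction_s - e1$t_max_contraction_s, 37.3)
  expect_equal(e1$fwhm_s, e2$fwhm_s)
  expect_equal(e1$depth_um, e2$depth_um)
})

test_that("exclusion rules implement no-return and the two-event cap", {
  tt <- seq(0, 30, 0.1)
  rest <- 100
  # fully recovering dip: included
  dA <- rest - 30 * exp(-(tt - 4)^2 / 0.5)
  dtrA <- distance_trace(tt, dA, resting_length_um = rest)
  evA <- apply_exclusion_rules(detect_contractions(dtrA, smoothing_s = 0),
                               dtrA)
  expect_true(evA$included[1])
  expect_true(is.na(evA$reason[1]))

  # dip followed by sustained 12% shortening: recovery (88 um) re-crosses
  # the half-max level (80 um) so the FWHM is measurable, but never
  # re-attains 95% of resting -> excluded as no-return
  dB <- rep(100, length(tt))
  dB[tt >= 6 & tt < 7] <- 100 - 40 * (tt[tt >= 6 & tt < 7] - 6)
  dB[tt >= 7 & tt < 8] <- 60 + 28 * (tt[tt >= 7 & tt < 8] - 7)
  dB[tt >= 8] <- 88
  dtrB <- distance_trace(tt, dB, resting_length_um = rest)
  evB <- apply_exclusion_rules(detect_contractions(dtrB, smoothing_s = 0),
                               dtrB)
  expect_equal(nrow(evB), 1)
  expect_false(evB$included[1])
  expect_equal(evB$reason[1], "no-return")

  # four clean events: numbers 3 and 4 dropped by the per-neuron cap
  d4 <- rest - 30 * rowSums(sapply(c(4, 10, 16, 22),
                                   function(m) exp(-(tt - m)^2 / 0.5)))
  dtr4 <- distance_trace(tt, d4, resting_length_um = rest)
  ev4 <- apply_exclusion_rules(detect_contractions(dtr4, smoothing_s = 0),
                               dtr4)
  expect_equal(ev4$included, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ev4$reason[3:4], rep("max-two-per-neuron", 2))
})

test_that("time normalization superimposes congruent events", {
  # two time-scaled copies of the same dip shape (FWHM 0.8 s and 1.6 s)
  tt <- seq(0, 40, 0.05)
  s1 <- 0.8 / 2.3548; s2 <- 1.6 / 2.3548
  rest <- 100; depth <- 30
  d <- rest - depth * (exp(-(tt - 8)^2 / (2 * s1^2)) +
                       exp(-(tt - 25)^2 / (2 * s2^2)))
  dtr <- distance_trace(tt, d, resting_length_um = rest)
  ev <- apply_exclusion_rules(detect_contractions(dtr, smoothing_s = 0), dtr)
  a1 <- normalize_event(ev[1, ], dtr)
  a2 <- normalize_event(ev[2, ], dtr)
  ok <- !is.na(a1$distance_um) & !is.na(a2$distance_um)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(a1$distance_um[ok] - a2$distance_um[ok])), 0.02 * depth)

  # amplitude normalization: peak of dRR0_norm is exactly 1 in the window
  act <- activity_trace(tt, 0.6 * exp(-(tt - 8.2)^2 / (2 * s1^2)))
  a1r <- normalize_event(ev[1, ], dtr, act)
  expect_equal(max(a1r$dRR0_norm, na.rm = TRUE), 1)
  expect_false(a1$truncated)

  # event at the recording edge: grid truncated and flagged
  ttE <- seq(0, 4, 0.05)
  dE <- rest - depth * exp(-(ttE - 2)^2 / (2 * s1^2))
  dtrE <- distance_trace(ttE, dE, resting_length_um = rest)
  evE <- detect_contractions(dtrE, smoothing_s = 0)
  aE <- normalize_event(evE[1, ], dtrE)
  expect_true(aE$truncated)
})

test_that("averaging reports pointwise mean, sd and n", {
  dtr <- gaussian_dip_trace(sigma = 0.5)
  ev <- apply_exclusion_rules(detect_contractions(dtr, smoothing_s = 0), dtr)
  tt <- dtr$time_s
  base <- 0.5 * exp(-(tt - 5)^2 / 0.3)
  a1 <- normalize_event(ev[1, ], dtr, activity_trace(tt, base + 0.05))
  a2 <- normalize_event(ev[1, ], dtr, activity_trace(tt, base - 0.05))
  # an event averaged with itself: mean = event, sd = 0
  avg_same <- average_events(list(a1, a1), signal = "dRR0")
  ok <- !is.na(a1$dRR0)
  expect_equal(avg_same$mean[ok], a1$dRR0[ok])
  expect_true(all(avg_same$sd[ok] == 0))
  expect_true(all(avg_same$n[ok] == 2))
  # mirror-image perturbations: mean recovers the common shape
  avg_mix <- average_events(list(a1, a2), signal = "dRR0")
  common <- normalize_event(ev[1, ], dtr, activity_trace(tt, base))
  expect_equal(avg_mix$mean[ok], common$dRR0[ok], tolerance = 1e-9)
  expect_error(average_events(list(a1)), "at least 2")
})

test_that("phase windows return resting mean and contraction max", {
  grid <- seq(-3, 3, by = 0.05)
  zero <- aligned_stub(rep(0, length(grid)))
  ps0 <- phase_statistics(zero)
  expect_equal(ps0$resting_value, 0)
  expect_equal(ps0$contraction_value, 0)
  # unit boxcar on [-0.5, 0.5] A.U.: resting 0, contraction 1
  box <- aligned_stub(as.numeric(grid >= -0.5 & grid <= 0.5))
  ps <- phase_statistics(box)
  expect_equal(ps$resting_value, 0)
  expect_equal(ps$contraction_value, 1)
  expect_true(ps$resting_complete && ps$contraction_complete)
})

test_that("half-max timing interpolates the first rising crossing", {
  grid <- seq(-3, 3, by = 0.05)
  # worked example: samples [0, 0.2, 0.8, 1.0] -> crossing 0.025 past the
  # second sample
  v <- rep(0, length(grid))
  i0 <- which(grid == 0)
  v[i0 + 0:3] <- c(0, 0.2, 0.8, 1.0)
  t_half <- half_max_time(aligned_stub(v))
  expect_equal(t_half, grid[i0 + 1] + (0.5 - 0.2) / (0.8 - 0.2) * 0.05)
  expect_equal(t_half - grid[i0 + 1], 0.025)
  # step 0 -> 1: crossing at the step within half a grid cell
  vs <- as.numeric(grid >= 0.5)
  expect_lt(abs(half_max_time(aligned_stub(vs)) - 0.5), 0.05 / 2 + 1e-12)
  # shifting the trace by delta shifts the crossing by exactly delta
  sh <- 10L  # 0.5 A.U.
  v2 <- c(rep(0, sh), v[seq_len(length(v) - sh)])
  expect_equal(half_max_time(aligned_stub(v2)) - t_half, 0.5)
  # non-positive maximum is flagged undefined
  neg <- aligned_stub(rep(0, length(grid)) - 1)
  neg$dRR0_norm <- neg$dRR0
  expect_true(is.na(half_max_time(neg)))
})

test_that("paired lag test matches hand-computed t and p", {
  res <- paired_lag_test(c(0, 0, 0), c(0.5, 1.0, 1.5))
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, stats::pt(sqrt(12), df = 2, lower.tail = FALSE))
  expect_equal(res$p, 0.0371, tolerance = 1e-2)
  # differences symmetric about zero: t = 0, p = 0.5
  res0 <- paired_lag_test(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)
  # zero-variance differences are refused, not reported as p = 0 or 1
  expect_error(paired_lag_test(c(1, 2, 3), c(2, 3, 4)), "degenerate variance")
})

test_that("GFP-like null activity shows no resting/contraction difference", {
  # 20 null events: phase values differ only by noise; two-tailed p > 0.05
  set.seed(1234)
  tt <- seq(0, 10, 0.1)
  dtr <- gaussian_dip_trace(sigma = 0.5)
  ev <- apply_exclusion_rules(detect_contractions(dtr, smoothing_s = 0), dtr)
  rest_v <- cont_v <- numeric(20)
  for (i in 1:20) {
    act <- activity_trace(tt, rnorm(length(tt), 0, 0.02))
    ps <- phase_statistics(normalize_event(ev[1, ], dtr, act))
    rest_v[i] <- ps$resting_value
    cont_v[i] <- ps$contraction_value
  }
  # contraction value is a max over the window, hence positively biased
  # under the null; compare against the same statistic in a disjoint
  # reference window by centering both on their medians
  p <- stats::t.test(rest_v - stats::median(rest_v),
                     cont_v - stats::median(cont_v), paired = TRUE)$p.value
  expect_gt(p, 0.05)
})

test_that("events serialize to JSON with machine-readable reasons", {
  dtr <- triangle_dip_trace()
  ev <- apply_exclusion_rules(detect_contractions(dtr, smoothing_s = 0), dtr)
  f <- tempfile(fileext = ".json")
  write_events_json(ev, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$depth_um, 40)
  expect_true(back$included)
  file.remove(f)
})
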
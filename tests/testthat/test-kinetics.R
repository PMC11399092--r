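test_that("event linking partitions localizations into maximal runs", {
  expect_equal(link_events(7L), 1L)
  expect_equal(link_events(c(3L, 4L, 5L, 9L)), c(1L, 1L, 1L, 2L))
  expect_equal(link_events(integer(0)), integer(0))
  # brute-force run-length oracle on random sparse frame sets
  set.seed(14)
  for (i in 1:20) {
    frames <- sort(sample.int(200, 60))
    ids <- link_events(frames)
    oracle <- cumsum(c(1L, as.integer(diff(frames) > 1L)))
    expect_equal(ids, oracle)
    # partition invariant: each localization in exactly one event
    expect_equal(length(ids), length(frames))
    expect_equal(sum(table(ids)), length(frames))
  }
  expect_error(link_events(c(3L, 3L, 4L)), "duplicate")
  expect_error(link_events(c(5L, 3L)), "sorted")
})

test_that("gap-tolerant linking merges runs within the tolerance", {
  expect_equal(link_events(c(1L, 3L, 7L), max_dark_frames = 1), c(1L, 1L, 2L))
})

test_that("binding_events summarises starts, ends and lengths", {
  ev <- binding_events(data.frame(frame = c(3L, 4L, 5L, 9L),
                                  photons = c(1, 2, 3, 4)))
  expect_equal(ev$start_frame, c(3L, 9L))
  expect_equal(ev$end_frame, c(5L, 9L))
  expect_equal(ev$length, c(3L, 1L))
})

test_that("CDF exponential fit agrees with the sample-mean MLE", {
  set.seed(31)
  x <- rexp(1e4, rate = 1 / 2)
  tau <- fit_mean_time(x)
  expect_equal(tau, 2.0, tolerance = 0.03)
  expect_lt(abs(tau - mean(x)) / mean(x), 0.03)
})

test_that("CDF fit is unbiased on frame-discretized exponential durations", {
  set.seed(32)
  ev <- generate_event_stream(0.35, 2, 5e4)
  d <- discretize_events(ev, 0.1, 0)
  len <- as.numeric(tapply(d$frame, d$event, function(f) max(f) - min(f) + 1))
  tau <- fit_mean_time(len * 0.1)
  expect_equal(tau, 0.35, tolerance = 0.03)
  # oracle equivalence: agrees with the unbiased moment estimate within 3%
  expect_lt(abs(tau - mean((len - 1) * 0.1)) / mean((len - 1) * 0.1), 0.03)
})

test_that("degenerate or scarce duration sets are flagged, not fitted", {
  few <- fit_mean_time(c(1, 2, 3))
  expect_true(is.na(few))
  expect_match(attr(few, "reason"), "few")
  same <- fit_mean_time(rep(0.2, 50))
  expect_true(is.na(same))
  expect_match(attr(same, "reason"), "degenerate")
})

test_that("center-frame photons use only interior frames of long events", {
  res <- center_frame_photons(data.frame(frame = 0:3,
                                         photons = c(500, 1000, 1000, 400)),
                              exposure = 0.1)
  expect_equal(res$mean, 1000)
  expect_equal(res$n, 2L)
  # events of length <= 2 contribute nothing
  res2 <- center_frame_photons(data.frame(frame = c(0L, 1L, 5L),
                                          photons = c(9, 9, 9)), 0.1)
  expect_true(is.na(res2$mean))
  expect_equal(res2$n, 0L)
})

test_that("center-frame photon rate is invariant to exposure rescaling", {
  # same 100 ms photon rate sampled at 50 ms frames: center frames halve
  # their counts but the per-100 ms scaling restores the rate
  set.seed(33)
  ev <- generate_event_stream(0.4, 10, 20000)
  for (expo in c(0.05, 0.1, 0.2)) {
    d <- discretize_events(ev, expo, 8000)
    # merge frames that record the tail of one event and the head of the
    # next, as a camera would
    ph <- tapply(d$photons, d$frame, sum)
    r <- center_frame_photons(data.frame(frame = as.integer(names(ph)),
                                         photons = as.numeric(ph)),
                              exposure = expo)
    expect_equal(r$mean, 8000, tolerance = 0.02)
  }
})

test_that("center-frame estimator recovers the rate where the naive mean is low", {
  set.seed(34)
  ev <- generate_event_stream(0.35, 10, 30000)
  d <- discretize_events(ev, 0.1, 6000)
  ph <- tapply(d$photons, d$frame, sum)
  d <- data.frame(frame = as.integer(names(ph)), photons = as.numeric(ph))
  cf <- center_frame_photons(d, 0.1)
  expect_equal(cf$mean, 6000, tolerance = 0.02)
  expect_lt(mean(d$photons), 0.9 * cf$mean)
})

test_that("SBR matches the pixel-integral closed form and 2D quadrature", {
  expect_equal(compute_sbr(1000, 10, 1, 1), 14.66, tolerance = 1e-3)
  expect_equal(compute_sbr(0, 10, 1, 1), 0)
  # point-mass limit: the pixel integral tends to N
  expect_equal(compute_sbr(500, 10, 1e-4, 1e-4), 50, tolerance = 1e-9)
  # numeric 2D quadrature oracle over a grid of PSF widths
  quad <- function(N, sx, sy) {
    fx <- function(x) exp(-x^2 / (2 * sx^2)) / (sqrt(2 * pi) * sx)
    fy <- function(y) exp(-y^2 / (2 * sy^2)) / (sqrt(2 * pi) * sy)
    N * stats::integrate(fx, -0.5, 0.5, rel.tol = 1e-10)$value *
      stats::integrate(fy, -0.5, 0.5, rel.tol = 1e-10)$value
  }
  for (sx in c(0.5, 1, 1.7, 2.5)) for (sy in c(0.5, 1.2, 2.5)) {
    got <- compute_sbr(2000, 25, sx, sy)
    want <- quad(2000, sx, sy) / 25
    expect_lt(abs(got - want) / want, 1e-4)
  }
  # excluded when background is non-positive
  expect_true(is.na(compute_sbr(100, 0, 1, 1)))
})

test_that("stability trace is flat for stationary kinetics", {
  s <- small_sim(seed = 41, n_sites = 300, n_frames = 2000, tau_d = 2)
  locs <- s$sim$locs
  st <- stability_trace(locs, 0.1, 2000, window_s = 20)
  expect_equal(nrow(st$trace), 10)
  expect_lt(abs(st$drop_pct_raw), 5)
})

test_that("on-rate decay produces the predicted localization drop", {
  # alternating-renewal event rate at time t is 1 / (tau_d exp(decay t) + tau_b);
  # choose decay so the last-window rate is half the first-window rate
  tau_b <- 0.35; tau_d <- 2; t1 <- 10; t2 <- 190
  decay <- stats::uniroot(function(l)
    (tau_d * exp(l * t1) + tau_b) / (tau_d * exp(l * t2) + tau_b) - 0.5,
    c(1e-5, 0.1))$root
  cfg <- sim_config(tau_b = tau_b, tau_d = tau_d, n_frames = 2000,
                    photon_rate = 5000, width = 128, height = 128,
                    onrate_decay = decay,
                    layout = layout_single_sites(400, 128, 128), seed = 6)
  locs <- emit_localizations(cfg)$locs
  st <- stability_trace(locs, 0.1, 2000, window_s = 20)
  expect_lt(abs(st$drop_pct - 50), 6)
})

test_that("a single-window measurement is an error", {
  s <- small_sim(seed = 43, n_sites = 9, n_frames = 100)
  expect_error(stability_trace(s$sim$locs, 0.1, 100, window_s = 20),
               "two stability windows")
})

test_that("destruction statistic recovers an exponential ratio histogram", {
  set.seed(51)
  d <- destruction_statistic(rexp(1e4))
  expect_equal(d$mu, 1.0, tolerance = 0.05)
  expect_lt(d$destroyed_pct, 0.5)
  # all sites sampled to the end: nothing destroyed after clamping
  set.seed(52)
  d0 <- destruction_statistic(runif(500, 0, 0.2))
  expect_equal(d0$destroyed_pct, 0)
})

test_that("destruction tail correction is the analytic exponential tail", {
  expect_equal(destruction_tail_correction(), 100 * exp(-4))
  expect_equal(destruction_tail_correction(2), 100 * exp(-2))
})

test_that("destruction estimate increases with the true destroyed fraction", {
  est <- vapply(c(0, 0.1, 0.2, 0.4), function(f) {
    cfg <- sim_config(tau_b = 0.35, tau_d = 2, n_frames = 3000,
                      photon_rate = 5000, width = 128, height = 128,
                      destroy_fraction = f,
                      layout = layout_single_sites(400, 128, 128),
                      seed = 61)
    a <- analyze_origami(emit_localizations(cfg)$locs, min_sites = 50,
                         nena = FALSE)
    a$destruction$destroyed_pct
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
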
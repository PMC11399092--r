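test_that("event stream durations follow the configured exponential means", {
  set.seed(101)
  ev <- generate_event_stream(2.0, 5.0, duration_s = 1.4e5)
  bright <- ev$t_end - ev$t_start
  dark <- ev$t_start[-1] - ev$t_end[-nrow(ev)]
  expect_gt(nrow(ev), 1.5e4)
  expect_equal(mean(bright), 2.0, tolerance = 0.02)
  expect_equal(mean(dark), 5.0, tolerance = 0.02)
  # relative error bound of the spec-level invariant
  expect_lt(abs(mean(bright) - 2.0) / 2.0, 3 / sqrt(nrow(ev)))
})

test_that("degenerate and invalid event-stream inputs are handled", {
  expect_identical(nrow(generate_event_stream(1, 1, 0)), 0L)
  expect_identical(nrow(generate_event_stream(1, 1, 5, destruction_time = 0)), 0L)
  expect_error(generate_event_stream(0, 1, 10), "tau_b")
  expect_error(generate_event_stream(1, -2, 10), "tau_d")
})

test_that("events never start after destruction and stop at the cutoff", {
  set.seed(5)
  ev <- generate_event_stream(0.5, 1, duration_s = 100, destruction_time = 37.3)
  expect_true(all(ev$t_start < 37.3))
  expect_true(all(ev$t_end <= 37.3))
})

test_that("on-rate decay thins late events", {
  set.seed(42)
  ev <- do.call(rbind, lapply(1:300, function(i)
    generate_event_stream(0.3, 2, duration_s = 100, onrate_decay = 0.05)))
  early <- sum(ev$t_start < 20)
  late <- sum(ev$t_start >= 80)
  # rate at t is exp(-0.05 t): expect roughly exp(-4)/1 ratio between windows
  expect_lt(late, early / 10)
})

test_that("stationary streams have uniform event counts over time", {
  set.seed(77)
  ev <- generate_event_stream(0.35, 2, duration_s = 3e4)
  expect_gt(nrow(ev), 1e4)
  win <- cut(ev$t_start, breaks = seq(0, 3e4, length.out = 21))
  p <- suppressWarnings(stats::chisq.test(table(win))$p.value)
  expect_gt(p, 0.01)
})

test_that("discretization maps events to the correct frames and fractions", {
  d <- discretize_events(data.frame(t_start = 0.0, t_end = 0.2), 0.1, 0)
  expect_equal(d$frame, c(0L, 1L))
  expect_equal(d$fraction, c(1, 1))
  d2 <- discretize_events(data.frame(t_start = 0.05, t_end = 0.25), 0.1, 0)
  expect_equal(d2$frame, 0:2)
  expect_equal(d2$fraction, c(0.5, 1, 0.5))
  expect_true(all(d2$fraction > 0 & d2$fraction <= 1))
})

test_that("per-event expected photons are conserved under discretization", {
  set.seed(3)
  ev <- generate_event_stream(0.35, 1, duration_s = 200)
  d <- discretize_events(ev, 0.1, 0)
  # sum of fractions * exposure = event duration, exactly
  by_ev <- tapply(d$fraction, d$event, sum) * 0.1
  durations <- (ev$t_end - ev$t_start)[as.integer(names(by_ev))]
  expect_equal(as.numeric(by_ev), durations, tolerance = 1e-9)
})

test_that("discretized photon draws have the configured Poisson mean", {
  set.seed(8)
  d <- discretize_events(data.frame(t_start = rep(0, 4000),
                                    t_end = rep(0.05, 4000)), 0.1, 1e4)
  expect_equal(mean(d$photons), 5000, tolerance = 0.01)
})

test_that("simulated tables are deterministic given the seed", {
  cfg <- sim_config(n_frames = 200, photon_rate = 3000,
                    layout = layout_single_sites(9), seed = 11)
  a <- emit_localizations(cfg)
  b <- emit_localizations(cfg)
  expect_identical(a$locs, b$locs)
  expect_identical(a$truth, b$truth)
})

test_that("localizations scatter around their site at the Mortensen scale", {
  s <- small_sim(seed = 21, n_sites = 16, n_frames = 600)
  locs <- s$sim$locs
  sites <- s$sim$truth$sites
  on <- as.data.frame(locs)[locs$site != 0, ]
  dx <- on$x - sites$x[match(on$site, sites$site)]
  dy <- on$y - sites$y[match(on$site, sites$site)]
  d <- sqrt(dx^2 + dy^2) / on$lpx
  expect_gt(mean(d < 5), 0.9999 - 3 / sqrt(nrow(on)))
})

test_that("all sites destroyed at t = 0 yields an empty table", {
  cfg <- sim_config(n_frames = 300, destroy_fraction = 1,
                    destroy_timing = "start",
                    layout = layout_single_sites(9), seed = 2)
  out <- emit_localizations(cfg)
  expect_identical(nrow(out$locs), 0L)
})

test_that("site layouts have distinct positions and the advertised counts", {
  g <- layout_grid20(4)
  expect_equal(nrow(g$positions), 48)
  expect_false(anyDuplicated(g$positions[, c("x", "y")]) > 0)
  ch <- layout_crosshair(3)
  expect_equal(nrow(ch$positions), 15)
  expect_equal(sum(ch$positions$is_target), 3)
  npc <- layout_npc(2)
  expect_equal(nrow(npc$positions), 32)
  # 20 nm spacing in pixels
  p1 <- g$positions[g$positions$structure == 1, ]
  expect_equal(min(dist(p1[, c("x", "y")])), 20 / 130, tolerance = 1e-9)
})

test_that("rendered movies conserve photons", {
  cfg <- sim_config(n_frames = 2, photon_rate = 5000, bg_rate = 0,
                    width = 64, height = 64,
                    layout = layout_custom(data.frame(x = 32.3, y = 30.7)),
                    seed = 4)
  tab <- loc_table(data.frame(frame = 0L, x = 32.3, y = 30.7, photons = 5000,
                              bg = 0, sx = 1, sy = 1),
                   exposure = 0.1, pixel_size = 130, width = 64, height = 64)
  mv <- render_movie(tab, cfg, noise = FALSE)
  expect_equal(sum(mv[, , 1]), 5000, tolerance = 1e-3)
  expect_equal(sum(mv[, , 2]), 0)
  # pixel-integrated mass within 1e-3 relative for a well-contained PSF
  expect_lt(abs(sum(mv[, , 1]) - 5000) / 5000, 1e-3)
})

test_that("a movie with no emitters and no background is identically zero", {
  cfg <- sim_config(n_frames = 3, bg_rate = 0, width = 16, height = 16,
                    layout = layout_single_sites(1, 16, 16), seed = 1)
  empty <- loc_table(data.frame(frame = integer(0), x = numeric(0),
                                y = numeric(0), photons = numeric(0),
                                bg = numeric(0), sx = numeric(0),
                                sy = numeric(0)),
                     exposure = 0.1, pixel_size = 130, width = 16, height = 16)
  mv <- render_movie(empty, cfg, noise = FALSE)
  expect_true(all(mv == 0))
})
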
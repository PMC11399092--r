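test_that("clustering matches a brute-force density oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 300
    centers <- data.frame(x = runif(6, 1, 9), y = runif(6, 1, 9))
    k <- sample.int(6, n, replace = TRUE)
    locs <- data.frame(x = centers$x[k] + rnorm(n, 0, 0.02),
                       y = centers$y[k] + rnorm(n, 0, 0.02))
    # add sparse noise
    locs <- rbind(locs, data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10)))
    got <- cluster_smlm(locs, radius = 0.06, min_locs = 10)
    want <- brute_force_cluster(locs, 0.06, 10)
    # same partition up to label permutation
    expect_equal(is.na(got$cluster), is.na(want))
    ok <- !is.na(want)
    expect_equal(length(unique(got$cluster[ok])), length(unique(want[ok])))
    tab <- table(got$cluster[ok], want[ok])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("clustering is invariant to input order", {
  set.seed(102)
  locs <- data.frame(x = c(rnorm(30, 2, 0.01), rnorm(30, 5, 0.01)),
                     y = c(rnorm(30, 2, 0.01), rnorm(30, 5, 0.01)))
  a <- cluster_smlm(locs, 0.04, 15)
  perm <- sample.int(nrow(locs))
  b <- cluster_smlm(locs[perm, ], 0.04, 15)
  expect_equal(a$cluster[perm], b$cluster)
  expect_equal(a$clusters[, c("x", "y", "n_locs")],
               b$clusters[, c("x", "y", "n_locs")])
})

test_that("the min_locs threshold is exact", {
  set.seed(103)
  pts14 <- data.frame(x = 5 + runif(14, -0.01, 0.01),
                      y = 5 + runif(14, -0.01, 0.01))
  expect_equal(nrow(cluster_smlm(pts14, 0.04, 15)$clusters), 0L)
  pts15 <- rbind(pts14, data.frame(x = 5, y = 5))
  expect_equal(nrow(cluster_smlm(pts15, 0.04, 15)$clusters), 1L)
})

test_that("well-separated blobs give exactly one cluster each", {
  set.seed(104)
  blob <- function(cx, cy) data.frame(x = cx + rnorm(20, 0, 0.02),
                                      y = cy + rnorm(20, 0, 0.02))
  locs <- rbind(blob(3, 3), blob(4, 3))
  cl <- cluster_smlm(locs, radius = 0.04, min_locs = 15)
  expect_equal(nrow(cl$clusters), 2L)
})

test_that("sparse uniform noise yields no clusters", {
  set.seed(105)
  hits <- vapply(1:20, function(i) {
    locs <- data.frame(x = runif(200, 0, 50), y = runif(200, 0, 50))
    nrow(cluster_smlm(locs, radius = 0.04, min_locs = 15)$clusters)
  }, numeric(1))
  expect_true(all(hits == 0))
})

crosshair_fixture <- function(seed, n_structures = 30, destroy_fraction = 0) {
  cfg <- sim_config(tau_b = 0.35, tau_d = 1, n_frames = 600,
                    photon_rate = 20000, width = 64, height = 64,
                    destroy_fraction = destroy_fraction,
                    destroy_timing = "start",
                    layout = layout_crosshair(n_structures, 64, 64, margin = 3),
                    seed = seed)
  list(cfg = cfg, sim = emit_localizations(cfg))
}

test_that("complete crosshairs are accepted, incomplete or noisy ones rejected", {
  fx <- crosshair_fixture(seed = 111)
  lay <- fx$cfg$layout$positions
  centers <- lay[lay$is_target, ]
  picks <- region_picks(centers$x, centers$y, diameter = 1.5)
  hits <- find_crosshairs(fx$sim$locs, picks, radius = 0.04, min_locs = 15)
  expect_equal(nrow(hits), nrow(picks))
  # returned positions are near the central (target) site
  d <- sqrt((hits$x - centers$x[hits$pick])^2 + (hits$y - centers$y[hits$pick])^2)
  expect_true(all(d < 0.05))
  # destroy one site of the first structure from t = 0: 4 clusters, rejected
  fx2 <- crosshair_fixture(seed = 112, destroy_fraction = 0.08)
  destroyed_structs <- unique(fx2$sim$truth$sites$structure[
    fx2$sim$truth$sites$destroyed])
  hits2 <- find_crosshairs(fx2$sim$locs, picks, radius = 0.04, min_locs = 15)
  expect_false(any(hits2$pick %in% destroyed_structs))
  ncl <- attr(hits2, "n_clusters")
  expect_true(all(ncl[destroyed_structs] < 5))
})

test_that("crosshair acceptance rate approaches (1 - f)^5", {
  f <- 0.12
  accepted <- 0L; total <- 0L
  for (seed in 1:6) {
    fx <- crosshair_fixture(seed = 120 + seed, n_structures = 36,
                            destroy_fraction = f)
    lay <- fx$cfg$layout$positions
    centers <- lay[lay$is_target, ]
    picks <- region_picks(centers$x, centers$y, diameter = 1.5)
    hits <- find_crosshairs(fx$sim$locs, picks, radius = 0.04, min_locs = 15)
    accepted <- accepted + nrow(hits)
    total <- total + nrow(picks)
  }
  p <- accepted / total
  want <- (1 - f)^5
  # binomial check: within 3 standard errors
  expect_lt(abs(p - want), 3 * sqrt(want * (1 - want) / total) + 1e-9)
})

test_that("relative specificity cancels global concentration factors", {
  set.seed(131)
  n <- 3000
  mk <- function(bg_scale = 1, global = 1) {
    ns <- round(1000 * global); nb <- round(n * bg_scale * global)
    df <- rbind(
      data.frame(x = 8 + rnorm(ns, 0, 0.3), y = 8 + rnorm(ns, 0, 0.3)),
      data.frame(x = runif(nb, 16, 32), y = runif(nb, 0, 32)))
    df <- df[df$x >= 0 & df$x < 32 & df$y >= 0 & df$y < 32, ]
    df$frame <- seq_len(nrow(df)) - 1L
    df$photons <- 1; df$bg <- 1; df$sx <- 1; df$sy <- 1
    loc_table(df, 0.1, 130, 32, 32)
  }
  sig <- region_picks(8, 8, diameter = 4)
  bgr <- region_picks(24, 16, diameter = 10, role = "background")
  ref <- mk()
  # identical tables: R = 1
  expect_equal(relative_specificity(ref, ref, sig, bgr)$R, 1)
  # doubled background density in the imaging round: R = 0.5
  img <- mk(bg_scale = 2)
  expect_equal(relative_specificity(img, ref, sig, bgr)$R, 0.5,
               tolerance = 0.1)
  # global scaling (imager concentration) leaves R unchanged
  img2 <- mk(global = 2)
  expect_equal(relative_specificity(img2, ref, sig, bgr)$R, 1,
               tolerance = 0.1)
})

test_that("mask-based specificity works and area units cancel", {
  set.seed(132)
  mk <- function(n_in, n_out) {
    df <- rbind(data.frame(x = runif(n_in, 0, 16), y = runif(n_in, 0, 32)),
                data.frame(x = runif(n_out, 16, 32), y = runif(n_out, 0, 32)))
    df$frame <- seq_len(nrow(df)) - 1L
    df$photons <- 1; df$bg <- 1; df$sx <- 1; df$sy <- 1
    loc_table(df, 0.1, 130, 32, 32)
  }
  m <- matrix(0, 32, 32); m[, 1:16] <- 1
  msk <- region_mask(m, mask_pixel_size = 130)
  ref <- mk(2000, 1000)
  img <- mk(2000, 2000)
  res <- relative_specificity(img, ref, msk)
  expect_equal(res$R, 0.5, tolerance = 0.02)
  # same mask declared at different (consistent) pixel size: identical R
  msk2 <- region_mask(m, mask_pixel_size = 130)
  expect_equal(relative_specificity(img, ref, msk2)$R, res$R)
})

test_that("zero background counts raise an informative error", {
  tb <- tiny_table(20, width = 16, height = 16)
  sig <- region_picks(8, 8, diameter = 30)
  bgr <- region_picks(100, 100, diameter = 0.1, role = "background")
  expect_error(
    suppressWarnings(relative_specificity(tb, tb, sig, bgr)),
    "background")
})
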
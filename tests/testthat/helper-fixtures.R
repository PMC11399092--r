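# fixtures built in code; kept small so the default run stays fast

# a minimal valid localization table
tiny_table <- function(n = 10, width = 16, height = 16, seed = 1) {
  withr::with_seed(seed, {
    loc_table(data.frame(frame = sort(sample(0:(2 * n), n)),
                         x = runif(n, 0, width), y = runif(n, 0, height),
                         photons = runif(n, 100, 5000),
                         bg = runif(n, 1, 30),
                         sx = runif(n, 0.8, 1.2), sy = runif(n, 0.8, 1.2)),
              exposure = 0.1, pixel_size = 130, width = width, height = height)
  })
}

# isolated sites revisited in adjacent frames with known isotropic jitter;
# used for NeNA ground-truth recovery
jitter_table <- function(sigma_nm, n_sites = 40, frames_per_site = 60,
                         pixel_size = 130, width = 64, height = 64, seed = 1) {
  sigma_px <- sigma_nm / pixel_size
  withr::with_seed(seed, {
    anchors <- expand.grid(x = seq(4, width - 4, length.out = ceiling(sqrt(n_sites))),
                           y = seq(4, height - 4, length.out = ceiling(sqrt(n_sites))))
    anchors <- anchors[seq_len(n_sites), ]
    rows <- lapply(seq_len(n_sites), function(i) {
      f <- seq_len(frames_per_site) - 1L
      data.frame(frame = f,
                 x = anchors$x[i] + rnorm(length(f), 0, sigma_px),
                 y = anchors$y[i] + rnorm(length(f), 0, sigma_px),
                 photons = 2000, bg = 10, sx = 1, sy = 1)
    })
    df <- do.call(rbind, rows)
    df$x <- pmin(pmax(df$x, 0), width - 1e-9)
    df$y <- pmin(pmax(df$y, 0), height - 1e-9)
    loc_table(df, exposure = 0.1, pixel_size = pixel_size,
              width = width, height = height)
  })
}

# O(n^2) density-clustering oracle: neighbour counts, core points,
# connected components; canonical (x, y) order like the implementation
brute_force_cluster <- function(locs, radius, min_locs) {
  n <- nrow(locs)
  d2 <- as.matrix(dist(locs[, c("x", "y")]))^2
  nb <- d2 <= radius^2
  core <- rowSums(nb) >= min_locs
  lab <- rep(NA_integer_, n)
  ord <- order(locs$x, locs$y)
  cid <- 0L
  for (i in ord[core[ord]]) {
    if (!is.na(lab[i])) next
    cid <- cid + 1L
    queue <- i; lab[i] <- cid
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      for (k in which(nb[j, ])) {
        if (core[k] && is.na(lab[k])) { lab[k] <- cid; queue <- c(queue, k) }
        else if (!core[k] && is.na(lab[k])) lab[k] <- cid
      }
    }
  }
  lab
}

# small end-to-end simulation reused by several tests
small_sim <- function(seed = 7, n_sites = 50, n_frames = 1000, tau_d = 2,
                      destroy_fraction = 0, ...) {
  cfg <- sim_config(tau_b = 0.35, tau_d = tau_d, n_frames = n_frames,
                    photon_rate = 5000, width = 64, height = 64,
                    destroy_fraction = destroy_fraction,
                    layout = layout_single_sites(n_sites, 64, 64),
                    seed = seed, ...)
  list(cfg = cfg, sim = emit_localizations(cfg))
}
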
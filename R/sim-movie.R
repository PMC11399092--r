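#' Render a synthetic raw movie from simulated emitters
#'
#' Produces a photon-count image stack: each frame is the sum of
#' pixel-integrated 2D Gaussian spots (one per localization scheduled in
#' that frame, with its drawn photon total and the config PSF width) plus
#' Poisson background at `bg_rate` per pixel. Pixel integration uses the
#' Gaussian CDF difference per axis, so rendered mass equals the photon
#' total up to boundary truncation. No camera gain, offset or read noise is
#' applied; pixel units are photons.
#'
#' @param sim result of [emit_localizations()] (its `locs` table provides
#'   positions, frames and photon counts), or a bare [loc_table].
#' @param config the [sim_config()] used for the simulation (dimensions,
#'   PSF width, background, seed).
#' @param noise draw Poisson photon/background noise per pixel (`TRUE`) or
#'   return the noiseless expectation plus constant background (`FALSE`).
#'
#' @return numeric array `height x width x n_frames` (photons). Write it
#'   with [write_movie()].
#' @export
render_movie <- function(sim, config, noise = TRUE) {
  validate_sim_config(config)
  locs <- if (is.list(sim) && !is.null(sim$locs)) sim$locs else sim
  withr::with_seed(config$seed + 1L,
                   render_movie_impl(as.data.frame(locs), config, noise))
}

render_movie_impl <- function(df, cfg, noise) {
  h <- cfg$height; w <- cfg$width
  movie <- array(0, dim = c(h, w, cfg$n_frames))
  for (i in seq_len(nrow(df))) {
    f <- df$frame[i] + 1L
    if (f < 1L || f > cfg$n_frames) next
    movie[, , f] <- movie[, , f] +
      spot_image(h, w, df$x[i], df$y[i], df$photons[i], cfg$psf_sigma)
  }
  if (noise) {
    movie[] <- rpois(length(movie), lambda = movie + cfg$bg_rate)
  } else {
    movie <- movie + cfg$bg_rate
  }
  movie
}

# pixel-integrated 2D Gaussian: pixel (row r, col c) covers
# x in [c-1, c), y in [r-1, r) in continuous coordinates
spot_image <- function(h, w, x, y, N, sigma) {
  px <- pnorm(seq_len(w), mean = x, sd = sigma) -
    pnorm(seq_len(w) - 1, mean = x, sd = sigma)
  py <- pnorm(seq_len(h), mean = y, sd = sigma) -
    pnorm(seq_len(h) - 1, mean = y, sd = sigma)
  N * outer(py, px)
}
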
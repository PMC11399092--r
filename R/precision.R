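#' Mortensen localization precision for a pixelated Gaussian PSF
#'
#' Closed-form per-localization precision of a least-squares Gaussian fit,
#' from photon count, per-pixel background, PSF width and pixel size:
#' \deqn{\sigma^2 = \frac{s_a^2}{N}\left(\frac{16}{9} +
#'   \frac{8\pi s_a^2 b}{N a^2}\right), \qquad s_a^2 = s^2 + a^2/12,}
#' where `N` is the total fitted photon count, `b` the expected background
#' photons per pixel, `s` the PSF standard deviation and `a` the pixel size,
#' all in consistent units (the default `a = 1` keeps everything in pixels).
#'
#' @param N total photons of the localization (> 0); vectorized.
#' @param b background photons per pixel (>= 0); vectorized.
#' @param s PSF standard deviation (> 0), same units as `a`; vectorized.
#' @param a pixel size (> 0); default 1 (pixel units).
#'
#' @return Localization precision sigma, in the units of `s` and `a`.
#' @examples
#' mortensen_sigma(N = 1600, b = 0, s = sqrt(1.2^2 - 1 / 12))  # 0.04 px
#' @export
mortensen_sigma <- function(N, b, s, a = 1) {
  if (any(!is.finite(N)) || any(N <= 0)) stop("N must be > 0")
  if (any(b < 0)) stop("b must be >= 0")
  if (any(s <= 0)) stop("s must be > 0")
  if (any(a <= 0)) stop("a must be > 0")
  sa2 <- s^2 + a^2 / 12
  sqrt((sa2 / N) * (16 / 9 + (8 * pi * sa2 * b) / (N * a^2)))
}

#' Average localization precision by nearest-neighbour analysis (NeNA)
#'
#' Estimates the average localization precision of a measurement from the
#' distances between localizations in adjacent frames. A docking site that is
#' bound in frames i and i+1 yields two independent localizations of the same
#' emitter; their distance follows the 2D distribution of the difference of
#' two isotropic Gaussians of width sigma,
#' \deqn{p_{same}(d) = \frac{d}{2\sigma^2} e^{-d^2 / 4\sigma^2},}
#' while false pairings (different sites, sticking) contribute a slowly
#' varying term, modelled as a linear density `2 d / W^2` over the search
#' window `W = max_distance`. The mixture
#' `A * p_same(d) + (1 - A) * 2 d / W^2` is fitted to the binned distance
#' histogram by least squares.
#'
#' @param locs a [loc_table] (or data.frame with `frame`, `x`, `y`).
#' @param max_distance nearest-neighbour search window, pixels.
#' @param frame_gap frame offset between paired frames (default 1, adjacent).
#' @param bin_width histogram bin width, pixels.
#' @param min_pairs minimum number of nearest-neighbour pairs required.
#' @param pixel_size nm per pixel for the nm conversion; defaults to the
#'   table metadata, else 130.
#'
#' @return A `nena_result`: list with `sigma_nm`, `sigma_px`, `amplitude`
#'   (same-emitter mixture weight A), `n_pairs`, and `histogram`
#'   (data.frame `d`, `density`, `fit`).
#' @seealso [mortensen_sigma()] for the per-localization counterpart.
#' @export
nena_sigma <- function(locs, max_distance = 1, frame_gap = 1,
                       bin_width = 0.02, min_pairs = 1000,
                       pixel_size = NULL) {
  df <- as.data.frame(locs)
  if (is.null(pixel_size))
    pixel_size <- loc_metadata(locs)$pixel_size %||% 130
  if (max_distance <= 0 || bin_width <= 0) stop("window and bins must be > 0")
  d <- nn_adjacent_distances(df, frame_gap)
  d <- d[is.finite(d) & d <= max_distance]
  if (length(d) < min_pairs)
    stop(sprintf(paste("only %d nearest-neighbour pairs within the window;",
                       "need >= %d - simulate or measure longer"),
                 length(d), min_pairs))
  # near-degenerate jitter: all distances inside one default bin would leave
  # sigma unresolved, so refine the binning to the scale of the data
  hi <- max_distance
  if (quantile(d, 0.9) < 2 * bin_width) {
    bin_width <- max(as.numeric(quantile(d, 0.9)) / 10, 1e-7)
    hi <- min(max_distance, max(d) + 2 * bin_width)
  }
  breaks <- seq(0, hi + bin_width, by = bin_width)
  breaks <- breaks[breaks <= hi + bin_width / 2]
  if (max(breaks) < max(d)) breaks[length(breaks)] <- max(d) + 1e-12
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  dens <- h$counts / (length(d) * bin_width)
  mid <- h$mids
  W <- max_distance
  sigma0 <- max(sqrt(mean(d^2) / 4), bin_width / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ A * (mid / (2 * sigma^2)) * exp(-mid^2 / (4 * sigma^2)) +
        (1 - A) * 2 * mid / W^2,
      start = list(A = 0.9, sigma = sigma0),
      lower = c(A = 0, sigma = 1e-4), upper = c(A = 1, sigma = W),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate histograms (e.g. near-zero jitter): fall back to the moment
    # estimate of the same-emitter term
    sigma_px <- sigma0
    A <- 1
    fitted_curve <- (mid / (2 * sigma_px^2)) * exp(-mid^2 / (4 * sigma_px^2))
  } else {
    co <- coef(fit)
    sigma_px <- unname(co["sigma"])
    A <- unname(co["A"])
    fitted_curve <- stats::fitted(fit)
  }
  structure(list(sigma_nm = sigma_px * pixel_size, sigma_px = sigma_px,
                 amplitude = A, n_pairs = length(d),
                 histogram = data.frame(d = mid, density = dens,
                                        fit = as.numeric(fitted_curve))),
            class = "nena_result")
}

#' @export
print.nena_result <- function(x, ...) {
  cat(sprintf("NeNA precision: %.3f nm (%.4f px) from %d pairs, A = %.2f\n",
              x$sigma_nm, x$sigma_px, x$n_pairs, x$amplitude))
  invisible(x)
}

# nearest-neighbour distance from each localization in frame f to the
# localizations in frame f + gap
nn_adjacent_distances <- function(df, gap) {
  sp <- split(seq_len(nrow(df)), df$frame)
  frames <- as.integer(names(sp))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    j <- match(as.character(frames[k] + gap), names(sp))
    if (is.na(j)) next
    ia <- sp[[k]]; ib <- sp[[j]]
    dx <- outer(df$x[ia], df$x[ib], "-")
    dy <- outer(df$y[ia], df$y[ib], "-")
    dd <- sqrt(dx * dx + dy * dy)
    out[[k]] <- if (length(ib) == 1L) as.numeric(dd) else apply(dd, 1L, min)
  }
  unlist(out, use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
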
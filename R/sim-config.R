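#' Site layouts for simulated DNA-PAINT samples
#'
#' A site layout places docking sites (single-stranded DNA binding sites) in
#' the camera field of view, in continuous pixel coordinates with the origin
#' at the top-left pixel corner. Structures (origami, nuclear pores) are laid
#' out on a coarse grid with a margin so that neighbouring structures do not
#' overlap optically.
#'
#' Available geometries:
#' \describe{
#'   \item{`layout_single_sites()`}{isolated single docking sites on a square
#'     grid; the workhorse for kinetic and destruction analyses.}
#'   \item{`layout_grid20()`}{origami displaying a 3 x 4 raster of docking
#'     strands at 20 nm spacing, the classic resolution test structure.}
#'   \item{`layout_crosshair()`}{origami carrying one central dye-of-interest
#'     docking site plus four barcode sites on the arms; a correctly folded,
#'     complete structure therefore shows exactly five localization clusters.}
#'   \item{`layout_npc()`}{nuclear-pore-like rings: eightfold radially
#'     symmetric arrangement of Nup96 pairs on a ring.}
#'   \item{`layout_custom()`}{caller-supplied positions.}
#' }
#'
#' @param n_structures,n_sites number of structures (or isolated sites) to place.
#' @param width,height field of view in pixels.
#' @param margin margin kept free at the field edge, pixels.
#' @param pixel_size camera pixel size in nm (default 130).
#' @param spacing_nm docking-strand spacing of the 20-nm grid origami, nm.
#' @param arm_nm crosshair arm length (center to barcode site), nm.
#' @param ring_radius_nm radius of the Nup96 ring, nm.
#' @param pair_sep_nm separation of the two sites of one Nup96 pair, nm.
#' @param positions data.frame with columns `x`, `y` (pixels) for
#'   `layout_custom()`; optional columns `structure`, `site`, `is_target`.
#'
#' @return A `site_layout` object: list with elements `kind`, `positions`
#'   (data.frame `site`, `structure`, `x`, `y`, `is_target`) and `metadata`.
#'   `is_target` marks the dye-of-interest site within a structure (all sites
#'   for plain geometries).
#' @examples
#' lay <- layout_single_sites(25, width = 64, height = 64)
#' nrow(lay$positions)
#' @name site_layout
NULL

new_site_layout <- function(kind, positions, metadata = list()) {
  stopifnot(is.data.frame(positions), nrow(positions) > 0L)
  if (is.null(positions$structure)) positions$structure <- seq_len(nrow(positions))
  if (is.null(positions$is_target)) positions$is_target <- TRUE
  positions$site <- seq_len(nrow(positions))
  positions <- positions[, c("site", "structure", "x", "y", "is_target")]
  if (anyDuplicated(positions[, c("x", "y")]))
    stop("site layout positions must be pairwise distinct")
  structure(list(kind = kind, positions = positions, metadata = metadata),
            class = "site_layout")
}

# coarse grid of structure anchor points with margin
structure_anchors <- function(n, width, height, margin) {
  k <- ceiling(sqrt(n))
  if (width - 2 * margin <= 0 || height - 2 * margin <= 0)
    stop("field of view too small for the requested margin")
  gx <- seq(margin, width - margin, length.out = max(k, 2L))
  gy <- seq(margin, height - margin, length.out = max(k, 2L))
  g <- expand.grid(x = gx, y = gy)
  g[seq_len(n), , drop = FALSE]
}

#' @rdname site_layout
#' @export
layout_single_sites <- function(n_sites, width = 64, height = 64, margin = 2) {
  a <- structure_anchors(n_sites, width, height, margin)
  new_site_layout("custom",
                  data.frame(structure = seq_len(n_sites), x = a$x, y = a$y,
                             is_target = TRUE),
                  metadata = list(n_sites = n_sites))
}

#' @rdname site_layout
#' @export
layout_grid20 <- function(n_structures, width = 64, height = 64, margin = 2,
                          spacing_nm = 20, pixel_size = 130) {
  a <- structure_anchors(n_structures, width, height, margin)
  d <- spacing_nm / pixel_size
  offs <- expand.grid(dx = (0:2) * d, dy = (0:3) * d)  # 12 sites, 3 x 4
  offs$dx <- offs$dx - mean(range(offs$dx))
  offs$dy <- offs$dy - mean(range(offs$dy))
  pos <- do.call(rbind, lapply(seq_len(n_structures), function(i) {
    data.frame(structure = i, x = a$x[i] + offs$dx, y = a$y[i] + offs$dy,
               is_target = TRUE)
  }))
  new_site_layout("grid20", pos,
                  metadata = list(spacing_nm = spacing_nm, sites_per_structure = 12L))
}

#' @rdname site_layout
#' @export
layout_crosshair <- function(n_structures, width = 64, height = 64, margin = 2,
                             arm_nm = 40, pixel_size = 130) {
  a <- structure_anchors(n_structures, width, height, margin)
  d <- arm_nm / pixel_size
  offs <- data.frame(dx = c(0, -d, d, 0, 0), dy = c(0, 0, 0, -d, d),
                     is_target = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  pos <- do.call(rbind, lapply(seq_len(n_structures), function(i) {
    data.frame(structure = i, x = a$x[i] + offs$dx, y = a$y[i] + offs$dy,
               is_target = offs$is_target)
  }))
  new_site_layout("crosshair", pos,
                  metadata = list(arm_nm = arm_nm, sites_per_structure = 5L,
                                  target_offset = c(0, 0)))
}

#' @rdname site_layout
#' @export
layout_npc <- function(n_structures, width = 64, height = 64, margin = 2,
                       ring_radius_nm = 53.7, pair_sep_nm = 12,
                       pixel_size = 130) {
  a <- structure_anchors(n_structures, width, height, margin)
  r <- ring_radius_nm / pixel_size
  half <- (pair_sep_nm / 2) / ring_radius_nm  # angular half separation, rad
  ang <- rep(seq(0, 2 * pi, length.out = 9L)[1:8], each = 2L) +
    rep(c(-half, half), times = 8L)
  pos <- do.call(rbind, lapply(seq_len(n_structures), function(i) {
    data.frame(structure = i, x = a$x[i] + r * cos(ang),
               y = a$y[i] + r * sin(ang), is_target = TRUE)
  }))
  new_site_layout("npc", pos,
                  metadata = list(ring_radius_nm = ring_radius_nm,
                                  pair_sep_nm = pair_sep_nm,
                                  sites_per_structure = 16L))
}

#' @rdname site_layout
#' @export
layout_custom <- function(positions) {
  if (is.null(positions$x) || is.null(positions$y))
    stop("custom layout needs columns 'x' and 'y'")
  new_site_layout("custom", positions)
}

#' Simulation configuration for synthetic DNA-PAINT data
#'
#' Bundles the full generative model: two-state (bright/dark) exponential
#' binding kinetics, photon emission, background, acquisition geometry, and
#' the degradation processes that the downstream estimators are designed to
#' detect (docking-site destruction, decaying effective on-rate, unspecific
#' sticking).
#'
#' Defaults correspond to the benchmark conditions of a well-performing
#' green-excited dye (Cy3B-like): mean bright time 0.35 s, ~23,000 photons
#' per 100 ms when fully bound, 100 ms frames, 130 nm pixels.
#'
#' @param tau_b mean bright (bound) time, seconds.
#' @param tau_d mean dark (unbound) time, seconds.
#' @param photon_rate expected photons collected from a fully bound imager in
#'   100 ms.
#' @param bg_rate expected background photons per pixel per frame.
#' @param exposure frame exposure time, seconds.
#' @param n_frames number of frames in the acquisition.
#' @param pixel_size camera pixel size, nm.
#' @param psf_sigma PSF standard deviation, pixels.
#' @param width,height image dimensions, pixels.
#' @param destroy_fraction fraction of docking sites destroyed during the
#'   acquisition, in `[0, 1]`.
#' @param destroy_timing `"uniform"` draws each destruction time uniformly on
#'   the acquisition; `"start"` destroys at t = 0 (useful for structure
#'   completeness tests).
#' @param onrate_decay exponential decay constant of the effective imager
#'   on-rate, 1/s; 0 means kinetically stable.
#' @param sticking_density off-target single-frame localizations per square
#'   micrometre per frame.
#' @param layout a [site_layout] object.
#' @param seed integer seed; all randomness in [emit_localizations()] and
#'   [render_movie()] flows from it.
#'
#' @return A validated `sim_config` object (list).
#' @examples
#' cfg <- sim_config(n_frames = 200, layout = layout_single_sites(9))
#' cfg$tau_b
#' @export
sim_config <- function(tau_b = 0.35, tau_d = 5, photon_rate = 23195,
                       bg_rate = 238, exposure = 0.1, n_frames = 2000,
                       pixel_size = 130, psf_sigma = 1.0,
                       width = 64, height = 64,
                       destroy_fraction = 0,
                       destroy_timing = c("uniform", "start"),
                       onrate_decay = 0, sticking_density = 0,
                       layout = layout_single_sites(25, width, height),
                       seed = 1L) {
  destroy_timing <- match.arg(destroy_timing)
  if (!inherits(layout, "site_layout")) stop("'layout' must be a site_layout")
  cfg <- list(tau_b = tau_b, tau_d = tau_d, photon_rate = photon_rate,
              bg_rate = bg_rate, exposure = exposure,
              n_frames = as.integer(n_frames), pixel_size = pixel_size,
              psf_sigma = psf_sigma, width = as.integer(width),
              height = as.integer(height),
              destroy_fraction = destroy_fraction,
              destroy_timing = destroy_timing,
              onrate_decay = onrate_decay,
              sticking_density = sticking_density,
              layout = layout, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is.finite(tau_b) || tau_b <= 0) stop("tau_b must be > 0")
    if (!is.finite(tau_d) || tau_d <= 0) stop("tau_d must be > 0")
    if (exposure <= 0) stop("exposure must be > 0")
    if (photon_rate < 0) stop("photon_rate must be >= 0")
    if (bg_rate < 0) stop("bg_rate must be >= 0")
    if (destroy_fraction < 0 || destroy_fraction > 1)
      stop("destroy_fraction must be in [0, 1]")
    if (onrate_decay < 0) stop("onrate_decay must be >= 0")
    if (sticking_density < 0) stop("sticking_density must be >= 0")
    if (n_frames < 1) stop("n_frames must be >= 1")
    if (psf_sigma <= 0) stop("psf_sigma must be > 0")
    if (pixel_size <= 0) stop("pixel_size must be > 0")
    if (nrow(layout$positions) == 0) stop("layout has no sites")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("DNA-PAINT simulation config\n")
  cat(sprintf("  kinetics: tau_b = %g s, tau_d = %g s, on-rate decay = %g 1/s\n",
              x$tau_b, x$tau_d, x$onrate_decay))
  cat(sprintf("  photons:  %g per 100 ms bound, bg %g /px/frame, PSF sigma %g px\n",
              x$photon_rate, x$bg_rate, x$psf_sigma))
  cat(sprintf("  frames:   %d x %g s, %d x %d px @ %g nm\n",
              x$n_frames, x$exposure, x$width, x$height, x$pixel_size))
  cat(sprintf("  sites:    %d (%s layout), destroy %g (%s), sticking %g /um^2/frame\n",
              nrow(x$layout$positions), x$layout$kind, x$destroy_fraction,
              x$destroy_timing, x$sticking_density))
  cat(sprintf("  seed:     %d\n", x$seed))
  invisible(x)
}
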
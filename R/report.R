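#' End-to-end origami analysis of a localization table
#'
#' Runs the single-docking-site analysis chain on a localization table with
#' known (or identified) site positions: assignment of localizations to
#' sites, per-site event linking and kinetic fits, pooled center-frame
#' photon count, pooled SBR, sampling-stability trace, destruction
#' statistic, and NeNA precision. This is the programmatic equivalent of
#' the origami evaluation that produces one dye-summary row.
#'
#' @param locs a [loc_table] (e.g. from [emit_localizations()], with or
#'   without a `site` column).
#' @param site_positions data.frame `site`, `x`, `y`; defaults to using the
#'   table's own `site` column (simulated ground truth).
#' @param assign_radius gate radius for site assignment, pixels (used only
#'   when `site_positions` is given).
#' @param min_events minimum durations for per-site CDF fits.
#' @param min_sites minimum sites for the destruction statistic.
#' @param window_s stability window, seconds.
#' @param nena logical: also estimate NeNA precision (needs enough
#'   adjacent-frame pairs).
#'
#' @return list with `sites` (per-site data.frame: `site`, `n_locs`,
#'   `n_events`, `tau_b`, `tau_d`, `t_end`, `r`), `photons` (list from
#'   [center_frame_photons()]), `sbr`, `stability`, `destruction`
#'   (a [destruction_statistic()] result or NULL), `nena` (or NULL),
#'   and `summary` (one-row [dye_summary()] data.frame).
#' @export
analyze_origami <- function(locs, site_positions = NULL, assign_radius = 0.5,
                            min_events = 10, min_sites = 100, window_s = 20,
                            nena = TRUE) {
  md <- loc_metadata(locs)
  if (is.null(md)) stop("'locs' must be a loc_table with metadata")
  df <- as.data.frame(locs)
  if (!is.null(site_positions)) {
    df$site <- assign_to_sites(df, site_positions, assign_radius)
    df$site[is.na(df$site)] <- 0L
  }
  if (is.null(df$site))
    stop("no site assignment: pass site_positions or a table with a 'site' column")
  n_frames <- ceiling(max(df$frame + 1L, 1L))

  on_site <- df[df$site != 0L, , drop = FALSE]
  per_site <- lapply(split(on_site, on_site$site), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    k <- site_kinetics(g, md$exposure, n_frames, min_events)
    data.frame(site = g$site[1L], n_locs = nrow(g), n_events = k$n_events,
               tau_b = k$tau_b, tau_d = k$tau_d, t_end = k$t_end, r = k$r)
  })
  sites <- do.call(rbind, per_site)
  rownames(sites) <- NULL

  photons <- center_frame_photons(on_site, md$exposure)
  sbr <- measurement_sbr(on_site)
  stability <- tryCatch(
    stability_trace(on_site, md$exposure, n_frames, window_s),
    error = function(e) NULL)
  destruction <- tryCatch(
    destruction_statistic(sites$r, min_sites = min_sites),
    error = function(e) NULL)
  nena_res <- if (isTRUE(nena))
    tryCatch(nena_sigma(locs), error = function(e) NULL) else NULL

  res <- list(sites = sites, photons = photons, sbr = sbr,
              stability = stability, destruction = destruction,
              nena = nena_res)
  res$summary <- dye_summary(res)
  res
}

#' One dye-summary row
#'
#' Collects the six benchmark metrics of a measurement into a single row:
#' NeNA precision (nm), mean photons per 100 ms, mean bright time (s,
#' unweighted mean of the per-site CDF fits), SBR, localization drop (%)
#' and destroyed binding sites (%). Missing components yield `NA` in their
#' column.
#'
#' @param analysis result of [analyze_origami()] (or a compatible list).
#' @return one-row data.frame with columns `precision_nm`,
#'   `photons_per_100ms`, `bright_time_s`, `sbr`, `loc_drop_pct`,
#'   `destroyed_pct`.
#' @export
dye_summary <- function(analysis) {
  data.frame(
    precision_nm = if (!is.null(analysis$nena)) analysis$nena$sigma_nm else NA_real_,
    photons_per_100ms = analysis$photons$mean %||% NA_real_,
    bright_time_s = if (!is.null(analysis$sites))
      mean(analysis$sites$tau_b, na.rm = TRUE) else NA_real_,
    sbr = analysis$sbr$mean %||% NA_real_,
    loc_drop_pct = if (!is.null(analysis$stability))
      analysis$stability$drop_pct else NA_real_,
    destroyed_pct = if (!is.null(analysis$destruction))
      analysis$destruction$destroyed_pct else NA_real_)
}

#' Mean and standard deviation across repeat measurements
#'
#' Stacks the summary rows of repeat measurements of one dye and reports
#' per-metric mean and standard deviation (sd is `NA` with a single
#' repeat), the usual form of a benchmark table row.
#'
#' @param rows list of one-row data.frames from [dye_summary()].
#' @return data.frame with columns `metric`, `mean`, `sd`, `n`.
#' @export
summarize_repeats <- function(rows) {
  stacked <- do.call(rbind, rows)
  data.frame(
    metric = names(stacked),
    mean = vapply(stacked, mean, numeric(1), na.rm = TRUE),
    sd = if (nrow(stacked) >= 2L)
      vapply(stacked, sd, numeric(1), na.rm = TRUE)
    else rep(NA_real_, ncol(stacked)),
    n = nrow(stacked), row.names = NULL)
}

#' Render a super-resolution image from localizations
#'
#' Draws each localization as a unit-mass isotropic 2D Gaussian with
#' sigma = max(lpx, lpy) (the "individual localization precision, iso"
#' weighting), pixel-integrated on an output raster of pitch
#' `pixel_size_out` nm. Total image mass equals the number of
#' localizations, up to boundary truncation.
#'
#' @param locs a [loc_table] with `lpx`, `lpy` columns (see
#'   [add_precision()]).
#' @param pixel_size_out output (display) pixel size, nm.
#' @param min_sigma_px floor on the rendered sigma in output pixels, to
#'   keep zero-precision localizations drawable (default 0.25).
#'
#' @return numeric matrix (rows = y) of the rendered image.
#' @export
render_image <- function(locs, pixel_size_out = 5, min_sigma_px = 0.25) {
  df <- as.data.frame(locs)
  if (nrow(df) == 0L) stop("empty localization table")
  md <- loc_metadata(locs)
  if (is.null(df$lpx) || is.null(df$lpy))
    stop("table has no lpx/lpy columns; run add_precision() first")
  scale <- md$pixel_size / pixel_size_out  # output px per camera px
  w_out <- ceiling(md$width * scale)
  h_out <- ceiling(md$height * scale)
  img <- matrix(0, h_out, w_out)
  x <- df$x * scale
  y <- df$y * scale
  s <- pmax(pmax(df$lpx, df$lpy) * scale, min_sigma_px)
  for (i in seq_len(nrow(df))) {
    r <- max(ceiling(4 * s[i]), 2L)
    c0 <- max(floor(x[i]) - r, 0L); c1 <- min(floor(x[i]) + r, w_out - 1L)
    r0 <- max(floor(y[i]) - r, 0L); r1 <- min(floor(y[i]) + r, h_out - 1L)
    if (c1 < c0 || r1 < r0) next
    px <- pnorm((c0:c1) + 1, x[i], s[i]) - pnorm(c0:c1, x[i], s[i])
    py <- pnorm((r0:r1) + 1, y[i], s[i]) - pnorm(r0:r1, y[i], s[i])
    img[(r0:r1) + 1L, (c0:c1) + 1L] <-
      img[(r0:r1) + 1L, (c0:c1) + 1L] + outer(py, px)
  }
  img
}
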
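#' Link consecutive-frame localizations into binding events
#'
#' Successive localizations from one docking site almost certainly stem from
#' a single imager binding event, so a maximal run of consecutive frames is
#' linked into one event. Linking is strict by default: any frame gap starts
#' a new event (`max_dark_frames = 0`); a tolerance can be allowed for
#' blinking-robust linking.
#'
#' @param frames integer vector of frame indices of one site, sorted
#'   ascending, no duplicates.
#' @param max_dark_frames number of missing frames tolerated inside one
#'   event (default 0 = strict consecutiveness).
#'
#' @return integer vector of event ids (1-based, same length as `frames`).
#'   Event ids partition the localizations: each belongs to exactly one
#'   event.
#' @examples
#' link_events(c(3, 4, 5, 9))  # 1 1 1 2
#' @export
link_events <- function(frames, max_dark_frames = 0) {
  if (length(frames) == 0L) return(integer(0))
  if (is.unsorted(frames)) stop("frames must be sorted ascending")
  if (anyDuplicated(frames))
    stop("duplicate frame for one site: cannot link events")
  gaps <- diff(frames)
  cumsum(c(1L, as.integer(gaps > max_dark_frames + 1L)))
}

#' Event table of one docking site
#'
#' Convenience wrapper around [link_events()]: summarises the localization
#' stream of one site into its binding events.
#'
#' @param site_locs data.frame with at least `frame` (sorted) and optionally
#'   `photons` for one docking site.
#' @param max_dark_frames passed to [link_events()].
#' @return data.frame with one row per event: `event`, `start_frame`,
#'   `end_frame`, `length` (frames); the input gains an `event` column in
#'   the `locs` attribute.
#' @export
binding_events <- function(site_locs, max_dark_frames = 0) {
  ids <- link_events(site_locs$frame, max_dark_frames)
  if (length(ids) == 0L)
    return(data.frame(event = integer(0), start_frame = integer(0),
                      end_frame = integer(0), length = integer(0)))
  ev <- data.frame(
    event = unique(ids),
    start_frame = as.integer(tapply(site_locs$frame, ids, min)),
    end_frame = as.integer(tapply(site_locs$frame, ids, max)))
  ev$length <- ev$end_frame - ev$start_frame + 1L
  site_locs$event <- ids
  attr(ev, "locs") <- site_locs
  ev
}

#' Mean bright or dark time from a cumulative-distribution fit
#'
#' Builds the empirical cumulative distribution function of the observed
#' durations and fits the exponential model `F(t) = 1 - a * exp(-t / tau)`
#' by least squares, with the empirical CDF evaluated at the observed
#' (unique) durations, weighted by multiplicity. The free amplitude `a`
#' absorbs the distortion that camera discretization imposes on the smallest
#' durations: for exponentially distributed true durations observed as
#' whole-frame counts, the survival function on the observed support is
#' exactly exponential in `tau` but with amplitude different from one, so
#' the two-parameter fit recovers `tau` without discretization bias. On
#' continuous exponential samples the fit agrees with the sample-mean
#' maximum-likelihood estimate.
#'
#' @param durations_s observed durations, seconds.
#' @param min_events minimum number of durations required (default 10).
#'
#' @return fitted mean time tau (seconds), or `NA` with attribute
#'   `reason` if the site must be excluded (too few or degenerate
#'   durations).
#' @examples
#' set.seed(1)
#' fit_mean_time(rexp(5000, 1 / 2))  # about 2
#' @export
fit_mean_time <- function(durations_s, min_events = 10) {
  if (length(durations_s) < min_events)
    return(structure(NA_real_, reason = "too few durations"))
  if (length(unique(durations_s)) < 2L)
    return(structure(NA_real_, reason = "degenerate durations"))
  tu <- sort(unique(durations_s))
  wt <- as.numeric(table(factor(durations_s, levels = tu)))
  Fh <- cumsum(wt) / sum(wt)
  m <- mean(durations_s)
  fit <- tryCatch(
    minpack.lm::nlsLM(Fh ~ 1 - a * exp(-tu / tau),
                      start = list(a = 1, tau = m),
                      weights = wt,
                      lower = c(a = 1e-6, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(NA_real_, reason = "fit failed"))
  unname(coef(fit)["tau"])
}

#' Per-site kinetic summary
#'
#' Computes, for one docking site, the binding events, the CDF-fitted mean
#' bright and dark times, the time from the last event to the end of the
#' measurement (`t_end`), and the destruction ratio `r = t_end / tau_d`.
#' Bright durations are event lengths in frames times the exposure; dark
#' durations are the frame gaps between consecutive events times the
#' exposure (the lead-in before the first event is not a dark time).
#' A site whose last event is still running in the final frame yields
#' `r = NA`: it is observed alive at the cutoff, so its gap time carries no
#' destruction information (and would otherwise put a spurious atom at
#' r = 0).
#'
#' @param site_locs data.frame of one site's localizations (sorted `frame`).
#' @param exposure frame time, seconds.
#' @param n_frames total frames in the measurement.
#' @param min_events minimum durations for the CDF fits (default 10).
#'
#' @return list with `events` (from [binding_events()]), `tau_b`, `tau_d`
#'   (s; `NA` when excluded), `t_end` (s), `r`, and `n_events`.
#' @export
site_kinetics <- function(site_locs, exposure, n_frames, min_events = 10) {
  ev <- binding_events(site_locs)
  n_ev <- nrow(ev)
  if (n_ev == 0L)
    return(list(events = ev, tau_b = NA_real_, tau_d = NA_real_,
                t_end = NA_real_, r = NA_real_, n_events = 0L))
  bright <- ev$length * exposure
  dark <- if (n_ev >= 2L)
    (ev$start_frame[-1L] - ev$end_frame[-n_ev]) * exposure else numeric(0)
  tau_b <- fit_mean_time(bright, min_events)
  tau_d <- fit_mean_time(dark, min_events)
  t_end <- (n_frames - 1L - ev$end_frame[n_ev]) * exposure
  # a site whose last event reaches the final frame is still being sampled
  # at the cutoff: it is trivially intact and its gap time is censored
  r <- if (is.finite(tau_d) && tau_d > 0 && ev$end_frame[n_ev] < n_frames - 1L)
    t_end / tau_d else NA_real_
  list(events = ev, tau_b = tau_b, tau_d = tau_d, t_end = t_end, r = r,
       n_events = n_ev)
}

#' Mean photon output per 100 ms from center frames
#'
#' Neither the start nor the end of a binding event is likely to coincide
#' with frame boundaries, so the first and last frames of an event
#' under-count photons. Only "center frames" - frames of events at least
#' three frames long that are neither first nor last - measure the output
#' of a continuously bound imager. Their photon counts are scaled to a
#' 100 ms basis.
#'
#' @param site_locs data.frame with `frame` (sorted) and `photons` of one
#'   site, or of several sites if a `site` column is present.
#' @param exposure frame time, seconds.
#'
#' @return list with `mean` (photons per 100 ms; `NA` if no eligible frame),
#'   `n` (number of center frames) and `photons` (the per-frame scaled
#'   values, for pooling across sites).
#' @examples
#' center_frame_photons(data.frame(frame = 0:3,
#'                                 photons = c(500, 1000, 1000, 400)), 0.1)$mean
#' @export
center_frame_photons <- function(site_locs, exposure) {
  if (exposure <= 0) stop("exposure must be > 0")
  vals <- center_frame_values(site_locs, "photons") * (0.1 / exposure)
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       n = length(vals), photons = vals)
}

# values of a column restricted to center frames (non-terminal frames of
# events >= 3 frames long); respects a 'site' grouping column
center_frame_values <- function(locs, column) {
  groups <- if (!is.null(locs$site)) split(locs, locs$site) else list(locs)
  unlist(lapply(groups, function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    ids <- link_events(g$frame)
    if (length(ids) == 0L) return(numeric(0))
    len <- stats::ave(seq_along(ids), ids, FUN = length)
    first <- !duplicated(ids)
    last <- !duplicated(ids, fromLast = TRUE)
    g[[column]][len >= 3L & !first & !last]
  }), use.names = FALSE)
}

#' Signal-to-background ratio of localizations
#'
#' The photon value of a localization integrates the whole fitted PSF,
#' whereas background is a per-pixel offset. For comparability the PSF is
#' integrated over a one-pixel square centered at its maximum,
#' `N * erf(0.5 / (sqrt(2) sx)) * erf(0.5 / (sqrt(2) sy))`, and divided by
#' the background offset, cancelling the area term and yielding a unitless
#' ratio. Localizations with non-positive background are excluded (`NA`).
#'
#' @param photons total fitted photons; vectorized.
#' @param bg background photons per pixel; vectorized.
#' @param sx,sy fitted PSF standard deviations, pixels; vectorized.
#'
#' @return numeric vector of per-localization SBR values (`NA` where
#'   `bg <= 0`).
#' @examples
#' compute_sbr(1000, 10, 1, 1)  # 14.66
#' @export
compute_sbr <- function(photons, bg, sx, sy) {
  if (any(sx <= 0) || any(sy <= 0)) stop("sx and sy must be > 0")
  ix <- 2 * pnorm(0.5 / sx) - 1   # erf(0.5 / (sqrt(2) sx))
  iy <- 2 * pnorm(0.5 / sy) - 1
  out <- photons * ix * iy / bg
  out[bg <= 0] <- NA_real_
  out
}

#' Measurement-level SBR over center frames
#'
#' Applies [compute_sbr()] to the center-frame localizations of a table
#' (grouped by `site`) and averages.
#'
#' @param locs data.frame with `frame`, `photons`, `bg`, `sx`, `sy` and
#'   optionally `site`.
#' @return list with `mean` SBR and `n` eligible localizations.
#' @export
measurement_sbr <- function(locs) {
  groups <- if (!is.null(locs$site)) split(locs, locs$site) else list(locs)
  vals <- unlist(lapply(groups, function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    ids <- link_events(g$frame)
    if (length(ids) == 0L) return(numeric(0))
    len <- stats::ave(seq_along(ids), ids, FUN = length)
    first <- !duplicated(ids)
    last <- !duplicated(ids, fromLast = TRUE)
    keep <- len >= 3L & !first & !last
    compute_sbr(g$photons[keep], g$bg[keep], g$sx[keep], g$sy[keep])
  }), use.names = FALSE)
  vals <- vals[is.finite(vals)]
  list(mean = if (length(vals)) mean(vals) else NA_real_, n = length(vals))
}

#' Sampling stability: localizations per docking site over time
#'
#' Counts localizations per site in consecutive time windows (20 s by
#' default), averages across sites, and reports the localization drop
#' between the first and the last window,
#' `100 * (1 - last / first)`. The raw drop is retained alongside a
#' `[0, 100]`-clamped value for reporting.
#'
#' @param locs data.frame with `frame` and `site` columns (site 0 /
#'   sticking rows are ignored).
#' @param exposure frame time, seconds.
#' @param n_frames total frames in the measurement.
#' @param window_s window length, seconds (default 20).
#'
#' @return list with `trace` (data.frame `window`, `t_mid`, `mean_locs`),
#'   `drop_pct` (clamped), `drop_pct_raw`, and `n_sites`.
#' @export
stability_trace <- function(locs, exposure, n_frames, window_s = 20) {
  duration <- n_frames * exposure
  n_win <- floor(duration / window_s)
  if (n_win < 2L)
    stop("measurement must cover at least two stability windows")
  df <- as.data.frame(locs)
  if (!is.null(df$site)) df <- df[df$site != 0L, , drop = FALSE]
  if (is.null(df$site)) df$site <- 1L
  n_sites <- length(unique(df$site))
  if (n_sites == 0L) stop("no site-assigned localizations")
  win <- floor(df$frame * exposure / window_s)
  keep <- win < n_win
  counts <- table(factor(win[keep], levels = 0:(n_win - 1L)))
  mean_locs <- as.numeric(counts) / n_sites
  if (mean_locs[1L] == 0)
    return(list(trace = data.frame(window = seq_len(n_win),
                                   t_mid = (seq_len(n_win) - 0.5) * window_s,
                                   mean_locs = mean_locs),
                drop_pct = NA_real_, drop_pct_raw = NA_real_,
                n_sites = n_sites))
  raw <- 100 * (1 - mean_locs[n_win] / mean_locs[1L])
  list(trace = data.frame(window = seq_len(n_win),
                          t_mid = (seq_len(n_win) - 0.5) * window_s,
                          mean_locs = mean_locs),
       drop_pct = min(max(raw, 0), 100), drop_pct_raw = raw,
       n_sites = n_sites)
}
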
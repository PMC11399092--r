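#' Simulate a full DNA-PAINT localization table
#'
#' Runs the complete generative model of a DNA-PAINT acquisition: for every
#' docking site of the layout, a binding-event stream
#' ([generate_event_stream()]) is drawn, discretized into frames with
#' partial-frame Poisson photon collection ([discretize_events()]), and each
#' frame-localization is jittered around the true site position with an
#' isotropic Gaussian whose sigma is the Mortensen precision
#' ([mortensen_sigma()]) at that localization's photons and background.
#' Docking-site destruction is a per-site Bernoulli flag
#' (`destroy_fraction`) with a destruction time drawn uniformly over the
#' acquisition (or fixed at t = 0 with `destroy_timing = "start"`).
#' Off-target "sticking" events last a single frame, land uniformly in the
#' field of view, and occur at `sticking_density` per square micrometre per
#' frame with a uniform partial-frame photon fraction.
#'
#' All randomness flows from `config$seed`; repeated calls with the same
#' config return identical tables.
#'
#' @param config a [sim_config()].
#'
#' @return list with
#' \describe{
#'   \item{`locs`}{a [loc_table] sorted by frame with columns `frame`, `x`,
#'     `y`, `photons`, `bg`, `sx`, `sy`, `lpx`, `lpy`, plus ground-truth
#'     bookkeeping columns `site` (0 = sticking) and `event` (0 = sticking).}
#'   \item{`truth`}{list with `sites` (per-site `site`, `structure`, `x`,
#'     `y`, `is_target`, `destroyed`, `t_destroy`) and `events` (per-event
#'     `site`, `event`, `t_start`, `t_end`, seconds).}
#' }
#' @examples
#' sim <- emit_localizations(sim_config(n_frames = 100,
#'                                      layout = layout_single_sites(4)))
#' head(sim$locs)
#' @export
emit_localizations <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, emit_localizations_impl(config))
}

emit_localizations_impl <- function(cfg) {
  sites <- cfg$layout$positions
  n_sites <- nrow(sites)
  duration <- cfg$n_frames * cfg$exposure

  destroyed <- runif(n_sites) < cfg$destroy_fraction
  t_destroy <- rep(Inf, n_sites)
  if (any(destroyed))
    t_destroy[destroyed] <-
      if (cfg$destroy_timing == "start") 0 else runif(sum(destroyed), 0, duration)

  loc_parts <- vector("list", n_sites)
  ev_parts <- vector("list", n_sites)
  n_events_before <- 0L
  for (i in seq_len(n_sites)) {
    ev <- generate_event_stream(cfg$tau_b, cfg$tau_d, duration,
                                destruction_time = t_destroy[i],
                                onrate_decay = cfg$onrate_decay)
    if (nrow(ev) == 0L) next
    disc <- discretize_events(ev, cfg$exposure, cfg$photon_rate)
    # a frame that catches the end of one event and the start of the next
    # integrates both: merge same-frame rows (Poisson sums remain Poisson)
    if (anyDuplicated(disc$frame)) {
      f <- factor(disc$frame, levels = unique(disc$frame))
      disc <- data.frame(
        event = as.integer(tapply(disc$event, f, min)),
        frame = as.integer(levels(f)),
        fraction = as.numeric(tapply(disc$fraction, f, sum)),
        photons = as.numeric(tapply(disc$photons, f, sum)))
    }
    disc <- disc[disc$photons > 0, , drop = FALSE]
    ev_parts[[i]] <- data.frame(site = sites$site[i],
                                event = n_events_before + seq_len(nrow(ev)),
                                t_start = ev$t_start, t_end = ev$t_end)
    if (nrow(disc) > 0L) {
      sig <- mortensen_sigma(disc$photons, cfg$bg_rate, cfg$psf_sigma)
      loc_parts[[i]] <- data.frame(
        frame = disc$frame,
        x = sites$x[i] + rnorm(nrow(disc), 0, sig),
        y = sites$y[i] + rnorm(nrow(disc), 0, sig),
        photons = disc$photons,
        bg = cfg$bg_rate,
        sx = cfg$psf_sigma, sy = cfg$psf_sigma,
        lpx = sig, lpy = sig,
        site = sites$site[i],
        event = n_events_before + disc$event)
    }
    n_events_before <- n_events_before + nrow(ev)
  }

  stick <- simulate_sticking(cfg)
  df <- do.call(rbind, c(loc_parts[!vapply(loc_parts, is.null, logical(1))],
                         if (nrow(stick) > 0L) list(stick)))
  if (is.null(df))
    df <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                     photons = numeric(0), bg = numeric(0), sx = numeric(0),
                     sy = numeric(0), lpx = numeric(0), lpy = numeric(0),
                     site = integer(0), event = integer(0))
  # clip jittered coordinates into the field of view
  eps <- 1e-9
  df$x <- pmin(pmax(df$x, 0), cfg$width - eps)
  df$y <- pmin(pmax(df$y, 0), cfg$height - eps)
  df <- df[order(df$frame, df$site, df$event), , drop = FALSE]

  events <- do.call(rbind, ev_parts[!vapply(ev_parts, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(site = integer(0), event = integer(0),
                         t_start = numeric(0), t_end = numeric(0))
  truth <- list(sites = cbind(sites, destroyed = destroyed,
                              t_destroy = t_destroy),
                events = events)
  list(locs = loc_table(df, exposure = cfg$exposure,
                        pixel_size = cfg$pixel_size,
                        width = cfg$width, height = cfg$height),
       truth = truth)
}

simulate_sticking <- function(cfg) {
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      photons = numeric(0), bg = numeric(0), sx = numeric(0),
                      sy = numeric(0), lpx = numeric(0), lpy = numeric(0),
                      site = integer(0), event = integer(0))
  if (cfg$sticking_density <= 0) return(empty)
  px_um <- cfg$pixel_size / 1000
  area_um2 <- cfg$width * cfg$height * px_um^2
  n <- rpois(1, cfg$sticking_density * area_um2 * cfg$n_frames)
  if (n == 0L) return(empty)
  frac <- runif(n)
  photons <- rpois(n, cfg$photon_rate * (cfg$exposure / 0.1) * frac)
  keep <- photons > 0
  if (!any(keep)) return(empty)
  photons <- photons[keep]
  sig <- mortensen_sigma(photons, cfg$bg_rate, cfg$psf_sigma)
  data.frame(frame = sample.int(cfg$n_frames, sum(keep), replace = TRUE) - 1L,
             x = runif(sum(keep), 0, cfg$width),
             y = runif(sum(keep), 0, cfg$height),
             photons = as.numeric(photons), bg = cfg$bg_rate,
             sx = cfg$psf_sigma, sy = cfg$psf_sigma,
             lpx = sig, lpy = sig, site = 0L, event = 0L)
}
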
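#' Simulate the binding-event stream of one docking site
#'
#' Draws an alternating renewal process of dark (unbound) and bright (bound)
#' periods, starting unbound at t = 0. Dark waiting times are exponential with
#' instantaneous rate `(1 / tau_d) * exp(-onrate_decay * t)`, so with
#' `onrate_decay = 0` they are i.i.d. exponential with mean `tau_d`; a
#' positive decay constant models the progressive loss of effective imager
#' on-rate caused by partial photodamage to concatenated docking sequences.
#' Bright durations are i.i.d. exponential with mean `tau_b`. No event starts
#' after `min(duration_s, destruction_time)` and bright periods are truncated
#' there.
#'
#' Randomness is taken from the current R random number generator; seed it
#' (e.g. `set.seed()` or [withr::with_seed()]) for reproducibility.
#' [emit_localizations()] does this for you via the config seed.
#'
#' @param tau_b mean bright time, seconds (> 0).
#' @param tau_d mean dark time, seconds (> 0).
#' @param duration_s measurement duration, seconds (>= 0).
#' @param destruction_time time at which the site is destroyed, seconds
#'   (`Inf` = never).
#' @param onrate_decay exponential decay constant of the on-rate, 1/s.
#'
#' @return data.frame with columns `t_start`, `t_end` (seconds), one row per
#'   binding event, ordered in time; zero rows if no event occurs.
#' @examples
#' set.seed(7)
#' ev <- generate_event_stream(0.35, 5, duration_s = 600)
#' mean(ev$t_end - ev$t_start)  # about 0.35
#' @export
generate_event_stream <- function(tau_b, tau_d, duration_s,
                                  destruction_time = Inf, onrate_decay = 0) {
  if (!is.finite(tau_b) || tau_b <= 0) stop("tau_b must be > 0")
  if (!is.finite(tau_d) || tau_d <= 0) stop("tau_d must be > 0")
  if (duration_s < 0) stop("duration_s must be >= 0")
  cutoff <- min(duration_s, destruction_time)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0))
  if (cutoff <= 0) return(empty)

  if (onrate_decay == 0) {
    # vectorized: draw dark/bright pairs in chunks until past the cutoff
    starts <- numeric(0); ends <- numeric(0); t <- 0
    chunk <- max(16L, ceiling(1.5 * cutoff / (tau_b + tau_d)))
    repeat {
      d <- rexp(chunk, rate = 1 / tau_d)
      b <- rexp(chunk, rate = 1 / tau_b)
      s <- t + cumsum(d + b) - b
      e <- s + b
      starts <- c(starts, s); ends <- c(ends, e)
      t <- e[length(e)]
      if (t > cutoff) break
      chunk <- max(16L, ceiling(1.5 * (cutoff - t) / (tau_b + tau_d)))
    }
    keep <- starts < cutoff
    starts <- starts[keep]
    ends <- pmin(ends[keep], duration_s, destruction_time)
  } else {
    # inhomogeneous dark waits by inversion of the integrated rate
    starts <- numeric(0); ends <- numeric(0); t <- 0; lam <- onrate_decay
    repeat {
      u <- rexp(1)
      arg <- 1 - u * tau_d * lam * exp(lam * t)
      if (arg <= 0) break  # integrated rate never reaches u: no more events
      t_start <- t - log(arg) / lam
      if (t_start >= cutoff) break
      t_end <- min(t_start + rexp(1, rate = 1 / tau_b), duration_s,
                   destruction_time)
      starts <- c(starts, t_start); ends <- c(ends, t_end)
      t <- t_end
      if (t >= cutoff) break
    }
  }
  if (length(starts) == 0L) return(empty)
  data.frame(t_start = starts, t_end = ends)
}

#' Discretize binding events into camera frames
#'
#' Maps continuous-time binding events onto the frame grid and draws the
#' photons each frame collects. A frame overlapped by an event records the
#' event for the overlapping fraction of its exposure only, so first and last
#' frames of an event almost always collect fewer photons than frames that
#' record a continuously bound imager. Photons are Poisson with mean
#' `photon_rate * (exposure / 0.1) * fraction` (the photon rate is specified
#' per 100 ms of fully bound time).
#'
#' Uses the current RNG state for the Poisson draws.
#'
#' @param events data.frame with `t_start`, `t_end` (seconds), as produced by
#'   [generate_event_stream()].
#' @param exposure frame time, seconds (> 0).
#' @param photon_rate expected photons per fully bound 100 ms.
#'
#' @return data.frame with columns `event` (index into `events`), `frame`
#'   (0-based), `fraction` (overlap / exposure, in (0, 1]) and `photons`.
#' @examples
#' discretize_events(data.frame(t_start = 0.05, t_end = 0.25), 0.1, 0)[, 1:3]
#' @export
discretize_events <- function(events, exposure, photon_rate) {
  if (exposure <= 0) stop("exposure must be > 0")
  if (photon_rate < 0) stop("photon_rate must be >= 0")
  if (nrow(events) == 0L)
    return(data.frame(event = integer(0), frame = integer(0),
                      fraction = numeric(0), photons = numeric(0)))
  f0 <- floor(events$t_start / exposure)
  f1 <- ceiling(events$t_end / exposure) - 1
  f1 <- pmax(f1, f0)
  n <- f1 - f0 + 1
  ev <- rep.int(seq_len(nrow(events)), n)
  frame <- unlist(lapply(seq_len(nrow(events)),
                         function(i) seq.int(f0[i], f1[i])), use.names = FALSE)
  lo <- pmax(events$t_start[ev], frame * exposure)
  hi <- pmin(events$t_end[ev], (frame + 1) * exposure)
  fraction <- (hi - lo) / exposure
  keep <- fraction > 1e-12
  ev <- ev[keep]; frame <- frame[keep]; fraction <- fraction[keep]
  photons <- rpois(length(fraction),
                   lambda = photon_rate * (exposure / 0.1) * fraction)
  data.frame(event = ev, frame = as.integer(frame), fraction = fraction,
             photons = as.numeric(photons))
}
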
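#' Density-based clustering of localizations (SMLM clusterer)
#'
#' DBSCAN-style clustering tuned for SMLM point data: a localization is a
#' core point if at least `min_locs` localizations (itself included) lie
#' within `radius`; clusters are the connected components of core points
#' within `radius` of each other, plus the non-core localizations within
#' `radius` of a core point. Non-core border points that neighbour several
#' clusters are assigned to the cluster of smallest id after a canonical
#' sort of the input by (x, y), which makes the result independent of input
#' order.
#'
#' Defaults mirror common origami-scale settings: minimum 15 localizations
#' within a 0.04 px (about 5 nm at 130 nm pixels) radius.
#'
#' @param locs data.frame with `x`, `y` (pixels).
#' @param radius neighbourhood radius, pixels (> 0).
#' @param min_locs minimum neighbours (self included) for a core point.
#'
#' @return list with `cluster` (integer id per localization in input order,
#'   `NA` = noise) and `clusters` (data.frame `cluster`, `x`, `y`
#'   centroids, `n_locs`).
#' @export
cluster_smlm <- function(locs, radius = 0.04, min_locs = 15) {
  if (radius <= 0) stop("radius must be > 0")
  if (min_locs < 1) stop("min_locs must be >= 1")
  n <- nrow(locs)
  if (n == 0L)
    return(list(cluster = integer(0),
                clusters = data.frame(cluster = integer(0), x = numeric(0),
                                      y = numeric(0), n_locs = integer(0))))
  ord <- order(locs$x, locs$y)
  x <- locs$x[ord]; y <- locs$y[ord]
  nbr <- radius_neighbors(x, y, radius)
  deg <- lengths(nbr)
  core <- deg >= min_locs
  lab <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(core)) {
    if (!is.na(lab[i])) next
    cid <- cid + 1L
    queue <- i
    lab[i] <- cid
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      for (k in nbr[[j]]) {
        if (core[k] && is.na(lab[k])) {
          lab[k] <- cid
          queue <- c(queue, k)
        } else if (!core[k] && is.na(lab[k])) {
          lab[k] <- cid  # border point: first (lowest-id) cluster wins
        }
      }
    }
  }
  out <- integer(n)
  out[ord] <- lab
  if (cid == 0L) {
    clusters <- data.frame(cluster = integer(0), x = numeric(0),
                           y = numeric(0), n_locs = integer(0))
  } else {
    clusters <- data.frame(
      cluster = seq_len(cid),
      x = as.numeric(tapply(locs$x, factor(out, levels = seq_len(cid)), mean)),
      y = as.numeric(tapply(locs$y, factor(out, levels = seq_len(cid)), mean)),
      n_locs = as.integer(table(factor(out, levels = seq_len(cid)))))
  }
  list(cluster = out, clusters = clusters)
}

# grid-bucketed fixed-radius neighbour lists (indices into x/y, self included)
radius_neighbors <- function(x, y, radius) {
  n <- length(x)
  cx <- floor(x / radius); cy <- floor(y / radius)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  r2 <- radius^2
  lapply(seq_len(n), function(i) {
    cand <- unlist(buckets[paste(rep(cx[i] + (-1:1), each = 3),
                                 rep(cy[i] + (-1:1), times = 3))],
                   use.names = FALSE)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= r2]
  })
}

#' Identify complete crosshair origami and their target sites
#'
#' A crosshair origami carries one dye-of-interest docking site plus four
#' barcode sites; a correctly folded, complete structure therefore shows
#' exactly five localization clusters within its pick. Picks with any other
#' cluster count (missing sites, spurious sticking clusters) are rejected.
#' For accepted picks the designated target site is the cluster closest to
#' the pick center plus `target_offset`.
#'
#' @param locs a [loc_table] of the (barcode/alignment) round.
#' @param picks a [region_picks] with one pick per candidate structure.
#' @param radius,min_locs clustering parameters, see [cluster_smlm()].
#' @param target_offset (dx, dy) of the dye-of-interest site relative to
#'   the pick center, pixels (default c(0, 0): central site).
#'
#' @return data.frame with one row per accepted pick: `pick`, `x`, `y`
#'   (target-site cluster centroid). Attribute `n_clusters` gives the
#'   cluster count of every pick.
#' @export
find_crosshairs <- function(locs, picks, radius = 0.04, min_locs = 15,
                            target_offset = c(0, 0)) {
  asg <- assign_to_regions(locs, picks)
  n_clusters <- integer(nrow(picks))
  rows <- vector("list", nrow(picks))
  for (i in seq_len(nrow(picks))) {
    sub <- asg$tables[[i]]
    cl <- cluster_smlm(sub, radius, min_locs)$clusters
    n_clusters[i] <- nrow(cl)
    if (nrow(cl) == 5L) {
      tx <- picks$x[i] + target_offset[1L]
      ty <- picks$y[i] + target_offset[2L]
      k <- which.min((cl$x - tx)^2 + (cl$y - ty)^2)
      rows[[i]] <- data.frame(pick = i, x = cl$x[k], y = cl$y[k])
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(pick = integer(0), x = numeric(0),
                                      y = numeric(0))
  attr(out, "n_clusters") <- n_clusters
  out
}

#' Relative labeling specificity between an imaging and a reference round
#'
#' Computes, for each round, the specificity `S` = (signal localizations
#' per area) / (background localizations per area) on identical regions,
#' then the relative specificity `R = S_imaging / S_reference`. Because the
#' same regions are used for both rounds, imager concentration, off-target
#' bound label and other shared effects cancel; `R` isolates the dye's own
#' off-target sticking relative to the reference dye.
#'
#' @param imaging,reference [loc_table]s of the imaging and reference
#'   (alignment) rounds.
#' @param signal_regions,background_regions [region_picks] or a single
#'   [region_mask] passed as `signal_regions` (its inside is signal, its
#'   outside background; `background_regions` is then ignored).
#'
#' @return A `specificity_result`: list with `R`, `S_imaging`,
#'   `S_reference`, and per-round counts and areas.
#' @export
relative_specificity <- function(imaging, reference, signal_regions,
                                 background_regions = NULL) {
  one_round <- function(tab) {
    if (inherits(signal_regions, "region_mask")) {
      asg <- assign_to_regions(tab, signal_regions)
      cs <- nrow(asg$tables[[1L]]); cb <- nrow(asg$tables[[2L]])
      as_ <- asg$areas_um2[1L]; ab <- asg$areas_um2[2L]
    } else {
      s <- assign_to_regions(tab, signal_regions)
      b <- assign_to_regions(tab, background_regions)
      cs <- sum(!is.na(s$assignment)); cb <- sum(!is.na(b$assignment))
      as_ <- sum(s$areas_um2); ab <- sum(b$areas_um2)
    }
    if (cb == 0L)
      stop("zero background localizations: use larger background regions")
    list(S = (cs / as_) / (cb / ab), counts = c(signal = cs, background = cb),
         areas = c(signal = as_, background = ab))
  }
  if (!inherits(signal_regions, "region_mask") && is.null(background_regions))
    stop("background_regions required with circular picks")
  ri <- one_round(imaging)
  rr <- one_round(reference)
  structure(list(R = ri$S / rr$S, S_imaging = ri$S, S_reference = rr$S,
                 imaging = ri[c("counts", "areas")],
                 reference = rr[c("counts", "areas")]),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("Relative specificity R = %.3f (S_imaging = %.3f, S_reference = %.3f)\n",
              x$R, x$S_imaging, x$S_reference))
  invisible(x)
}

#' Assign localizations to known docking-site positions
#'
#' Nearest-site gating: each localization is assigned to the closest site
#' position if that distance is below `radius`, otherwise left unassigned
#' (off-target/sticking).
#'
#' @param locs a [loc_table] or data.frame with `x`, `y`.
#' @param positions data.frame with `site`, `x`, `y` (e.g.
#'   `layout$positions` or [find_crosshairs()] output with a `site` column
#'   added).
#' @param radius gate radius, pixels.
#' @return integer vector of site ids (`NA` = unassigned), parallel to
#'   `locs` rows.
#' @export
assign_to_sites <- function(locs, positions, radius = 0.5) {
  df <- as.data.frame(locs)
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  sid <- if (!is.null(positions$site)) positions$site else seq_len(nrow(positions))
  best <- rep(Inf, n)
  assign <- rep(NA_integer_, n)
  for (i in seq_len(nrow(positions))) {
    d2 <- (df$x - positions$x[i])^2 + (df$y - positions$y[i])^2
    take <- d2 < best & d2 < radius^2
    assign[take] <- sid[i]
    best[take] <- d2[take]
  }
  assign
}
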
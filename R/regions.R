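#' Region sets: circular picks and raster masks
#'
#' Regions select localizations for region-based statistics (per-structure
#' analysis, signal vs. off-target densities). Two kinds are supported:
#' circular picks (center and diameter, in pixels) and raster masks
#' (grayscale image, nonzero = inside).
#'
#' @param x,y pick centers, pixels.
#' @param diameter pick diameters, pixels (> 0); recycled.
#' @param role per-region label, `"signal"` or `"background"`; recycled.
#' @param mask numeric matrix (rows = y, columns = x); nonzero pixels are
#'   inside.
#' @param mask_pixel_size nm per mask pixel. A mask may be rendered at a
#'   display pixel size different from the camera's (e.g. 100 nm display vs.
#'   130 nm camera); localization coordinates are converted with the camera
#'   `pixel_size` at assignment time.
#'
#' @return A `region_picks` (data.frame `x`, `y`, `diameter`, `role`) or
#'   `region_mask` object.
#' @name regions
NULL

#' @rdname regions
#' @export
region_picks <- function(x, y, diameter, role = "signal") {
  if (any(diameter <= 0)) stop("pick diameters must be > 0")
  df <- data.frame(x = x, y = y, diameter = diameter, role = role)
  structure(df, class = c("region_picks", "data.frame"))
}

#' @rdname regions
#' @export
region_mask <- function(mask, mask_pixel_size = 130) {
  stopifnot(is.matrix(mask))
  structure(list(mask = mask, mask_pixel_size = mask_pixel_size),
            class = "region_mask")
}

#' Read and write pick files (YAML) and masks (TIFF)
#'
#' Picks are stored as a small YAML document (one mapping per pick with
#' `x`, `y`, `diameter`, `role`); masks as grayscale TIFF where nonzero
#' means inside, with the mask pixel size in a YAML sidecar.
#'
#' @param picks a [region_picks] object.
#' @param mask a [region_mask] object.
#' @param path file path (`.yaml` for picks, `.tif` for masks).
#' @return readers return the region object; writers invisibly return `path`.
#' @name region_io
NULL

#' @rdname region_io
#' @export
write_picks <- function(picks, path) {
  recs <- lapply(seq_len(nrow(picks)), function(i)
    list(x = picks$x[i], y = picks$y[i], diameter = picks$diameter[i],
         role = picks$role[i]))
  yaml::write_yaml(list(picks = recs), path)
  invisible(path)
}

#' @rdname region_io
#' @export
read_picks <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$picks) || length(doc$picks) == 0L)
    stop("no picks found in ", path)
  region_picks(x = vapply(doc$picks, `[[`, numeric(1), "x"),
               y = vapply(doc$picks, `[[`, numeric(1), "y"),
               diameter = vapply(doc$picks, `[[`, numeric(1), "diameter"),
               role = vapply(doc$picks, `[[`, character(1), "role"))
}

#' @rdname region_io
#' @export
write_mask <- function(mask, path) {
  m <- mask$mask
  tiff::writeTIFF(ifelse(m != 0, 1, 0), path, bits.per.sample = 8L)
  yaml::write_yaml(list(mask_pixel_size = mask$mask_pixel_size),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname region_io
#' @export
read_mask <- function(path) {
  md <- yaml::read_yaml(sidecar_path(path))
  region_mask(tiff::readTIFF(path), mask_pixel_size = md$mask_pixel_size)
}

#' Assign localizations to regions
#'
#' Circular picks: a localization is inside a pick if its distance to the
#' center is strictly less than the radius (boundary points are outside). If
#' picks overlap, the localization goes to the nearest center and a warning
#' is raised. Mask: a localization is inside if the mask pixel under it is
#' nonzero; `"signal"` is inside, `"background"` outside. Areas are
#' analytical for circles and pixel counts times pixel area for masks,
#' reported in square micrometres.
#'
#' @param locs a [loc_table].
#' @param regions a [region_picks] or [region_mask] object.
#'
#' @return list with `assignment` (integer region index per localization, NA
#'   if unassigned; for masks 1 = inside/signal, 2 = outside/background),
#'   `tables` (list of per-region sub-data.frames), `areas_um2` and `roles`.
#' @export
assign_to_regions <- function(locs, regions) {
  df <- as.data.frame(locs)
  md <- loc_metadata(locs)
  px_um <- (md$pixel_size %||% 130) / 1000
  if (inherits(regions, "region_picks")) {
    n <- nrow(df)
    assign <- rep(NA_integer_, n)
    best <- rep(Inf, n)
    hits <- integer(n)
    for (i in seq_len(nrow(regions))) {
      d2 <- (df$x - regions$x[i])^2 + (df$y - regions$y[i])^2
      inside <- d2 < (regions$diameter[i] / 2)^2
      hits <- hits + inside
      take <- inside & d2 < best
      assign[take] <- i
      best[take] <- d2[take]
    }
    if (any(hits > 1L))
      warning("overlapping picks: localizations assigned to nearest center")
    areas <- pi * (regions$diameter / 2)^2 * px_um^2
    roles <- regions$role
    k <- nrow(regions)
  } else if (inherits(regions, "region_mask")) {
    m <- regions$mask
    scale <- regions$mask_pixel_size / (md$pixel_size %||% 130)
    col <- floor(df$x / scale) + 1L
    row <- floor(df$y / scale) + 1L
    okpix <- row >= 1L & row <= nrow(m) & col >= 1L & col <= ncol(m)
    inside <- logical(nrow(df))
    inside[okpix] <- m[cbind(row[okpix], col[okpix])] != 0
    assign <- ifelse(inside, 1L, 2L)
    mask_px_um <- regions$mask_pixel_size / 1000
    areas <- c(sum(m != 0), sum(m == 0)) * mask_px_um^2
    roles <- c("signal", "background")
    k <- 2L
  } else stop("'regions' must be region_picks or region_mask")
  tables <- lapply(seq_len(k), function(i)
    df[!is.na(assign) & assign == i, , drop = FALSE])
  list(assignment = assign, tables = tables, areas_um2 = areas, roles = roles)
}
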
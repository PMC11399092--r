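#' Localization tables
#'
#' The lingua franca of the pipeline: one row per localization with the
#' column convention of common SMLM software (Picasso-style names), plus
#' acquisition metadata carried as attributes.
#'
#' Required columns: `frame` (integer, 0-based), `x`, `y` (continuous pixels,
#' origin at the top-left pixel corner), `photons` (total fitted photons),
#' `bg` (background photons per pixel), `sx`, `sy` (fitted PSF sigma,
#' pixels). Optional: `lpx`, `lpy` (per-axis precision, pixels; computable
#' via [add_precision()]) and any extra bookkeeping columns (`site`,
#' `event`, ...). Metadata: `exposure` (s), `pixel_size` (nm), `width`,
#' `height` (pixels).
#'
#' @param df data.frame of localizations.
#' @param exposure frame time, seconds.
#' @param pixel_size nm per pixel.
#' @param width,height image dimensions, pixels.
#'
#' @return `df` validated, sorted by frame, with class `loc_table` and a
#'   `metadata` attribute.
#' @examples
#' tb <- loc_table(data.frame(frame = 0L, x = 1.5, y = 2.5, photons = 1000,
#'                            bg = 10, sx = 1, sy = 1),
#'                 exposure = 0.1, pixel_size = 130, width = 8, height = 8)
#' loc_metadata(tb)$exposure
#' @export
loc_table <- function(df, exposure, pixel_size, width, height) {
  md <- list(exposure = exposure, pixel_size = pixel_size,
             width = as.integer(width), height = as.integer(height))
  validate_loc_table(df, md)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, metadata = md, class = c("loc_table", "data.frame"))
}

#' @rdname loc_table
#' @param locs a `loc_table`.
#' @export
loc_metadata <- function(locs) attr(locs, "metadata")

required_loc_columns <- c("frame", "x", "y", "photons", "bg", "sx", "sy")

validate_loc_table <- function(df, md) {
  for (col in required_loc_columns)
    if (is.null(df[[col]]))
      stop(sprintf("localization table is missing required column '%s'", col))
  for (f in c("exposure", "pixel_size", "width", "height"))
    if (is.null(md[[f]]) || !is.finite(md[[f]]))
      stop(sprintf("localization metadata is missing field '%s'", f))
  if (md$exposure <= 0) stop("metadata field 'exposure' must be > 0")
  if (md$pixel_size <= 0) stop("metadata field 'pixel_size' must be > 0")
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$frame < 0)) stop("column 'frame' must be non-negative")
  if (any(df$photons < 0)) stop("column 'photons' must be non-negative")
  if (any(df$bg < 0)) stop("column 'bg' must be non-negative")
  if (any(df$sx <= 0)) stop("column 'sx' must be positive")
  if (any(df$sy <= 0)) stop("column 'sy' must be positive")
  if (any(df$x < 0 | df$x >= md$width))
    stop("column 'x' must lie in [0, width)")
  if (any(df$y < 0 | df$y >= md$height))
    stop("column 'y' must lie in [0, height)")
  invisible(df)
}

#' Fill per-axis localization precision from the Mortensen formula
#'
#' Adds (or overwrites) `lpx`/`lpy` columns computed with [mortensen_sigma()]
#' from each localization's photons, background and fitted PSF width, in
#' pixel units.
#'
#' @param locs a [loc_table].
#' @return The table with `lpx` and `lpy` columns set.
#' @export
add_precision <- function(locs) {
  locs$lpx <- mortensen_sigma(locs$photons, locs$bg, locs$sx)
  locs$lpy <- mortensen_sigma(locs$photons, locs$bg, locs$sy)
  locs
}

#' Read and write localization tables
#'
#' Tables are stored as plain CSV (RFC 4180, header row) with a YAML sidecar
#' (`<stem>.yaml`) carrying the acquisition metadata. `write_locs()` followed
#' by `read_locs()` restores values and metadata exactly (round-trip
#' identity, up to the usual 17-digit decimal representation of doubles).
#'
#' @param locs a [loc_table].
#' @param path CSV file path.
#' @return `read_locs()` returns a [loc_table]; `write_locs()` invisibly
#'   returns `path`.
#' @export
write_locs <- function(locs, path) {
  md <- loc_metadata(locs)
  df <- as.data.frame(locs)
  con <- file(path, open = "w")
  on.exit(close(con))
  # full precision so the round trip is exact
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(md, sidecar_path(path))
  invisible(path)
}

#' @rdname write_locs
#' @export
read_locs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc)
  md <- yaml::read_yaml(sc)
  df <- read.csv(path, check.names = FALSE)
  df$frame <- as.integer(df$frame)
  loc_table(df, exposure = md$exposure, pixel_size = md$pixel_size,
            width = md$width, height = md$height)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Read and write rendered movies as multi-page TIFF
#'
#' Frames hold expected or drawn photon counts per pixel. Because baseline
#' TIFF float storage is defined on `[0, 1]`, frames are normalized by a
#' single `intensity_scale` (the maximum pixel value) written to the YAML
#' sidecar; `read_movie()` undoes the scaling. Values round-trip to float32
#' precision (~1e-7 relative).
#'
#' @param movie numeric array `height x width x n_frames` (photon counts).
#' @param path TIFF file path.
#' @return `read_movie()` returns the array; `write_movie()` invisibly
#'   returns `path`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  scale <- max(movie, 1e-12)
  pages <- lapply(seq_len(dim(movie)[3]), function(k) movie[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(intensity_scale = scale, n_frames = dim(movie)[3]),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  md <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * md$intensity_scale
  arr
}
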
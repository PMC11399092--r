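#' Fit a 2D affine transform from matched point pairs
#'
#' Least-squares affine (shift, rotation, scale, skew) mapping source bead
#' localizations onto destination ones, minimizing
#' `sum(|A [x y 1]' - dst|^2)`. The transform is the 2 x 3 matrix `A`
#' (linear part plus translation, row-major, convention
#' `dst = A %*% c(x, y, 1)`).
#'
#' @param src,dst data.frames (or 2-column matrices) of matched `x`, `y`
#'   coordinates, pixels; at least 3 non-collinear pairs.
#'
#' @return An `affine2d` object: list with `A` (2 x 3 matrix) and `rms`
#'   (root-mean-square Euclidean residual, pixels).
#' @examples
#' src <- data.frame(x = c(0, 1, 0, 2), y = c(0, 0, 1, 2))
#' dst <- data.frame(x = src$x + 3, y = src$y - 2)
#' fit_affine(src, dst)$A
#' @export
fit_affine <- function(src, dst) {
  src <- as.data.frame(src); dst <- as.data.frame(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal rows")
  if (nrow(src) < 3L) stop("need at least 3 matched pairs")
  X <- cbind(src$x, src$y, 1)
  if (qr(X)$rank < 3L)
    stop("degenerate (collinear) points: affine transform is not identifiable")
  cf <- qr.solve(X, cbind(dst$x, dst$y))
  A <- t(cf)  # 2 x 3: rows are (a11 a12 tx), (a21 a22 ty)
  res <- cbind(dst$x, dst$y) - X %*% cf
  structure(list(A = A, rms = sqrt(mean(rowSums(res^2)))),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("2D affine transform (dst = A [x y 1]'):\n")
  print(round(x$A, 6))
  cat(sprintf("RMS residual: %.4g px\n", x$rms))
  invisible(x)
}

#' Apply an affine transform to a localization table
#'
#' Maps the `x`, `y` coordinates; all other columns and the metadata are
#' preserved.
#'
#' @param transform an `affine2d` (from [fit_affine()] or [read_affine()]).
#' @param locs a [loc_table] or data.frame with `x`, `y`.
#' @return the table with transformed coordinates.
#' @export
apply_affine <- function(transform, locs) {
  A <- transform$A
  x <- locs$x; y <- locs$y
  locs$x <- A[1, 1] * x + A[1, 2] * y + A[1, 3]
  locs$y <- A[2, 1] * x + A[2, 2] * y + A[2, 3]
  locs
}

#' Invert an affine transform
#'
#' @param transform an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
invert_affine <- function(transform) {
  L <- transform$A[, 1:2]
  t <- transform$A[, 3]
  Li <- solve(L)
  structure(list(A = cbind(Li, -Li %*% t), rms = NA_real_),
            class = "affine2d")
}

#' Store affine transforms as YAML
#'
#' Six numbers, row-major (`a11 a12 tx a21 a22 ty`), with the convention
#' `dst = A [x y 1]'` documented in the file.
#'
#' @param transform an `affine2d`.
#' @param path YAML file path.
#' @return `read_affine()` returns an `affine2d`; `write_affine()`
#'   invisibly returns `path`.
#' @export
write_affine <- function(transform, path) {
  yaml::write_yaml(list(convention = "dst = A [x y 1]'",
                        matrix_row_major = as.numeric(t(transform$A))),
                   path)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  doc <- yaml::read_yaml(path)
  v <- doc$matrix_row_major
  if (length(v) != 6L) stop("affine file must contain 6 numbers")
  structure(list(A = matrix(v, nrow = 2, byrow = TRUE), rms = NA_real_),
            class = "affine2d")
}

#' Inter-channel cross-talk from registered localization tables
#'
#' For a round in which only one dye (the `correct` channel's) is present,
#' counts the localizations falling within `radius` of the known docking
#' sites in every channel; the cross-talk of an incorrect channel is its
#' count divided by the correct channel's count.
#'
#' @param channel_tables named list of registered [loc_table]s, one per
#'   channel.
#' @param site_positions data.frame with `x`, `y` of the round's true
#'   docking sites.
#' @param correct name of the channel whose dye was imaged.
#' @param radius gate radius around each site, pixels.
#'
#' @return named numeric vector of cross-talk ratios for the incorrect
#'   channels (and 1 for the correct one), with attribute `counts`.
#' @export
crosstalk <- function(channel_tables, site_positions, correct, radius = 0.5) {
  if (!correct %in% names(channel_tables))
    stop("'correct' must name an element of channel_tables")
  counts <- vapply(channel_tables, function(tab)
    sum(!is.na(assign_to_sites(tab, site_positions, radius))), numeric(1))
  if (counts[[correct]] == 0)
    stop("no localizations near sites in the correct channel")
  ratios <- counts / counts[[correct]]
  attr(ratios, "counts") <- counts
  ratios
}
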
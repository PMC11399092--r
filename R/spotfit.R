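#' Detect candidate spots in a raw frame
#'
#' Candidates are strict local intensity maxima (within a box-sized window)
#' whose net gradient exceeds a threshold. The net gradient of a candidate
#' is the sum, over the pixels of its box, of the dot product of the local
#' intensity gradient (central differences) with the unit vector pointing
#' from the pixel toward the box center: light converging on the center
#' scores positive, flat or divergent structure scores near zero.
#' Non-maximum suppression keeps at most one candidate per box
#' neighbourhood.
#'
#' @param frame_image numeric matrix (rows = y, columns = x), photon counts.
#' @param box odd box side length, pixels (>= 3; default 7).
#' @param min_net_gradient detection threshold; measurement-specific, by
#'   convention determined manually per imaging round.
#'
#' @return data.frame with one row per candidate: `x`, `y` (integer pixel
#'   indices, 1-based column/row), `net_gradient`.
#' @export
detect_spots <- function(frame_image, box = 7, min_net_gradient = 0) {
  if (box %% 2 != 1 || box < 3) stop("box must be odd and >= 3")
  h <- nrow(frame_image); w <- ncol(frame_image)
  if (box > h || box > w) stop("box larger than the frame")
  half <- (box - 1L) / 2L
  # central-difference gradients
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (frame_image[, 3:w] - frame_image[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (frame_image[3:h, ] - frame_image[1:(h - 2), ]) / 2

  cand <- local_maxima(frame_image, half)
  cand <- cand[cand$x > half & cand$x <= w - half &
                 cand$y > half & cand$y <= h - half, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(x = integer(0), y = integer(0),
                      net_gradient = numeric(0)))
  off <- expand.grid(dx = -half:half, dy = -half:half)
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  nrm <- sqrt(off$dx^2 + off$dy^2)
  ux <- -off$dx / nrm  # unit vector from box pixel toward the center
  uy <- -off$dy / nrm
  ng <- vapply(seq_len(nrow(cand)), function(i) {
    rows <- cand$y[i] + off$dy
    cols <- cand$x[i] + off$dx
    idx <- cbind(rows, cols)
    sum(gx[idx] * ux + gy[idx] * uy)
  }, numeric(1))
  cand$net_gradient <- ng
  cand <- cand[cand$net_gradient > min_net_gradient, , drop = FALSE]
  # non-maximum suppression within one box (chebyshev distance)
  cand <- cand[order(-cand$net_gradient), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prior <- cand[keep, , drop = FALSE]
    keep[i] <- all(pmax(abs(prior$x - cand$x[i]),
                        abs(prior$y - cand$y[i])) >= box)
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# strict local maxima within a (2*half+1)^2 window
local_maxima <- function(img, half) {
  h <- nrow(img); w <- ncol(img)
  res <- vector("list", 0L)
  is_max <- matrix(TRUE, h, w)
  for (dy in -half:half) for (dx in -half:half) {
    if (dx == 0 && dy == 0) next
    sh <- shift_matrix(img, dy, dx)
    is_max <- is_max & (img > sh)
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(x = as.integer(idx[, 2L]), y = as.integer(idx[, 1L]))
}

# shift with -Inf padding so borders can still be maxima
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(-Inf, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Fit a pixel-integrated Gaussian to a spot candidate
#'
#' Least-squares fit of the model `bg + N * G(x, y, sx, sy)` over the
#' candidate box, where `G` is the 2D Gaussian integrated over each pixel
#' via per-axis CDF differences (not point-sampled). Initialization:
#' center at the brightest pixel, `sx = sy = sigma_prior`, background at
#' the box median, `N` at the background-subtracted box sum.
#'
#' @param frame_image numeric matrix (rows = y, columns = x).
#' @param candidate one-row data.frame from [detect_spots()] (or any list
#'   with integer `x`, `y`).
#' @param box odd box side, pixels.
#' @param sigma_prior PSF sigma initialization, pixels.
#' @param max_iter iteration cap for the optimizer (default 100);
#'   non-convergence flags the record so it can be excluded downstream.
#'
#' @return one-row data.frame: `x`, `y` (continuous pixels, top-left pixel
#'   corner origin), `photons`, `bg`, `sx`, `sy`, `converged`, `rss`.
#' @export
fit_spot <- function(frame_image, candidate, box = 7, sigma_prior = 1,
                     max_iter = 100) {
  if (box %% 2 != 1 || box < 3) stop("box must be odd and >= 3")
  half <- (box - 1L) / 2L
  cx <- as.integer(candidate$x[1L]); cy <- as.integer(candidate$y[1L])
  h <- nrow(frame_image); w <- ncol(frame_image)
  if (cx - half < 1L || cx + half > w || cy - half < 1L || cy + half > h)
    stop("candidate box out of bounds")
  rows <- (cy - half):(cy + half)
  cols <- (cx - half):(cx + half)
  z <- frame_image[rows, cols]
  # continuous coordinates of pixel edges: pixel (r, c) covers [c-1, c) x [r-1, r)
  xe <- c(cols - 1, cols[box])
  ye <- c(rows - 1, rows[box])
  bright <- which(z == max(z), arr.ind = TRUE)[1L, ]
  bg0 <- median(z)
  N0 <- max(sum(z) - bg0 * box^2, 1)
  start <- list(x0 = cols[bright[2L]] - 0.5, y0 = rows[bright[1L]] - 0.5,
                N = N0, bg = max(bg0, 0), sx = sigma_prior, sy = sigma_prior)
  zv <- as.vector(z)
  model <- function(x0, y0, N, bg, sx, sy) {
    px <- diff(pnorm(xe, mean = x0, sd = sx))
    py <- diff(pnorm(ye, mean = y0, sd = sy))
    as.vector(bg + N * outer(py, px))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(zv ~ model(x0, y0, N, bg, sx, sy), start = start,
                      lower = c(x0 = min(xe), y0 = min(ye), N = 0, bg = 0,
                                sx = 0.1, sy = 0.1),
                      upper = c(x0 = max(xe), y0 = max(ye), N = Inf, bg = Inf,
                                sx = box, sy = box),
                      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  if (is.null(fit))
    return(data.frame(x = NA_real_, y = NA_real_, photons = NA_real_,
                      bg = NA_real_, sx = NA_real_, sy = NA_real_,
                      converged = FALSE, rss = NA_real_))
  co <- as.list(coef(fit))
  converged <- isTRUE(fit$convInfo$isConv)
  data.frame(x = co$x0, y = co$y0, photons = co$N, bg = co$bg,
             sx = co$sx, sy = co$sy, converged = converged,
             rss = sum(stats::resid(fit)^2))
}
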
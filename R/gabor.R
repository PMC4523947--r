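#' Gabor filter parameters
#'
#' Parameter set for one V1-like Gabor kernel.  The envelope width `sigma` is
#' derived from the wavelength `lambda` and the half-response spatial
#' bandwidth `b` (in octaves) by the standard relation
#' \deqn{\sigma = \frac{\lambda}{\pi}\sqrt{\frac{\ln 2}{2}}
#'       \frac{2^b + 1}{2^b - 1}.}
#'
#' @param lambda Wavelength in pixels (default 2).
#' @param bandwidth Spatial bandwidth in octaves (default 1.5).
#' @param theta Orientation in radians (default 0).
#' @param psi Phase offset in radians: 0 responds to a white-on-black bar,
#'   `pi` to black-on-white (default 0).
#' @param gamma Spatial aspect ratio (default 0.5).
#' @return A `gabor_params` list with the derived `sigma`.
#' @export
gabor_params <- function(lambda = 2, bandwidth = 1.5, theta = 0, psi = 0,
                         gamma = 0.5) {
  stopifnot(lambda > 0, bandwidth > 0, gamma > 0)
  sigma <- (lambda / pi) * sqrt(log(2) / 2) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
  structure(list(lambda = lambda, bandwidth = bandwidth, theta = theta,
                 psi = psi, gamma = gamma, sigma = sigma),
            class = "gabor_params")
}

#' Evaluate a Gabor function at a point
#'
#' \deqn{g(x, y) = \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
#'       \cos\!\left(\frac{2\pi x'}{\lambda} + \psi\right)}
#' with \eqn{x' = x\cos\theta + y\sin\theta},
#' \eqn{y' = -x\sin\theta + y\cos\theta}.
#'
#' @param x,y Coordinates of a light impulse relative to the kernel center
#'   (vectorized).
#' @param params A [gabor_params()] object.
#' @return Filter value(s).
#' @examples
#' gabor_value(0, 0, gabor_params(psi = 0))   # 1
#' gabor_value(0, 0, gabor_params(psi = pi))  # -1
#' @export
gabor_value <- function(x, y, params) {
  xp <- x * cos(params$theta) + y * sin(params$theta)
  yp <- -x * sin(params$theta) + y * cos(params$theta)
  exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$sigma^2)) *
    cos(2 * pi * xp / params$lambda + params$psi)
}

#' Build the retinal Gabor filter bank
#'
#' Discretizes one kernel per (orientation, phase) pair on a
#' `(2 * support + 1)^2` pixel grid.  With the default four orientations and
#' two phases the bank holds 8 kernels.  Each kernel is mean-subtracted so
#' that spatially uniform images produce zero output.  An optional second
#' wavelength doubles the bank to 16 kernels.
#'
#' @param lambda Wavelength(s) in pixels; give two values for a two-scale
#'   bank (default 2).
#' @param bandwidth Bandwidth in octaves (default 1.5).
#' @param thetas Orientations in radians (default `c(0, pi/4, pi/2, 3*pi/4)`).
#' @param psis Phases in radians (default `c(0, pi)`).
#' @param gamma Aspect ratio (default 0.5).
#' @param support Kernel half-width in pixels; default `ceiling(4 * max(lambda))`.
#'   A warning is issued if the support truncates the envelope (`support <
#'   sigma`).
#' @return A `gabor_bank`: list of kernel matrices plus a `params` tibble.
#' @export
gabor_bank <- function(lambda = 2, bandwidth = 1.5,
                       thetas = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       psis = c(0, pi), gamma = 0.5, support = NULL) {
  if (is.null(support)) support <- ceiling(4 * max(lambda))
  grid <- expand.grid(lambda = lambda, psi = psis, theta = thetas,
                      KEEP.OUT.ATTRS = FALSE)
  xs <- -support:support
  kernels <- vector("list", nrow(grid))
  sigmas <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- gabor_params(grid$lambda[i], bandwidth, grid$theta[i], grid$psi[i],
                      gamma)
    sigmas[i] <- p$sigma
    if (support < p$sigma) {
      warning(sprintf("kernel support %d px is below sigma = %.2f px: envelope truncated",
                      support, p$sigma))
    }
    k <- outer(xs, xs, function(yy, xx) gabor_value(xx, yy, p))
    kernels[[i]] <- k - mean(k)
  }
  params <- tibble::as_tibble(grid)
  params$sigma <- sigmas
  params$kernel <- seq_len(nrow(grid))
  structure(list(kernels = kernels, params = params, support = support,
                 cache = new.env(parent = emptyenv())),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d kernels (%d px support), lambda = %s, theta = %s\n",
              length(x$kernels), 2 * x$support + 1,
              paste(unique(x$params$lambda), collapse = "/"),
              paste(round(unique(x$params$theta), 3), collapse = ", ")))
  invisible(x)
}

# --- toroidal-wrap convolution ---------------------------------------------

# Cross-correlation of `x` with a small kernel under toroidal wrap:
# r[i, j] = sum_{a, b} k[a, b] * x[i + a, j + b]  (offsets centered on k).
# The kernel is laid out in wrap order so its center lands at index (1, 1).
wrap_kernel_fft <- function(k, dims) {
  h <- dims[1]; w <- dims[2]
  kh <- nrow(k); kw <- ncol(k)
  stopifnot(kh <= h, kw <= w)
  oy <- (kh - 1) / 2; ox <- (kw - 1) / 2
  kp <- matrix(0, h, w)
  ridx <- ((seq_len(kh) - 1 - oy) %% h) + 1
  cidx <- ((seq_len(kw) - 1 - ox) %% w) + 1
  kp[ridx, cidx] <- k
  stats::fft(kp)
}

conv_wrap <- function(x, kfft) {
  Re(stats::fft(stats::fft(x) * Conj(kfft), inverse = TRUE)) / length(x)
}

#' Apply a Gabor bank to a retinal image
#'
#' Convolves the image with every kernel of the bank under toroidal wrap
#' boundary conditions (which preserve exact shift-equivariance) and, by
#' default, half-rectifies the result so the layer-1 inputs are
#' firing-rate-like; contrast polarity is carried by the two phases.
#'
#' @param image Numeric matrix (rows = retina y).
#' @param bank A [gabor_bank()].
#' @param rectify Set negative responses to zero (default `TRUE`).
#' @return A `retinal_activation` 3-D array `[y, x, kernel]`.
#' @export
gabor_filter <- function(image, bank, rectify = TRUE) {
  stopifnot(is.matrix(image), inherits(bank, "gabor_bank"))
  dims <- dim(image)
  key <- paste(dims, collapse = "x")
  kffts <- bank$cache[[key]]
  if (is.null(kffts)) {
    kffts <- lapply(bank$kernels, wrap_kernel_fft, dims = dims)
    bank$cache[[key]] <- kffts
  }
  fx <- stats::fft(image)
  out <- array(0, c(dims, length(bank$kernels)))
  n <- prod(dims)
  for (i in seq_along(bank$kernels)) {
    r <- Re(stats::fft(fx * Conj(kffts[[i]]), inverse = TRUE)) / n
    if (rectify) r[r < 0] <- 0
    out[, , i] <- r
  }
  structure(out, class = "retinal_activation")
}
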
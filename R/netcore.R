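#' Sparse topological connectivity between two layers
#'
#' Each post-synaptic neuron draws `n_conn` distinct afferents from the
#' topologically corresponding position in the pre-synaptic sheet, using an
#' isotropic 2-D Gaussian over grid offsets whose scale is calibrated so the
#' stated `radius` contains approximately 67% of the realized connections.
#' The calibration accounts for the discreteness of the grid and for the
#' draws being distinct: the inclusion probability of each source cell under
#' repeated Gaussian draws until `n_conn` distinct sources are found is
#' modeled as \eqn{1 - (1 - p_c)^T} (an occupancy approximation), and the
#' Gaussian scale is solved numerically so the expected in-radius fraction
#' equals the target.  Where the target is geometrically unattainable (fewer
#' than `0.67 * n_conn` grid cells inside the radius, as in heavily
#' scaled-down presets) the closest attainable scale is used.  The sheet is
#' treated as a torus, so no neuron is starved near the border.  When the
#' pre-synaptic sheet is a filter volume (`pre_dims = c(rows, cols, k)`),
#' the filter index of each afferent is drawn uniformly.  Weights are
#' initialized to positive uniform random values and renormalized to unit
#' length per neuron.
#'
#' @param pre_dims Pre-synaptic dimensions `c(rows, cols)` or
#'   `c(rows, cols, k)`.
#' @param post_dims Post-synaptic grid `c(rows, cols)`.
#' @param n_conn Afferents per post-synaptic neuron.
#' @param radius Topological radius in pre-synaptic grid units.
#' @param seed Optional integer seed (the map is deterministic given it).
#' @return A `synaptic_map`: list with `idx` (neurons x n_conn matrix of
#'   linear indices into the pre-synaptic array), `w` (weights, unit-norm
#'   rows), `dist` (grid distance of each afferent from the neuron's
#'   topological center) and the geometry fields.
#' @export
build_connectivity <- function(pre_dims, post_dims, n_conn, radius,
                               seed = NULL) {
  stopifnot(length(pre_dims) %in% c(2, 3), length(post_dims) == 2,
            n_conn >= 1, radius > 0)
  ph <- pre_dims[1]; pw <- pre_dims[2]
  nk <- if (length(pre_dims) == 3) pre_dims[3] else 1L
  if (n_conn > ph * pw * nk) {
    stop("n_conn exceeds the number of pre-synaptic sources", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  sigma <- calibrate_conn_sigma(pre_dims, post_dims, n_conn, radius)
  n_post <- post_dims[1] * post_dims[2]
  idx <- matrix(0L, n_post, n_conn)
  dist <- matrix(0, n_post, n_conn)
  # post neuron i (column-major): grid position -> pre-sheet center
  rows <- ((seq_len(n_post) - 1L) %% post_dims[1]) + 1L
  cols <- ((seq_len(n_post) - 1L) %/% post_dims[1]) + 1L
  y0 <- (rows - 0.5) * ph / post_dims[1] + 0.5
  x0 <- (cols - 0.5) * pw / post_dims[2] + 0.5
  for (i in seq_len(n_post)) {
    got_idx <- integer(0); got_d <- numeric(0)
    tries <- 0L
    while (length(got_idx) < n_conn) {
      tries <- tries + 1L
      if (tries > 60L) {
        stop(sprintf("cannot draw %d distinct afferents within reach of neuron %d (radius %.2f)",
                     n_conn, i, radius), call. = FALSE)
      }
      m <- 2L * n_conn
      dy <- stats::rnorm(m, 0, sigma)
      dx <- stats::rnorm(m, 0, sigma)
      yy <- ((round(y0[i] + dy) - 1) %% ph) + 1
      xx <- ((round(x0[i] + dx) - 1) %% pw) + 1
      kk <- if (nk > 1L) sample.int(nk, m, replace = TRUE) else rep(1L, m)
      lin <- as.integer(yy + (xx - 1) * ph + (kk - 1) * ph * pw)
      # wrap-aware grid distance between source cell and topological center
      ddy <- abs(yy - y0[i]); ddy <- pmin(ddy, ph - ddy)
      ddx <- abs(xx - x0[i]); ddx <- pmin(ddx, pw - ddx)
      d <- sqrt(ddy^2 + ddx^2)
      new <- !(lin %in% got_idx) & !duplicated(lin)
      got_idx <- c(got_idx, lin[new])
      got_d <- c(got_d, d[new])
    }
    idx[i, ] <- got_idx[seq_len(n_conn)]
    dist[i, ] <- got_d[seq_len(n_conn)]
  }
  w <- matrix(stats::runif(n_post * n_conn), n_post, n_conn)
  w <- w / sqrt(rowSums(w^2))
  structure(list(idx = idx, w = w, dist = dist, pre_dims = pre_dims,
                 post_dims = post_dims, n_conn = n_conn, radius = radius),
            class = "synaptic_map")
}

# Expected fraction of the n_conn distinct afferents that land within
# `radius`, under Gaussian-with-rounding draws repeated until n_conn distinct
# sources are found (occupancy approximation; deterministic).
occupancy_in_radius <- function(sigma, pre_dims, post_dims, n_conn, radius) {
  ph <- pre_dims[1]; pw <- pre_dims[2]
  nk <- if (length(pre_dims) == 3) pre_dims[3] else 1L
  # fractional offset of the topological center from the cell grid (shared
  # by all neurons when the layer sizes are integer multiples)
  y0 <- 0.5 * ph / post_dims[1] + 0.5
  x0 <- 0.5 * pw / post_dims[2] + 0.5
  fy <- y0 - round(y0); fx <- x0 - round(x0)
  ext <- ceiling(max(4 * sigma, radius + 3))
  dy <- (-ext:ext) - fy
  dx <- (-ext:ext) - fx
  d2 <- outer(dy^2, dx^2, "+")
  p <- exp(-d2 / (2 * sigma^2))
  p <- as.vector(p) / sum(p) / nk
  inside <- rep(as.vector(d2) <= radius^2, nk)
  p <- rep(p, nk)
  # effective number of raw draws T so that E[#distinct] = n_conn
  g <- function(tt) sum(1 - (1 - p)^tt) - n_conn
  hi <- n_conn
  while (g(hi) < 0 && hi < n_conn * 1e6) hi <- hi * 4
  tt <- stats::uniroot(g, c(1, hi))$root
  inc <- 1 - (1 - p)^tt
  sum(inc[inside]) / n_conn
}

calibrate_conn_sigma <- function(pre_dims, post_dims, n_conn, radius,
                                 target = 0.67) {
  f <- function(s) occupancy_in_radius(s, pre_dims, post_dims, n_conn,
                                       radius) - target
  nk <- if (length(pre_dims) == 3) pre_dims[3] else 1L
  # smallest scale that keeps >= ~1.5x n_conn distinct sources in
  # comfortable reach (2.5 sigma), so distinct sampling cannot stall
  sigma_min <- sqrt(1.5 * n_conn / (nk * pi)) / 2.5
  lo <- max(0.35 * radius, sigma_min); hi <- max(1.5 * radius, lo * 1.01)
  flo <- f(lo)
  if (flo < 0) return(lo)  # target unattainable at feasible scales
  fhi <- f(hi)
  if (fhi > 0) return(hi)
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-3 * radius)$root
}

#' @export
print.synaptic_map <- function(x, ...) {
  cat(sprintf("<synaptic_map> %d neurons x %d afferents, radius %.2f, in-radius fraction %.3f\n",
              nrow(x$idx), x$n_conn, x$radius, mean(x$dist <= x$radius)))
  invisible(x)
}

#' Linear feed-forward activation
#'
#' \eqn{h_i = \sum_j w_{ij} y_j} over the afferents of each neuron.
#'
#' @param map A [build_connectivity()] synaptic map.
#' @param pre_rates Numeric vector of pre-synaptic firing rates (length =
#'   `prod(pre_dims)`).
#' @return Numeric vector of activations, one per post-synaptic neuron.
#' @export
activate <- function(map, pre_rates) {
  if (length(pre_rates) != prod(map$pre_dims)) {
    stop(sprintf("pre_rates has length %d, expected %d",
                 length(pre_rates), prod(map$pre_dims)), call. = FALSE)
  }
  pm <- pre_rates[map$idx]
  dim(pm) <- dim(map$idx)
  rowSums(map$w * pm)
}

# --- lateral interaction ----------------------------------------------------

#' Lateral interaction filter specification
#'
#' @param mode `"competitive"` (graded lateral inhibition: a negative
#'   Gaussian surround with a center coefficient of one minus the surround
#'   sum, so the kernel sums to exactly 1) or `"som"` (a Mexican-hat
#'   difference of Gaussians with short-range excitation and longer-range
#'   inhibition).
#' @param delta,sigma Contrast and radius of the competitive surround.
#' @param delta_E,sigma_E,delta_I,sigma_I Excitatory/inhibitory contrasts and
#'   radii of the SOM kernel.
#' @return A `lateral_spec` list.
#' @export
lateral_spec <- function(mode = c("competitive", "som"), delta = 1.5,
                         sigma = 1.38, delta_E = 5.35, sigma_E = 1.4,
                         delta_I = 1.5, sigma_I = 2.76) {
  mode <- match.arg(mode)
  if (mode == "competitive") stopifnot(sigma > 0, delta >= 0)
  else stopifnot(sigma_E > 0, sigma_I > 0, delta_E >= 0, delta_I >= 0)
  structure(list(mode = mode, delta = delta, sigma = sigma,
                 delta_E = delta_E, sigma_E = sigma_E,
                 delta_I = delta_I, sigma_I = sigma_I),
            class = "lateral_spec")
}

#' Build a lateral interaction kernel on a layer grid
#'
#' Competitive mode: \eqn{I_{a,b} = -\delta \exp(-(a^2+b^2)/\sigma^2)} off
#' center, with the center coefficient \eqn{1 - \sum_{(a,b) \ne 0} I_{a,b}},
#' so the discrete kernel sums to exactly 1 and a uniform activation pattern
#' is a fixed point of the filter.  SOM mode:
#' \eqn{I_{a,b} = -\delta_I \exp(-(a^2+b^2)/\sigma_I^2) +
#'      \delta_E \exp(-(a^2+b^2)/\sigma_E^2)} at every offset, giving
#' \eqn{\delta_E - \delta_I} at the origin.
#'
#' Offsets are taken on the torus of the layer grid.
#'
#' @param spec A [lateral_spec()].
#' @param dims Layer grid `c(rows, cols)`.
#' @param layout `"wrap"` (center at element `[1, 1]`, FFT-ready) or
#'   `"centered"` (center in the middle, for inspection).
#' @return A `dims`-sized kernel matrix.
#' @export
lateral_kernel <- function(spec, dims, layout = c("wrap", "centered")) {
  layout <- match.arg(layout)
  h <- dims[1]; w <- dims[2]
  ai <- ifelse(seq_len(h) - 1 <= h / 2, seq_len(h) - 1, seq_len(h) - 1 - h)
  bi <- ifelse(seq_len(w) - 1 <= w / 2, seq_len(w) - 1, seq_len(w) - 1 - w)
  d2 <- outer(ai^2, bi^2, "+")
  if (spec$mode == "competitive") {
    k <- -spec$delta * exp(-d2 / spec$sigma^2)
    k[1, 1] <- 0
    k[1, 1] <- 1 - sum(k)
  } else {
    k <- -spec$delta_I * exp(-d2 / spec$sigma_I^2) +
      spec$delta_E * exp(-d2 / spec$sigma_E^2)
  }
  if (layout == "centered") {
    k <- k[order(ai), order(bi), drop = FALSE]
  }
  k
}

#' Apply lateral interaction to a layer's activations
#'
#' Convolves the activation sheet with the lateral kernel under toroidal
#' wrap boundary conditions.
#'
#' @param h Numeric matrix of activations on the layer grid, or a vector
#'   (then `dims` must be given).
#' @param spec A [lateral_spec()].
#' @param dims Layer grid, required when `h` is a vector.
#' @return Filtered activations, same shape as `h`.
#' @export
lateral_filter <- function(h, spec, dims = NULL) {
  vec <- !is.matrix(h)
  if (vec) {
    stopifnot(!is.null(dims))
    h <- matrix(h, dims[1], dims[2])
  }
  kf <- stats::fft(lateral_kernel(spec, dim(h)))
  r <- Re(stats::fft(stats::fft(h) * Conj(kf), inverse = TRUE)) / length(h)
  if (vec) as.vector(r) else r
}

# --- sigmoid contrast enhancement ------------------------------------------

#' Sigmoid contrast enhancement with percentile-controlled sparseness
#'
#' \eqn{y = 1 / (1 + \exp(-2\beta(r - \alpha)))}, where the threshold
#' \eqn{\alpha} is set to the given percentile of the current activation
#' distribution, so that (100 - percentile)% of neurons fire above 0.5.  The
#' threshold is recomputed for every presentation.
#'
#' @param r Numeric vector of lateral-filtered activations.
#' @param percentile Threshold percentile in (0, 100), e.g. 96 for 4%
#'   sparseness.
#' @param beta Sigmoid slope.
#' @return Firing rates in `[0, 1]`.
#' @export
sigmoid_transfer <- function(r, percentile, beta) {
  stopifnot(length(r) > 0, percentile > 0, percentile < 100, beta > 0)
  alpha <- stats::quantile(r, percentile / 100, names = FALSE)
  1 / (1 + exp(-2 * beta * (r - alpha)))
}

# --- learning ---------------------------------------------------------------

#' One learning update on a synaptic map
#'
#' Hebb rule: \eqn{\delta w_{ij} = k\, y_i\, y_j}.  Trace rule:
#' \eqn{\delta w_{ij} = k\, \bar r_i^{\tau-1}\, y_j} using the trace from the
#' previous timestep, after which the trace is updated as
#' \eqn{\bar r_i^{\tau} = (1 - \eta)\, y_i^{\tau} + \eta\, \bar r_i^{\tau-1}}.
#' After the update every weight vector is renormalized to unit length.
#'
#' @param map A `synaptic_map`.
#' @param pre_rates Pre-synaptic firing rates \eqn{y_j}.
#' @param post_rates Post-synaptic firing rates \eqn{y_i}.
#' @param rule `"hebb"` or `"trace"`.
#' @param rate Learning rate `k`.
#' @param trace Previous trace \eqn{\bar r^{\tau-1}} (trace rule only);
#'   defaults to zero.
#' @param eta Trace decay \eqn{\eta \in [0, 1]} (default 0.8).
#' @return List with the updated `map` and the new `trace`.
#' @export
learn_step <- function(map, pre_rates, post_rates, rule = c("hebb", "trace"),
                       rate = 0.1, trace = NULL, eta = 0.8) {
  rule <- match.arg(rule)
  stopifnot(eta >= 0, eta <= 1, rate >= 0)
  if (is.null(trace)) trace <- numeric(length(post_rates))
  pm <- pre_rates[map$idx]
  dim(pm) <- dim(map$idx)
  fac <- if (rule == "hebb") post_rates else trace
  w <- map$w + rate * fac * pm
  nrm <- sqrt(rowSums(w^2))
  if (any(nrm == 0)) {
    stop("weight vector collapsed to zero: renormalization undefined",
         call. = FALSE)
  }
  map$w <- w / nrm
  trace_new <- (1 - eta) * post_rates + eta * trace
  list(map = map, trace = trace_new)
}

# --- network ----------------------------------------------------------------

full_scale_tables <- function() {
  list(
    dims = list(c(128, 128), c(128, 128), c(128, 128), c(128, 128)),
    n_conn = c(201, 100, 100, 100),
    radius = c(6, 6, 9, 12),
    competitive = list(sigma = c(1.38, 2.7, 4.0, 6.0),
                       delta = c(1.5, 1.5, 1.6, 1.4)),
    som = list(sigma_E = c(1.4, 1.1, 0.8, 1.2),
               delta_E = c(5.35, 33.15, 117.57, 120.12),
               sigma_I = c(2.76, 5.4, 8.0, 12.0),
               delta_I = c(1.5, 1.5, 1.6, 1.4)),
    sigmoid = list(percentile = c(99.2, 98, 88, 91),
                   beta = c(190, 40, 75, 26))
  )
}

make_layer_config <- function(tab, l, dims, n_conn, radius, mode) {
  lat <- if (mode == "competitive") {
    lateral_spec("competitive", delta = tab$competitive$delta[l],
                 sigma = tab$competitive$sigma[l])
  } else {
    lateral_spec("som", delta_E = tab$som$delta_E[l],
                 sigma_E = tab$som$sigma_E[l],
                 delta_I = tab$som$delta_I[l], sigma_I = tab$som$sigma_I[l])
  }
  list(dims = dims, n_conn = n_conn, radius = radius, lateral = lat,
       sigmoid = list(percentile = tab$sigmoid$percentile[l],
                      beta = tab$sigmoid$beta[l]))
}

#' Network configuration presets
#'
#' Returns a full network configuration for a named preset.  The full-scale
#' presets reproduce the published parameter tables verbatim (256x256 retina,
#' 128x128 layers, 201/100 connections, radii 6/6/9/12, the competitive and
#' SOM lateral tables, and the per-layer sigmoid percentiles 99.2/98/88/91
#' with slopes 190/40/75/26).  The `test_small` presets are desk-scale:
#' 64x64 retina, three 32x32 layers, 50 afferents per neuron and connection
#' radii halved; lateral kernels and sigmoid parameters are local per-neuron
#' properties and are kept at their table values.
#'
#' Available presets: `study1` (3 competitive layers, full scale),
#' `study1_som` (3 SOM layers), `study1_trace` (4 SOM layers),
#' `study2` (3 SOM layers of 64x64 on a 256 retina), `study3`
#' (as `study2`), `test_small`, `test_small_som`, and `test_small_trace`
#' (4 SOM layers at desk scale, for translation-invariance training).
#'
#' @param name Preset name.
#' @param lateral Optionally override the lateral mode
#'   (`"competitive"`/`"som"`).
#' @return A `network_config` list with `retina`, `gabor` and `layers`.
#' @export
network_preset <- function(name = c("study1", "study1_som", "study1_trace",
                                    "study2", "study3", "test_small",
                                    "test_small_som", "test_small_trace"),
                           lateral = NULL) {
  name <- match.arg(name)
  tab <- full_scale_tables()
  cfg <- switch(name,
    study1 = list(retina = c(256, 256), n_layers = 3, mode = "competitive",
                  dims = tab$dims, n_conn = tab$n_conn, radius = tab$radius),
    study1_som = list(retina = c(256, 256), n_layers = 3, mode = "som",
                      dims = tab$dims, n_conn = tab$n_conn,
                      radius = tab$radius),
    study1_trace = list(retina = c(256, 256), n_layers = 4, mode = "som",
                        dims = tab$dims, n_conn = tab$n_conn,
                        radius = tab$radius),
    study2 = ,
    study3 = list(retina = c(256, 256), n_layers = 3, mode = "som",
                  dims = rep(list(c(64, 64)), 4), n_conn = tab$n_conn,
                  radius = tab$radius),
    test_small = list(retina = c(64, 64), n_layers = 3, mode = "competitive",
                      dims = rep(list(c(32, 32)), 4),
                      n_conn = c(50, 50, 50, 50),
                      radius = tab$radius / 2),
    test_small_som = list(retina = c(64, 64), n_layers = 3, mode = "som",
                          dims = rep(list(c(32, 32)), 4),
                          n_conn = c(50, 50, 50, 50),
                          radius = tab$radius / 2),
    test_small_trace = list(retina = c(64, 64), n_layers = 4, mode = "som",
                            dims = rep(list(c(32, 32)), 4),
                            n_conn = c(50, 50, 50, 50),
                            radius = tab$radius / 2)
  )
  if (!is.null(lateral)) cfg$mode <- match.arg(lateral, c("competitive", "som"))
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    make_layer_config(tab, l, cfg$dims[[l]], cfg$n_conn[l], cfg$radius[l],
                      cfg$mode)
  })
  structure(list(name = name, retina = cfg$retina, mode = cfg$mode,
                 gabor = list(lambda = 2, bandwidth = 1.5, gamma = 0.5),
                 layers = layers),
            class = "network_config")
}

#' Build an untrained network from a configuration
#'
#' Instantiates the Gabor bank and every layer's sparse topological
#' connectivity with random unit-norm weights.
#'
#' @param config A [network_preset()] (or compatible) configuration.
#' @param seed Integer seed controlling connectivity and weight
#'   initialization.
#' @return A `contour_network`.
#' @export
build_network <- function(config, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  bank <- gabor_bank(lambda = config$gabor$lambda,
                     bandwidth = config$gabor$bandwidth,
                     gamma = config$gabor$gamma)
  n_k <- length(bank$kernels)
  layers <- vector("list", length(config$layers))
  pre_dims <- c(config$retina, n_k)
  for (l in seq_along(config$layers)) {
    lc <- config$layers[[l]]
    map <- build_connectivity(pre_dims, lc$dims, lc$n_conn, lc$radius,
                              seed = seed + 1000L * l)
    layers[[l]] <- list(dims = lc$dims, map = map, lateral = lc$lateral,
                        sigmoid = lc$sigmoid,
                        lat_kfft = stats::fft(lateral_kernel(lc$lateral,
                                                             lc$dims)))
    pre_dims <- lc$dims
  }
  structure(list(config = config, bank = bank, layers = layers, seed = seed),
            class = "contour_network")
}

#' @export
print.contour_network <- function(x, ...) {
  cat(sprintf("<contour_network> preset '%s': retina %dx%d, %d layers (%s lateral)\n",
              x$config$name, x$config$retina[1], x$config$retina[2],
              length(x$layers), x$config$mode))
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  layer %d: %dx%d, %d afferents, radius %.2f\n", l,
                ly$dims[1], ly$dims[2], ly$map$n_conn, ly$map$radius))
  }
  invisible(x)
}

layer_lateral_apply <- function(layer, h) {
  hm <- matrix(h, layer$dims[1], layer$dims[2])
  as.vector(Re(stats::fft(stats::fft(hm) * Conj(layer$lat_kfft),
                          inverse = TRUE)) / length(hm))
}

layer_forward <- function(layer, pre_rates) {
  h <- activate(layer$map, pre_rates)
  r <- layer_lateral_apply(layer, h)
  y <- sigmoid_transfer(r, layer$sigmoid$percentile, layer$sigmoid$beta)
  list(h = h, r = r, y = y)
}

#' Propagate one image through the network
#'
#' Applies the Gabor bank, then `activate -> lateral_filter ->
#' sigmoid_transfer` at each layer in sequence.  Deterministic given the
#' weights.
#'
#' @param net A `contour_network`.
#' @param image Retina-sized image matrix.
#' @return List with `gabor` (flattened retinal activation vector) and
#'   `layers` (per-layer list of `h`, `r`, `y`).
#' @export
forward_pass <- function(net, image) {
  stopifnot(inherits(net, "contour_network"))
  if (!all(dim(image)[1:2] == net$config$retina)) {
    stop(sprintf("image is %dx%d but the retina is %dx%d",
                 nrow(image), ncol(image),
                 net$config$retina[1], net$config$retina[2]), call. = FALSE)
  }
  g <- as.vector(gabor_filter(unclass_image(image), net$bank))
  pre <- g
  states <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    states[[l]] <- layer_forward(net$layers[[l]], pre)
    pre <- states[[l]]$y
  }
  list(gabor = g, layers = states, top = states[[length(states)]]$y)
}

#' Train the network on a presentation sequence
#'
#' Layers are trained one at a time, bottom-up, with lower layers frozen;
#' each layer sees `epochs` full passes of the sequence.  For the trace rule
#' the post-synaptic memory trace is reset to zero at every object boundary
#' so temporal binding never spans two objects.  Outputs of trained lower
#' layers are cached per unique stimulus, which is exact because frozen
#' layers are deterministic.
#'
#' @param net A `contour_network` (untrained or to be trained further).
#' @param sequence A [make_sequence()] presentation sequence.
#' @param rule `"hebb"` or `"trace"`.
#' @param rate Learning rate `k` (default 0.1).
#' @param eta Trace decay (default 0.8).
#' @param epochs Passes of the sequence per layer (default 50).
#' @param schedule `"sequential"` (default): layers trained one at a time,
#'   bottom-up, lower layers frozen, `epochs` passes each.
#'   `"simultaneous"`: every layer learns in each pass as activity propagates
#'   upward, for `epochs` passes total.
#' @param verbose Print per-layer progress.
#' @return The trained network, with a `history` attribute: a tibble of the
#'   mean absolute weight change per (layer, epoch).
#' @export
train_network <- function(net, sequence, rule = c("hebb", "trace"),
                          rate = 0.1, eta = 0.8, epochs = 50,
                          schedule = c("sequential", "simultaneous"),
                          verbose = FALSE) {
  rule <- match.arg(rule)
  schedule <- match.arg(schedule)
  stopifnot(inherits(net, "contour_network"),
            inherits(sequence, "presentation_sequence"),
            nrow(sequence$frames) > 0)
  keys <- names(sequence$images)
  pre_cache <- lapply(sequence$images,
                      function(img) as.vector(gabor_filter(img, net$bank)))
  frames <- sequence$frames
  frame_key <- match(frames$key, keys)
  hist <- list()
  if (schedule == "simultaneous") {
    n_layers <- length(net$layers)
    traces <- lapply(net$layers, function(l) numeric(prod(l$dims)))
    for (ep in seq_len(epochs)) {
      dw_acc <- numeric(n_layers)
      for (f in seq_len(nrow(frames))) {
        pre <- pre_cache[[frame_key[f]]]
        if (frames$boundary[f]) {
          traces <- lapply(net$layers, function(l) numeric(prod(l$dims)))
        }
        for (l in seq_len(n_layers)) {
          layer <- net$layers[[l]]
          st <- layer_forward(layer, pre)
          w_old <- layer$map$w
          up <- learn_step(layer$map, pre, st$y, rule = rule, rate = rate,
                           trace = traces[[l]], eta = eta)
          net$layers[[l]]$map <- up$map
          traces[[l]] <- up$trace
          dw_acc[l] <- dw_acc[l] + mean(abs(up$map$w - w_old))
          pre <- st$y
        }
      }
      hist[[length(hist) + 1]] <- tibble::tibble(
        layer = seq_len(n_layers), epoch = ep,
        mean_abs_dw = dw_acc / nrow(frames))
      if (verbose) message(sprintf("epoch %d/%d (simultaneous)", ep, epochs))
    }
    attr(net, "history") <- dplyr::bind_rows(hist)
    attr(net, "trained") <- rule
    return(net)
  }
  for (l in seq_along(net$layers)) {
    layer <- net$layers[[l]]
    n_post <- prod(layer$dims)
    for (ep in seq_len(epochs)) {
      trace <- numeric(n_post)
      dw_acc <- 0
      for (f in seq_len(nrow(frames))) {
        pre <- pre_cache[[frame_key[f]]]
        st <- layer_forward(layer, pre)
        if (frames$boundary[f]) trace <- numeric(n_post)
        w_old <- layer$map$w
        up <- learn_step(layer$map, pre, st$y, rule = rule, rate = rate,
                         trace = trace, eta = eta)
        layer$map <- up$map
        trace <- up$trace
        dw_acc <- dw_acc + mean(abs(layer$map$w - w_old))
      }
      hist[[length(hist) + 1]] <- tibble::tibble(
        layer = l, epoch = ep, mean_abs_dw = dw_acc / nrow(frames))
    }
    net$layers[[l]] <- layer
    # next layer's inputs: this layer's (now frozen) outputs per stimulus
    pre_cache <- lapply(pre_cache, function(pre) layer_forward(layer, pre)$y)
    if (verbose) {
      message(sprintf("trained layer %d (%s, %d epochs)", l, rule, epochs))
    }
  }
  attr(net, "history") <- dplyr::bind_rows(hist)
  attr(net, "trained") <- rule
  net
}

#' Record responses of network cells to every frame of a sequence
#'
#' Runs a forward pass for each unique stimulus of the sequence and returns
#' the firing rates of all recorded cells in long (tidy) form.
#'
#' @param net A `contour_network`.
#' @param sequence A [make_sequence()] sequence describing the test set.
#' @param layers Integer vector of layers to record, or `"top"` (default).
#' @return A tibble with columns `cell`, `layer`, `object_id`, `location`,
#'   `location_x`, `location_y`, `orientation`, `rate`.
#' @export
response_table <- function(net, sequence, layers = "top") {
  stopifnot(inherits(net, "contour_network"),
            inherits(sequence, "presentation_sequence"))
  if (identical(layers, "top")) layers <- length(net$layers)
  layers <- as.integer(layers)
  stopifnot(all(layers >= 1), all(layers <= length(net$layers)))
  keys <- names(sequence$images)
  per_key <- lapply(keys, function(k) {
    fp <- forward_pass(net, sequence$images[[k]])
    lapply(layers, function(l) fp$layers[[l]]$y)
  })
  frames <- sequence$frames
  out <- vector("list", nrow(frames) * length(layers))
  pos <- 0L
  for (f in seq_len(nrow(frames))) {
    ki <- match(frames$key[f], keys)
    for (li in seq_along(layers)) {
      y <- per_key[[ki]][[li]]
      pos <- pos + 1L
      out[[pos]] <- tibble::tibble(
        cell = seq_along(y), layer = layers[li],
        object_id = frames$object_id[f], location = frames$location[f],
        location_x = frames$center_x[f], location_y = frames$center_y[f],
        orientation = frames$orientation[f], rate = y)
    }
  }
  dplyr::bind_rows(out)
}
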
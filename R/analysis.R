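#' Single-cell stimulus-specific information
#'
#' For every cell and every stimulus category `s` (a boundary element: a
#' particular conformation at a particular side), computes
#' \deqn{I(s, R) = \sum_{r \in R} P(r \mid s) \log_2 \frac{P(r \mid s)}{P(r)}}
#' where responses are quantized into `n_bins` equal-width bins on `[0, 1]`,
#' \eqn{P(r \mid s)} is estimated over all presentations of objects that
#' contain element `s` (across every tested location and orientation) and
#' \eqn{P(r)} over all presentations.  In a design with `p` conformations per
#' side, a cell that responds if and only if its preferred element is present
#' attains the maximum of \eqn{\log_2 p} bits.
#'
#' @param responses A [response_table()] tibble (columns `cell`, `object_id`,
#'   `rate`; any transform columns are treated as extra presentations).
#' @param elements An [element_table()] tibble mapping `object_id` to the
#'   categories (`element`) it contains.
#' @param n_bins Number of equal-width response bins on `[0, 1]` (default 10).
#' @return A tibble `cell`, `element`, `info` (bits).  Use
#'   `dplyr::slice_max()` per cell for the per-cell maximum, or
#'   [information_curve()] for the rank-ordered curve.
#' @export
single_cell_information <- function(responses, elements, n_bins = 10) {
  stopifnot(all(c("cell", "object_id", "rate") %in% names(responses)),
            all(c("object_id", "element") %in% names(elements)),
            n_bins >= 2)
  cats <- unique(elements$element)
  missing <- setdiff(unique(responses$object_id), unique(elements$object_id))
  if (length(missing) > 0) {
    stop("objects without element annotation: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  resp <- responses
  resp$bin <- pmin(pmax(ceiling(resp$rate * n_bins), 1L), n_bins)
  cells <- sort(unique(resp$cell))
  # response-bin counts per (cell, object): collapse once, then aggregate
  # per category through the object->element map
  tab_all <- table(factor(resp$cell, cells), factor(resp$bin, seq_len(n_bins)))
  p_all <- tab_all / rowSums(tab_all)
  out <- vector("list", length(cats))
  for (ci in seq_along(cats)) {
    objs <- elements$object_id[elements$element == cats[ci]]
    sub <- resp[resp$object_id %in% objs, ]
    if (nrow(sub) == 0) {
      stop(sprintf("category '%s' has no presentations", cats[ci]),
           call. = FALSE)
    }
    tab_s <- table(factor(sub$cell, cells), factor(sub$bin, seq_len(n_bins)))
    p_s <- tab_s / rowSums(tab_s)
    ratio <- p_s / p_all
    term <- p_s * log2(ifelse(p_s > 0, ratio, 1))
    term[p_s == 0] <- 0
    out[[ci]] <- tibble::tibble(cell = cells, element = cats[ci],
                                info = unname(rowSums(term)))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_bins") <- n_bins
  res
}

#' Rank-ordered single-cell information curve
#'
#' The per-cell maximum information over categories, sorted in decreasing
#' order — the standard way of displaying how many cells attained (close to)
#' the maximal `log2(p)` bits.
#'
#' @param info Output of [single_cell_information()].
#' @return A tibble `rank`, `cell`, `element` (the maximizing category),
#'   `info`.
#' @export
information_curve <- function(info) {
  info |>
    dplyr::group_by(.data$cell) |>
    dplyr::slice_max(.data$info, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$info)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "cell", "element", "info")
}

#' Count cells selective for single boundary elements
#'
#' A cell counts as selective for element `e` iff its firing rate is
#' approximately 1 (`rate >= hi`) for every presentation of every object
#' containing `e` and approximately 0 (`rate < lo`) for every presentation of
#' every object lacking `e`.  Because "every presentation" includes every
#' tested retinal location and orientation, the criterion automatically
#' demands transform invariance in invariance test designs.
#'
#' @param responses A [response_table()] tibble.
#' @param elements An [element_table()] tibble.
#' @param hi Lower bound of the "on" band (default 0.99995).
#' @param lo Upper (exclusive) bound of the "off" band (default 0.00005).
#' @return A tibble `element`, `n_selective`, plus attribute `cells`: a named
#'   list of the selective cell ids per element.
#' @export
count_selective_cells <- function(responses, elements, hi = 0.99995,
                                  lo = 0.00005) {
  stopifnot(all(c("cell", "object_id", "rate") %in% names(responses)))
  cats <- unique(elements$element)
  cells_by_el <- vector("list", length(cats))
  names(cells_by_el) <- cats
  for (e in cats) {
    objs <- elements$object_id[elements$element == e]
    pos <- responses[responses$object_id %in% objs, ]
    neg <- responses[!(responses$object_id %in% objs), ]
    on_ok <- tapply(pos$rate >= hi & pos$rate <= 1, pos$cell, all)
    off_ok <- tapply(neg$rate < lo & neg$rate >= 0, neg$cell, all)
    common <- intersect(names(on_ok), names(off_ok))
    sel <- common[on_ok[common] & off_ok[common]]
    if (length(neg$cell) == 0) sel <- names(on_ok)[on_ok]
    cells_by_el[[e]] <- as.integer(sel)
  }
  out <- tibble::tibble(element = cats,
                        n_selective = unname(lengths(cells_by_el)))
  attr(out, "cells") <- cells_by_el
  out
}

#' Trace a cell's effective receptive field back to the Gabor inputs
#'
#' Effective weight of retinal Gabor filter `f` onto a cell = the sum over
#' all feed-forward paths from `f` to the cell of the product of the path's
#' synaptic weights.  Plotting the strongest effective inputs visualizes
#' what the cell has learned to respond to.
#'
#' @param net A `contour_network`.
#' @param cell Cell id (column-major index into the layer grid).
#' @param layer Layer of the cell (default: top layer).
#' @return A 3-D array `[retina_y, retina_x, kernel]` of effective weights,
#'   with attribute `params` (the bank's kernel parameters).
#' @export
backtrace_receptive_field <- function(net, cell, layer = length(net$layers)) {
  stopifnot(inherits(net, "contour_network"))
  n_top <- prod(net$layers[[layer]]$dims)
  if (cell < 1 || cell > n_top) {
    stop(sprintf("cell id %d out of range 1..%d", cell, n_top), call. = FALSE)
  }
  v <- numeric(n_top)
  v[cell] <- 1
  for (l in rev(seq_len(layer))) {
    map <- net$layers[[l]]$map
    v_pre <- numeric(prod(map$pre_dims))
    act <- which(v != 0)
    for (i in act) {
      j <- map$idx[i, ]
      v_pre[j] <- v_pre[j] + v[i] * map$w[i, ]
    }
    v <- v_pre
  }
  dims <- c(net$config$retina, length(net$bank$kernels))
  structure(array(v, dims), params = net$bank$params,
            class = "receptive_field")
}

# --- boundary segmentation and curvature tuning -----------------------------

#' Segment a closed boundary contour into curvature elements
#'
#' Resamples the contour at uniform arc length, computes the signed local
#' curvature (positive = convex), and cuts the contour where the rate of
#' change of curvature `|dk/ds|` exceeds a fixed threshold.  Each resulting
#' segment is summarized by its mean curvature and the angular position of
#' its midpoint relative to the contour's center of mass (counter-clockwise
#' from "right" = 0 degrees, "top" = 90 degrees).
#'
#' @param contour Two-column matrix of `(x, y)` points (screen coordinates,
#'   y down) tracing a closed contour, e.g. from [shape_contour()] or the
#'   `contour` attribute of a rendered stimulus.
#' @param threshold Cut threshold on `|dk/ds|` in 1/px^2 (default 0.05:
#'   smooth arcs stay whole, polygon corners and conformation junctions cut).
#' @param n_resample Number of uniform arc-length samples (default 360).
#' @param smooth Half-width of the moving-average curvature smoother in
#'   samples (default 2).
#' @return A tibble with one row per segment: `segment`, `curvature` (mean
#'   signed curvature, 1/px), `angle` (degrees in `[0, 360)`), `arc_frac`
#'   (fraction of total arc length).
#' @export
segment_boundary <- function(contour, threshold = 0.05, n_resample = 360,
                             smooth = 2) {
  stopifnot(is.matrix(contour), ncol(contour) == 2)
  if (sqrt(sum((contour[1, ] - contour[nrow(contour), ])^2)) >
      0.05 * sum(sqrt(rowSums(diff(contour)^2)))) {
    stop("contour is not closed", call. = FALSE)
  }
  pts <- resample_contour(contour, n_resample)
  # math coordinates (y up) so counter-clockwise = positive turning
  x <- pts[, 1]; y <- -pts[, 2]
  n <- length(x)
  nxt <- c(2:n, 1)
  dx <- x[nxt] - x; dy <- y[nxt] - y
  ds <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  dtheta <- diff(c(theta, theta[1]))
  dtheta <- (dtheta + pi) %% (2 * pi) - pi
  kappa <- dtheta / ds
  # ensure the contour is traversed counter-clockwise so convex => positive
  if (sum(dtheta) < 0) kappa <- -kappa
  if (smooth > 0) kappa <- circular_ma(kappa, smooth)
  dkds <- abs(diff(c(kappa, kappa[1]))) / ds
  cuts <- which(dkds > threshold)
  cx <- mean(x); cy <- mean(y)
  ang <- (atan2(y - cy, x - cx) * 180 / pi) %% 360
  if (length(cuts) == 0) {
    return(tibble::tibble(segment = 1L,
                          curvature = mean(kappa),
                          angle = (atan2(mean(sin(ang * pi / 180)),
                                         mean(cos(ang * pi / 180))) *
                                   180 / pi) %% 360,
                          arc_frac = 1))
  }
  # group cut samples into junction clusters; a sharp corner produces two
  # |dk/ds| lobes (rise and fall of the curvature bump) that must merge
  gap <- 2L * smooth + 2L
  bounds <- sort(unique(cuts))
  lab <- cumsum(c(TRUE, diff(bounds) > gap))
  cl_start <- tapply(bounds, lab, min)
  cl_end <- tapply(bounds, lab, max)
  # wrap-merge first/last clusters if they touch across the seam
  if (length(cl_start) > 1 && (n - max(cl_end)) + min(cl_start) <= gap) {
    cl_start[1] <- cl_start[length(cl_start)] - n
    cl_start <- cl_start[-length(cl_start)]
    cl_end <- cl_end[-length(cl_end)]
  }
  k <- length(cl_start)
  trim <- smooth + 1L
  segs <- vector("list", k)
  for (si in seq_len(k)) {
    a <- cl_end[si] + 1L + trim
    b <- (if (si == k) cl_start[1] + n else cl_start[si + 1]) - 1L - trim
    if (b < a) { a <- cl_end[si] + 1L; b <- a }
    ii <- (((a:b) - 1) %% n) + 1
    mid <- ii[ceiling(length(ii) / 2)]
    segs[[si]] <- tibble::tibble(segment = si,
                                 curvature = mean(kappa[ii]),
                                 angle = ang[mid],
                                 arc_frac = length(ii) / n)
  }
  dplyr::bind_rows(segs)
}

circular_ma <- function(v, half) {
  n <- length(v)
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(v[idx], n))
}

#' Boundary segments for every object and orientation of a test set
#'
#' Computes [segment_boundary()] once per object at orientation 0 and rotates
#' the segment angular positions for the remaining orientations (rotation
#' moves a boundary element around the object's center without changing its
#' curvature).
#'
#' @param shapes Shape table with `object_id` and `shape` columns.
#' @param orientations Orientations in degrees.
#' @param radius Circumradius used for the contour (should match rendering).
#' @param ... Passed to [segment_boundary()].
#' @return A tibble `object_id`, `orientation`, `segment`, `curvature`,
#'   `angle`, `arc_frac`.
#' @export
segment_table <- function(shapes, orientations = 0, radius = 40, ...) {
  base <- purrr::map2_dfr(shapes$object_id, shapes$shape, function(id, sp) {
    segs <- segment_boundary(shape_contour(sp, radius = radius), ...)
    segs$object_id <- id
    segs
  })
  purrr::map_dfr(orientations, function(o) {
    out <- base
    out$orientation <- o
    out$angle <- (out$angle + o) %% 360
    out
  })
}

#' Curvature-by-angular-position tuning heatmap of one cell
#'
#' Bins the (curvature, angular position) boundary elements of every
#' presented stimulus and averages the cell's response over all presentations
#' whose boundary contains an element in each bin — averaged over all
#' orientations (and, unless split, all locations) of all objects.
#'
#' @param responses [response_table()] rows for a single cell (or pass
#'   `cell` to filter).
#' @param segments A [segment_table()] for the same test set.
#' @param cell Optional cell id filter.
#' @param curvature_bins,angle_bins Bin counts (defaults 8 and 16; angle bins
#'   cover 0-360 degrees circularly).
#' @param curvature_range Numeric range clamped for binning; default the
#'   symmetric range of observed segment curvatures.
#' @return A `tuning_heatmap`: tibble `curv_bin`, `angle_bin`, `curvature`,
#'   `angle` (bin centers), `rate` (mean; `NA` for empty bins), `n`
#'   (presentations per bin), with bin metadata in attributes.
#' @export
tuning_heatmap <- function(responses, segments, cell = NULL,
                           curvature_bins = 8, angle_bins = 16,
                           curvature_range = NULL) {
  if (!is.null(cell)) responses <- responses[responses$cell == cell, ]
  stopifnot(nrow(responses) > 0)
  if (is.null(curvature_range)) {
    m <- max(abs(segments$curvature))
    curvature_range <- c(-m, m)
  }
  cb <- seq(curvature_range[1], curvature_range[2],
            length.out = curvature_bins + 1)
  ab <- seq(0, 360, length.out = angle_bins + 1)
  seg <- segments
  seg$curv_bin <- pmin(pmax(findInterval(seg$curvature, cb,
                                         rightmost.closed = TRUE), 1L),
                       curvature_bins)
  seg$angle_bin <- pmin(findInterval(seg$angle %% 360, ab), angle_bins)
  joined <- dplyr::inner_join(
    responses, seg, by = intersect(c("object_id", "orientation"),
                                   intersect(names(responses), names(seg))))
  agg <- joined |>
    dplyr::group_by(.data$curv_bin, .data$angle_bin) |>
    dplyr::summarise(rate = mean(.data$rate), n = dplyr::n(),
                     .groups = "drop")
  full <- tidyr::expand_grid(curv_bin = seq_len(curvature_bins),
                             angle_bin = seq_len(angle_bins))
  out <- dplyr::left_join(full, agg, by = c("curv_bin", "angle_bin"))
  out$n[is.na(out$n)] <- 0L
  out$curvature <- (cb[out$curv_bin] + cb[out$curv_bin + 1]) / 2
  out$angle <- (ab[out$angle_bin] + ab[out$angle_bin + 1]) / 2
  out <- out[, c("curv_bin", "angle_bin", "curvature", "angle", "rate", "n")]
  structure(out, curvature_breaks = cb, angle_breaks = ab,
            class = c("tuning_heatmap", class(out)))
}

heatmap_matrix <- function(hm) {
  cb <- attr(hm, "curvature_breaks"); ab <- attr(hm, "angle_breaks")
  m <- matrix(NA_real_, length(cb) - 1, length(ab) - 1)
  m[cbind(hm$curv_bin, hm$angle_bin)] <- hm$rate
  m
}

#' Count local peaks of a tuning heatmap
#'
#' A peak is a bin whose value is at least as large as all of its
#' 8-neighbors (the angle axis wraps circularly, the curvature axis does
#' not), strictly larger than at least one of them, and greater than
#' `fraction` times the mean rate across the heatmap.  A plateau of equal
#' maxima counts once.  Empty bins are ignored.
#'
#' @param hm A [tuning_heatmap()] (or a plain matrix, rows = curvature,
#'   columns = angle).
#' @param fraction Threshold as a fraction of the heatmap mean (default 0.6).
#' @return Integer number of peaks.
#' @export
count_heatmap_peaks <- function(hm, fraction = 0.6) {
  m <- if (inherits(hm, "tuning_heatmap")) heatmap_matrix(hm) else hm
  stopifnot(is.matrix(m), length(m) > 0)
  nr <- nrow(m); nc <- ncol(m)
  thr <- fraction * mean(m, na.rm = TRUE)
  is_cand <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- m[i, j]
      if (is.na(v) || v <= thr) next
      ge_all <- TRUE; gt_any <- FALSE
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di
        jj <- ((j + dj - 1) %% nc) + 1
        if (ii < 1 || ii > nr) next
        nb <- m[ii, jj]
        if (is.na(nb)) next
        if (v < nb) ge_all <- FALSE
        if (v > nb) gt_any <- TRUE
      }
      is_cand[i, j] <- ge_all && gt_any
    }
  }
  if (!any(is_cand)) return(0L)
  # merge plateau candidates: connected equal-valued candidates count once
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is_cand[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- ((p[2] + dj - 1) %% nc) + 1
        if (ii < 1 || ii > nr) next
        if (is_cand[ii, jj] && lab[ii, jj] == 0L &&
            isTRUE(m[ii, jj] == m[p[1], p[2]])) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  cur
}

#' Correlate a tuning heatmap with a Gaussian model neuron
#'
#' Builds the predicted tuning surface of an idealized neuron with Gaussian
#' tuning centered on a preferred curvature and a preferred angular position
#' (wrapped on the circle), then computes the Pearson correlation with the
#' observed heatmap over its non-empty bins.
#'
#' @param hm A [tuning_heatmap()].
#' @param preferred_curvature Preferred curvature (1/px).
#' @param preferred_angle Preferred angular position in degrees.
#' @param widths `c(curvature_sd, angle_sd_degrees)` tuning widths.
#' @return Pearson correlation coefficient.
#' @export
v4_model_correlation <- function(hm, preferred_curvature, preferred_angle,
                                 widths = c(0.05, 45)) {
  stopifnot(inherits(hm, "tuning_heatmap"))
  ok <- !is.na(hm$rate)
  if (!any(ok)) stop("heatmap has no non-empty bins", call. = FALSE)
  obs <- hm$rate[ok]
  if (stats::sd(obs) == 0) {
    stop("heatmap has zero variance over non-empty bins: correlation undefined",
         call. = FALSE)
  }
  dang <- (hm$angle[ok] - preferred_angle + 180) %% 360 - 180
  dcur <- hm$curvature[ok] - preferred_curvature
  model <- exp(-(dcur^2 / (2 * widths[1]^2) + dang^2 / (2 * widths[2]^2)))
  stats::cor(obs, model)
}

#' Spatial map of maximally informative cells per element
#'
#' For each boundary element, locates the cells whose single-cell information
#' is at the element-wise maximum (within tolerance), reports their grid
#' coordinates, and scores their spatial clustering as the mean pairwise grid
#' distance compared with a permutation null (random cell subsets of the same
#' size).  Lower `clustering_z` means more spatially clustered, the signature
#' of topographic (SOM) organization.
#'
#' @param info Output of [single_cell_information()].
#' @param dims Layer grid `c(rows, cols)` (cells are column-major ids).
#' @param tol Cells within `tol` of the element maximum count (default 1e-6).
#' @param n_perm Permutation draws for the null (default 200).
#' @param seed Seed for the permutation null.
#' @return A tibble `element`, `n_cells`, `mean_dist`, `null_mean`,
#'   `clustering_z`, plus attribute `cells` (named list of grid coordinate
#'   matrices).
#' @export
feature_map <- function(info, dims, tol = 1e-6, n_perm = 200, seed = 1) {
  stopifnot(all(c("cell", "element", "info") %in% names(info)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_cells_total <- max(info$cell)
  coords_all <- cbind(((seq_len(n_cells_total) - 1) %% dims[1]) + 1,
                      ((seq_len(n_cells_total) - 1) %/% dims[1]) + 1)
  cats <- unique(info$element)
  cell_sets <- list()
  rows <- vector("list", length(cats))
  for (ci in seq_along(cats)) {
    sub <- info[info$element == cats[ci], ]
    mx <- max(sub$info)
    sel <- sub$cell[sub$info >= mx - tol]
    cell_sets[[cats[ci]]] <- coords_all[sel, , drop = FALSE]
    if (length(sel) < 2 || mx <= tol) {
      rows[[ci]] <- tibble::tibble(element = cats[ci], n_cells = length(sel),
                                   mean_dist = NA_real_, null_mean = NA_real_,
                                   clustering_z = NA_real_)
      next
    }
    md <- mean(stats::dist(coords_all[sel, , drop = FALSE]))
    null <- replicate(n_perm, {
      rs <- sample.int(n_cells_total, length(sel))
      mean(stats::dist(coords_all[rs, , drop = FALSE]))
    })
    rows[[ci]] <- tibble::tibble(
      element = cats[ci], n_cells = length(sel), mean_dist = md,
      null_mean = mean(null),
      clustering_z = (md - mean(null)) / max(stats::sd(null), 1e-12))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "cells") <- cell_sets
  out
}
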
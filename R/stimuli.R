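#' Define a family of polygonal boundary-element shapes
#'
#' A shape family fixes the number of sides `n` and the number of possible
#' boundary conformations per side `p`.  Every whole object in the family is
#' one of the `p^n` combinations of conformations over the `n` sides, and the
#' family exposes `n * p` distinct localized boundary elements (side x
#' conformation).  Sides are indexed counter-clockwise starting from the side
#' whose midpoint sits at the top of the shape (90 degrees, measured
#' counter-clockwise from "right").
#'
#' Each conformation is drawn as a circular arc whose sagitta (arc height at
#' the chord midpoint) is a signed fraction of the chord length: negative for
#' concave (bulging towards the shape center), zero for straight, positive for
#' convex.  By default the `p` sagitta ratios are evenly spaced on
#' `[-max_sagitta, max_sagitta]`, which for `p = 3` gives the classic
#' concave / straight / convex triple and for `p = 2` gives concave / convex.
#'
#' @param n_sides Number of sides `n` (>= 3).
#' @param n_conformations Number of conformations per side `p` (>= 1).
#' @param labels Optional character vector of conformation labels, ordered
#'   from most concave to most convex.  Sensible defaults are supplied for
#'   `p <= 5`.
#' @param sagitta Optional numeric vector of signed sagitta-to-chord ratios,
#'   one per conformation.  Defaults to `max_sagitta * seq(-1, 1, length.out =
#'   n_conformations)` (for `p = 1` a single straight side).
#' @param max_sagitta Largest |sagitta|/chord ratio used by the default
#'   spacing (default 0.25).
#' @return An object of class `shape_family`.
#' @examples
#' fam <- shape_family(4, 3)
#' fam$p^fam$n          # 81 whole objects
#' fam$n * fam$p        # 12 boundary elements
#' @export
shape_family <- function(n_sides, n_conformations, labels = NULL,
                         sagitta = NULL, max_sagitta = 0.25) {
  stopifnot(n_sides >= 3, n_conformations >= 1)
  p <- as.integer(n_conformations)
  if (is.null(sagitta)) {
    sagitta <- if (p == 1) 0 else max_sagitta * seq(-1, 1, length.out = p)
  }
  stopifnot(length(sagitta) == p)
  if (is.null(labels)) labels <- default_conformation_labels(p)
  stopifnot(length(labels) == p, !anyDuplicated(labels))
  structure(
    list(n = as.integer(n_sides), p = p, labels = labels,
         sagitta = as.numeric(sagitta)),
    class = "shape_family"
  )
}

default_conformation_labels <- function(p) {
  switch(as.character(p),
    "1" = "straight",
    "2" = c("concave", "convex"),
    "3" = c("concave", "straight", "convex"),
    "4" = c("sharp-concave", "concave", "convex", "sharp-convex"),
    "5" = c("sharp-concave", "concave", "straight", "convex", "sharp-convex"),
    paste0("conf", seq_len(p))
  )
}

#' @export
print.shape_family <- function(x, ...) {
  cat(sprintf("<shape_family> n = %d sides, p = %d conformations (%s); %d objects, %d elements\n",
              x$n, x$p, paste(x$labels, collapse = ", "),
              x$p^x$n, x$n * x$p))
  invisible(x)
}

#' Side labels of a shape family
#'
#' Human-readable side names by the angular position of the side midpoint
#' (counter-clockwise from "right" = 0 degrees, "top" = 90 degrees).
#' @param family A [shape_family()].
#' @return Character vector of length `n`.
#' @export
side_labels <- function(family) {
  ang <- round(side_midpoint_angles(family$n)) %% 360
  sprintf("side%02d_%03d", seq_len(family$n) - 1L, ang)
}

side_midpoint_angles <- function(n) 90 + 360 * (seq_len(n) - 1) / n

#' Enumerate all whole objects of a shape family
#'
#' Produces the full combinatorial set of `p^n` objects, one per assignment of
#' a conformation to every side, in deterministic lexicographic order (the
#' first side varies slowest).
#'
#' @param family A [shape_family()].
#' @param max_shapes Refuse enumeration when `p^n` exceeds this cap
#'   (default 1000, matching the practical limit used in the simulations).
#' @return A tibble with columns `object_id`, `elements` (list column of
#'   per-side conformation labels) and `shape` (list column of `shape_spec`
#'   objects ready for [render_shape()]).
#' @examples
#' nrow(enumerate_shapes(shape_family(3, 2)))  # 8
#' @export
enumerate_shapes <- function(family, max_shapes = 1000) {
  stopifnot(inherits(family, "shape_family"))
  n_obj <- family$p^family$n
  if (n_obj > max_shapes) {
    stop(sprintf("family has p^n = %d objects, above the cap of %d",
                 n_obj, max_shapes), call. = FALSE)
  }
  grids <- rev(rep(list(seq_len(family$p)), family$n))
  combos <- rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  combos <- as.matrix(combos)[, seq_len(family$n), drop = FALSE]
  elements <- lapply(seq_len(nrow(combos)),
                     function(i) family$labels[combos[i, ]])
  tibble::tibble(
    object_id = vapply(elements, paste, "", collapse = "|"),
    elements = elements,
    shape = lapply(elements, function(e) shape_spec(family, e))
  )
}

#' Construct a single shape specification
#'
#' @param family A [shape_family()].
#' @param elements Character vector of conformation labels, one per side.
#' @param vertex_angles Optional vector of vertex angular separations in
#'   degrees (must sum to 360); default places vertices evenly.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(family, elements, vertex_angles = NULL) {
  stopifnot(inherits(family, "shape_family"),
            length(elements) == family$n,
            all(elements %in% family$labels))
  if (!is.null(vertex_angles)) {
    stopifnot(length(vertex_angles) == family$n)
    if (abs(sum(vertex_angles) - 360) > 1e-8) {
      stop("vertex_angles must sum to 360 degrees", call. = FALSE)
    }
  }
  structure(list(family = family, elements = as.character(elements),
                 vertex_angles = vertex_angles),
            class = "shape_spec")
}

#' Long table of boundary elements per object
#'
#' Expands a shape table (from [enumerate_shapes()] or [pasupathy_shapes()])
#' into one row per (object, side, conformation) boundary element, the
#' categorical structure used by the information and selectivity analyses.
#'
#' @param shapes A tibble with `object_id` and `elements` columns.
#' @return A tibble with columns `object_id`, `side`, `conformation` and
#'   `element` (`"side:conformation"`).
#' @export
element_table <- function(shapes) {
  stopifnot(all(c("object_id", "elements") %in% names(shapes)))
  purrr::map2_dfr(shapes$object_id, shapes$elements, function(id, el) {
    tibble::tibble(object_id = id, side = seq_along(el) - 1L,
                   conformation = el,
                   element = paste0("s", seq_along(el) - 1L, ":", el))
  })
}

# --- geometry ---------------------------------------------------------------

# Vertex positions (screen coordinates: x right, y down, angles measured
# counter-clockwise from "right" so that "top" = 90 degrees).
shape_vertices <- function(spec, radius, center, orientation = 0) {
  n <- spec$family$n
  if (is.null(spec$vertex_angles)) {
    # side j (1-based) runs from vertex j to j+1; this placement puts the
    # midpoint of side j at 90 + 360*(j-1)/n degrees (side 1 = top)
    ang <- 90 + 360 * (seq_len(n) - 1.5) / n
  } else {
    ang <- 90 + cumsum(c(0, spec$vertex_angles[-n]))
  }
  ang <- (ang + orientation) * pi / 180
  cbind(x = center[1] + radius * cos(ang),
        y = center[2] - radius * sin(ang))
}

# Circular-arc side from p0 to p1 with sagitta h (signed: positive bulges
# along `outward`, the unit normal pointing away from the shape center).
arc_points <- function(p0, p1, h, outward, n_pts) {
  t <- seq(0, 1, length.out = n_pts)
  base <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  if (abs(h) < 1e-12) return(base)
  chord <- sqrt(sum((p1 - p0)^2))
  rc <- (chord^2 / 4 + h^2) / (2 * abs(h))
  # circular profile: perpendicular offset at parameter t along the chord
  off <- sqrt(pmax(rc^2 - (chord * (t - 0.5))^2, 0)) - (rc - abs(h))
  base + sign(h) * outer(off, outward)
}

#' Analytic closed contour of a shape
#'
#' Traces the closed outline of a shape as a dense polyline, with each side
#' drawn as a circular arc whose signed sagitta is `sagitta_ratio * chord`
#' (negative concave, positive convex, relative to the shape center).
#'
#' @param spec A [shape_spec()].
#' @param radius Circumradius of the vertex circle in pixels.
#' @param center Numeric `(x, y)` center in pixel coordinates (x right,
#'   y down, 0-based).
#' @param orientation Rotation in degrees, positive counter-clockwise.
#' @param points_per_side Sampling density of the returned polyline.
#' @return A two-column matrix of `(x, y)` points; the contour is closed
#'   (first point repeated at the end).
#' @export
shape_contour <- function(spec, radius = 40, center = c(0, 0),
                          orientation = 0, points_per_side = 120) {
  stopifnot(inherits(spec, "shape_spec"))
  fam <- spec$family
  v <- shape_vertices(spec, radius, center, orientation)
  n <- fam$n
  pts <- vector("list", n)
  for (j in seq_len(n)) {
    p0 <- v[j, ]
    p1 <- v[if (j == n) 1L else j + 1L, ]
    mid <- (p0 + p1) / 2
    outward <- mid - center
    nrm <- sqrt(sum(outward^2))
    # for degenerate mid == center fall back to the chord normal
    if (nrm < 1e-9) {
      d <- p1 - p0
      outward <- c(d[2], -d[1])
      nrm <- sqrt(sum(outward^2))
    }
    outward <- outward / nrm
    h <- fam$sagitta[match(spec$elements[j], fam$labels)] *
      sqrt(sum((p1 - p0)^2))
    seg <- arc_points(p0, p1, h, outward, points_per_side)
    pts[[j]] <- seg[-nrow(seg), , drop = FALSE]
  }
  out <- do.call(rbind, pts)
  rbind(out, out[1, , drop = FALSE])
}

# Resample a closed polyline to N points at uniform arc length.
resample_contour <- function(pts, n_out) {
  if (!all(pts[1, ] == pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  si <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  x <- stats::approx(s, pts[, 1], xout = si)$y
  y <- stats::approx(s, pts[, 2], xout = si)$y
  cbind(x = x, y = y)
}

# --- rasterization ----------------------------------------------------------

stroke_offsets <- function(stroke) {
  r <- max(stroke / 2, 0.5)
  g <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, , drop = FALSE]
}

rasterize_outline <- function(pts, retina, stroke = 2) {
  h <- retina[1]; w <- retina[2]
  # densify so the stroke has no gaps
  pts <- resample_contour(pts, max(4L * nrow(pts), 512L))
  px <- round(pts[, 1]); py <- round(pts[, 2])
  off <- stroke_offsets(stroke)
  xs <- rep(px, each = nrow(off)) + off$dx
  ys <- rep(py, each = nrow(off)) + off$dy
  if (any(xs < 0 | xs >= w | ys < 0 | ys >= h)) {
    stop(sprintf("shape exceeds retina bounds (%dx%d): x in [%d, %d], y in [%d, %d]",
                 w, h, min(xs), max(xs), min(ys), max(ys)), call. = FALSE)
  }
  img <- matrix(0, h, w)
  img[cbind(ys + 1L, xs + 1L)] <- 1
  img
}

# Even-odd scanline polygon fill.
rasterize_filled <- function(pts, retina) {
  h <- retina[1]; w <- retina[2]
  if (any(pts[, 1] < 0 | pts[, 1] >= w | pts[, 2] < 0 | pts[, 2] >= h)) {
    stop(sprintf("shape exceeds retina bounds (%dx%d)", w, h), call. = FALSE)
  }
  img <- matrix(0, h, w)
  if (any(pts[1, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
  n <- nrow(pts)
  x0 <- pts[-n, 1]; y0 <- pts[-n, 2]
  x1 <- pts[-1, 1]; y1 <- pts[-1, 2]
  keep <- y0 != y1
  x0 <- x0[keep]; y0 <- y0[keep]; x1 <- x1[keep]; y1 <- y1[keep]
  for (row in floor(min(c(y0, y1))):ceiling(max(c(y0, y1)))) {
    yc <- row
    hit <- (y0 <= yc & y1 > yc) | (y1 <= yc & y0 > yc)
    if (!any(hit)) next
    xc <- x0[hit] + (yc - y0[hit]) / (y1[hit] - y0[hit]) * (x1[hit] - x0[hit])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      a <- ceiling(xc[k]); b <- floor(xc[k + 1])
      if (b >= a) img[row + 1L, (a:b) + 1L] <- 1
    }
  }
  img
}

#' Render a shape onto a simulated retina
#'
#' Draws the closed outline (or filled silhouette) of a shape as a white
#' figure on a black background, the polarity the phase-0 Gabor filters are
#' tuned to.  Rendering is deterministic (no anti-aliasing), so integer
#' translations of `center` shift every foreground pixel exactly.
#'
#' @param spec A [shape_spec()].
#' @param retina Retina size in pixels, scalar or `(rows, cols)`.
#' @param center `(x, y)` placement in 0-based pixel coordinates; default is
#'   the retina center.
#' @param orientation Rotation in degrees (counter-clockwise positive).
#' @param mirror If `TRUE`, reflect the contour about the vertical axis
#'   `x = mirror_axis` before rasterizing.
#' @param mirror_axis x-position of the reflection axis; default is the
#'   vertical midline of the retina.
#' @param radius Circumradius in pixels; default scales with the retina
#'   (30% of the smaller dimension).
#' @param stroke Outline stroke width in pixels (default 2).
#' @param fill If `TRUE`, render a filled silhouette instead of an outline.
#' @return A `rendered_stimulus`: the image matrix (values 0/1, rows = y)
#'   with attributes `center`, `orientation`, `mirror` and `contour`.
#' @export
render_shape <- function(spec, retina = 64, center = NULL, orientation = 0,
                         mirror = FALSE, mirror_axis = NULL, radius = NULL,
                         stroke = 2, fill = FALSE) {
  retina <- as_retina(retina)
  if (is.null(center)) center <- (rev(retina) - 1) / 2
  if (is.null(radius)) radius <- 0.3 * min(retina)
  pts <- shape_contour(spec, radius = radius, center = center,
                       orientation = orientation)
  if (isTRUE(mirror)) {
    if (is.null(mirror_axis)) mirror_axis <- (retina[2] - 1) / 2
    pts[, 1] <- 2 * mirror_axis - pts[, 1]
  }
  img <- if (fill) rasterize_filled(resample_contour(pts, 1024), retina)
         else rasterize_outline(pts, retina, stroke)
  structure(img, center = center, orientation = orientation,
            mirror = mirror, contour = pts, class = "rendered_stimulus")
}

as_retina <- function(retina) {
  if (length(retina) == 1) retina <- c(retina, retina)
  as.integer(retina)
}

#' @export
print.rendered_stimulus <- function(x, ...) {
  cat(sprintf("<rendered_stimulus> %dx%d, %d foreground px, center (%.1f, %.1f), %.0f deg\n",
              nrow(x), ncol(x), sum(x > 0),
              attr(x, "center")[1], attr(x, "center")[2],
              attr(x, "orientation")))
  invisible(x)
}

# --- Pasupathy-and-Connor-style curvature stimuli ---------------------------

#' Closed curvature shapes in the style of Pasupathy and Connor
#'
#' Enumerates closed shapes built by combining five boundary-element types
#' (sharp convex, medium convex, broad convex, medium concave, broad concave)
#' between vertices placed at the given angular separations, the stimulus
#' construction used in single-unit studies of V4 boundary conformation
#' coding.
#'
#' @param vertex_angle_sets List of numeric vectors of vertex angular
#'   separations in degrees; each must sum to 360.  Default is the
#'   `135/135/90` set together with `180/90/90` and the even `120/120/120`.
#' @param sagitta Named numeric vector mapping the five element labels to
#'   signed sagitta-to-chord ratios.
#' @return A tibble with `object_id`, `angle_set`, `elements` and `shape`
#'   columns, as [enumerate_shapes()].
#' @export
pasupathy_shapes <- function(vertex_angle_sets = list(c(135, 135, 90),
                                                      c(180, 90, 90),
                                                      c(120, 120, 120)),
                             sagitta = c("sharp-convex" = 0.45,
                                         "medium-convex" = 0.30,
                                         "broad-convex" = 0.15,
                                         "medium-concave" = -0.30,
                                         "broad-concave" = -0.15)) {
  stopifnot(is.list(vertex_angle_sets), length(sagitta) == 5)
  out <- purrr::map_dfr(vertex_angle_sets, function(angles) {
    if (abs(sum(angles) - 360) > 1e-8) {
      stop(sprintf("vertex angle set (%s) does not sum to 360 degrees",
                   paste(angles, collapse = ", ")), call. = FALSE)
    }
    m <- length(angles)
    fam <- shape_family(max(m, 3), 5, labels = names(sagitta),
                        sagitta = unname(sagitta))
    fam$n <- as.integer(m)  # allow m-vertex shapes (m >= 3 in practice)
    combos <- rev(expand.grid(rev(rep(list(seq_len(5)), m)),
                              KEEP.OUT.ATTRS = FALSE))
    combos <- as.matrix(combos)[, seq_len(m), drop = FALSE]
    elements <- lapply(seq_len(nrow(combos)), function(i) fam$labels[combos[i, ]])
    set_id <- paste(angles, collapse = "/")
    tibble::tibble(
      object_id = paste0(set_id, "#",
                         vapply(elements, paste, "", collapse = "|")),
      angle_set = set_id,
      elements = elements,
      shape = lapply(elements, function(e) shape_spec(fam, e, vertex_angles = angles))
    )
  })
  out
}

# --- synthetic smooth blob objects ------------------------------------------

#' Generate smooth synthetic blob objects
#'
#' Random closed shapes with a smooth boundary, built from low-order Fourier
#' descriptors of the radius function \eqn{r(\phi) = r_0 (1 + \sum_k a_k
#' \cos(k\phi + \phi_k))} with amplitudes decaying as \eqn{1/k^2}.  These are
#' synthetic stand-ins for photographs of real objects: they share the smooth,
#' varied boundary-curvature statistics that drive boundary-element learning
#' but none of the internal texture or shading of real images.
#'
#' @param count Number of objects (>= 1).
#' @param retina Retina size in pixels.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param smoothness Overall amplitude of the radius modulation (default 0.25);
#'   smaller values give rounder blobs.
#' @param n_harmonics Highest Fourier order used (default 6).
#' @param fill Render filled silhouettes (default `TRUE`).
#' @return A list of `count` `rendered_stimulus` objects.
#' @export
blob_stimuli <- function(count, retina = 64, seed = 1, smoothness = 0.25,
                         n_harmonics = 6, fill = TRUE) {
  stopifnot(count >= 1)
  retina <- as_retina(retina)
  center <- (rev(retina) - 1) / 2
  r0 <- 0.28 * min(retina)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(count), function(i) {
    k <- 2:n_harmonics
    amp <- stats::runif(length(k), 0, smoothness) / (k / 2)^2
    ph <- stats::runif(length(k), 0, 2 * pi)
    phi <- seq(0, 2 * pi, length.out = 721)[-721]
    rr <- r0 * (1 + colSums(amp * cos(outer(k, phi) + ph)))
    rr <- pmax(rr, 0.2 * r0)
    pts <- cbind(center[1] + rr * cos(phi), center[2] - rr * sin(phi))
    pts <- rbind(pts, pts[1, , drop = FALSE])
    img <- if (fill) rasterize_filled(pts, retina)
           else rasterize_outline(pts, retina, 2)
    structure(img, center = center, orientation = 0, mirror = FALSE,
              contour = pts, object_id = paste0("blob", i),
              class = "rendered_stimulus")
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- presentation sequences -------------------------------------------------

#' Build a temporally ordered presentation sequence
#'
#' Constructs the training schedule the trace rule depends on: for each
#' object, each orientation in turn, the object is swept through every
#' location of a retinal grid (fixed raster order) before the orientation
#' changes, and all of one object's transforms appear before the next object.
#' `boundary` is `TRUE` exactly at the first frame of each object, where the
#' post-synaptic memory trace must be reset so that temporal binding never
#' spans two different objects.
#'
#' @param shapes A shape table ([enumerate_shapes()] / [pasupathy_shapes()])
#'   or a list of `rendered_stimulus` objects (e.g. from [blob_stimuli()]).
#' @param retina Retina size in pixels.
#' @param grid `(rows, cols)` of retinal locations (e.g. `c(2, 2)`).
#' @param spacing Horizontal/vertical shift between neighboring grid
#'   locations, in pixels (default 10).
#' @param orientations Vector of orientations in degrees (default 0).
#' @param ... Further arguments passed to [render_shape()] (e.g. `radius`,
#'   `stroke`, `fill`).
#' @return A `presentation_sequence`: list with `frames` (a tibble with
#'   columns `frame`, `object_id`, `orientation`, `center_x`, `center_y`,
#'   `location`, `boundary`, `key`) and `images` (named list of unique
#'   rendered image matrices keyed by `key`).
#' @export
make_sequence <- function(shapes, retina = 64, grid = c(1, 1), spacing = 10,
                          orientations = 0, ...) {
  retina <- as_retina(retina)
  base <- (rev(retina) - 1) / 2
  offs_y <- spacing * (seq_len(grid[1]) - 1) - round(spacing * (grid[1] - 1) / 2)
  offs_x <- spacing * (seq_len(grid[2]) - 1) - round(spacing * (grid[2] - 1) / 2)
  locs <- expand.grid(dy = offs_y, dx = offs_x, KEEP.OUT.ATTRS = FALSE)
  locs <- locs[order(locs$dy, locs$dx), , drop = FALSE]
  from_images <- !inherits(shapes, "data.frame")
  if (from_images) {
    ids <- vapply(seq_along(shapes), function(i) {
      id <- attr(shapes[[i]], "object_id")
      if (is.null(id)) paste0("obj", i) else id
    }, "")
    src <- shapes
  } else {
    ids <- shapes$object_id
    src <- shapes$shape
  }
  frames <- tidyr::expand_grid(
    object_id = ids,
    orientation = orientations,
    location = seq_len(nrow(locs))
  )
  frames$center_x <- base[1] + locs$dx[frames$location]
  frames$center_y <- base[2] + locs$dy[frames$location]
  frames$boundary <- !duplicated(frames$object_id)
  frames$key <- paste0(frames$object_id, "@", frames$orientation, "@",
                       frames$center_x, ",", frames$center_y)
  frames$frame <- seq_len(nrow(frames))
  frames <- frames[, c("frame", "object_id", "orientation", "center_x",
                       "center_y", "location", "boundary", "key")]
  uniq <- !duplicated(frames$key)
  images <- vector("list", sum(uniq))
  names(images) <- frames$key[uniq]
  for (i in which(uniq)) {
    obj <- src[[match(frames$object_id[i], ids)]]
    img <- if (from_images) {
      shift_image(obj, round(frames$center_x[i] - attr(obj, "center")[1]),
                  round(frames$center_y[i] - attr(obj, "center")[2]))
    } else {
      render_shape(obj, retina = retina,
                   center = c(frames$center_x[i], frames$center_y[i]),
                   orientation = frames$orientation[i], ...)
    }
    images[[frames$key[i]]] <- unclass_image(img)
  }
  structure(list(frames = tibble::as_tibble(frames), images = images,
                 retina = retina),
            class = "presentation_sequence")
}

unclass_image <- function(img) {
  attributes(img) <- list(dim = dim(img))
  img
}

# integer shift with zero padding (for pre-rendered stimuli)
shift_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' @export
print.presentation_sequence <- function(x, ...) {
  cat(sprintf("<presentation_sequence> %d frames, %d unique images, retina %dx%d\n",
              nrow(x$frames), length(x$images), x$retina[1], x$retina[2]))
  invisible(x)
}
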
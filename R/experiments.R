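#' Capacity threshold of a competitive output layer
#'
#' With `n` trained items presented in pairs, the number of possible pairs
#' \eqn{\binom{n}{2} = n(n-1)/2} outgrows the number of output neurons much
#' faster than `n` itself.  This returns the largest `n` for which all pairs
#' can still be represented by dedicated output neurons, i.e. the largest `n`
#' with \eqn{n(n-1)/2 \le} `n_outputs`.  Beyond it, individual output neurons
#' are forced to switch from coding conjunctions to coding individual items —
#' the combinatorial pressure that drives boundary-element coding.
#'
#' @param n_outputs Number of output neurons (e.g. `64 * 64 = 4096`).
#' @return Integer threshold `n`.
#' @examples
#' capacity_threshold(4096)  # 91
#' @export
capacity_threshold <- function(n_outputs) {
  stopifnot(n_outputs >= 1)
  as.integer(floor((1 + sqrt(1 + 8 * n_outputs)) / 2 + 1e-9))
}

#' Configure a simulation study
#'
#' Bundles the stimulus family, presentation schedule, network preset and
#' learning specification for [run_study()].
#'
#' @param study Study id, one of `"study1"`, `"study1_sweep"`,
#'   `"study1_trace"`, `"study2"`, `"study2_trace"`, `"study3_like"`,
#'   `"mirror_test"`, `"capacity"`.
#' @param n_sides,n_conformations Shape family parameters (Study-1 designs).
#' @param preset Network preset name (see [network_preset()]).
#' @param rule Learning rule, `"hebb"` or `"trace"`.
#' @param grid Retinal location grid `c(rows, cols)` (default single
#'   location).
#' @param spacing Grid spacing in pixels (default 10).
#' @param orientations Orientations in degrees (default 0).
#' @param rate,eta,epochs Learning parameters.  `rate = NULL` resolves to
#'   0.1 for the Hebb rule and 0.5 for the trace rule: the trace update is
#'   driven by the decayed memory trace (at most `1 - eta` of the rate on
#'   the first shifted frame), so transform binding needs a larger constant
#'   to outweigh the initial random-weight advantage of transform-specific
#'   winners.
#' @param seed Master seed.
#' @param record_layers Layers to record at test time (default `"top"`).
#' @param n_blobs Number of blob objects for `study3_like` (default 40).
#' @param max_shapes Enumeration cap on `p^n` (default 1000).
#' @return A `study_config` list.
#' @export
study_config <- function(study = "study1", n_sides = 3, n_conformations = 2,
                         preset = "test_small", rule = "hebb",
                         grid = c(1, 1), spacing = 10, orientations = 0,
                         rate = NULL, eta = 0.8, epochs = 50, seed = 1,
                         record_layers = "top", n_blobs = 40,
                         max_shapes = 1000) {
  if (is.null(rate)) rate <- if (rule == "trace") 0.5 else 0.1
  cfg <- list(study = study, n_sides = n_sides,
              n_conformations = n_conformations, preset = preset,
              rule = rule, grid = grid, spacing = spacing,
              orientations = orientations, rate = rate, eta = eta,
              epochs = epochs, seed = seed, record_layers = record_layers,
              n_blobs = n_blobs, max_shapes = max_shapes)
  structure(cfg, class = "study_config")
}

study_stimuli <- function(config, retina) {
  if (config$study == "study3_like") {
    blob_stimuli(config$n_blobs, retina = retina, seed = config$seed)
  } else if (config$study %in% c("study2", "study2_trace")) {
    pasupathy_shapes(vertex_angle_sets = list(c(135, 135, 90)))
  } else {
    fam <- shape_family(config$n_sides, config$n_conformations)
    enumerate_shapes(fam, max_shapes = config$max_shapes)
  }
}

#' Run a complete simulation study
#'
#' Builds the study's stimuli, constructs the network from its preset,
#' evaluates the untrained baseline, trains with the configured rule, tests
#' again, and attaches the standard analyses (element-selectivity counts and
#' single-cell information, both before and after training).  Identical
#' configuration and seed give an identical result.
#'
#' @param config A [study_config()].
#' @param verbose Print progress.
#' @return A `study_result`: list with the trained `network`, the untrained
#'   and trained [response_table()]s, `selectivity` / `information` tibbles
#'   for both, the `elements` table, the `sequence`, and provenance
#'   (`config`, `hash`).
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  net_cfg <- network_preset(config$preset)
  shapes <- study_stimuli(config, net_cfg$retina)
  seq <- make_sequence(shapes, retina = net_cfg$retina, grid = config$grid,
                       spacing = config$spacing,
                       orientations = config$orientations)
  net0 <- build_network(net_cfg, seed = config$seed)
  resp0 <- response_table(net0, seq, layers = config$record_layers)
  net1 <- train_network(net0, seq, rule = config$rule, rate = config$rate,
                        eta = config$eta, epochs = config$epochs,
                        verbose = verbose)
  resp1 <- response_table(net1, seq, layers = config$record_layers)
  elements <- if (inherits(shapes, "data.frame")) element_table(shapes)
              else NULL
  sel0 <- sel1 <- info0 <- info1 <- NULL
  if (!is.null(elements)) {
    sel0 <- count_selective_cells(resp0, elements)
    sel1 <- count_selective_cells(resp1, elements)
    info0 <- single_cell_information(resp0, elements)
    info1 <- single_cell_information(resp1, elements)
  }
  structure(
    list(config = config, hash = rlang::hash(config), network = net1,
         untrained_network = NULL, shapes = shapes, sequence = seq,
         elements = elements,
         responses = list(untrained = resp0, trained = resp1),
         selectivity = list(untrained = sel0, trained = sel1),
         information = list(untrained = info0, trained = info1)),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s (%s rule, preset '%s', seed %d)\n",
              x$config$study, x$config$rule, x$config$preset,
              x$config$seed))
  if (!is.null(x$selectivity$trained)) {
    cat(sprintf("  selective cells: %d untrained -> %d trained\n",
                sum(x$selectivity$untrained$n_selective),
                sum(x$selectivity$trained$n_selective)))
  }
  invisible(x)
}

#' Mirror-image control test
#'
#' Tests whether element-selective cells encode boundary elements in the
#' object's frame of reference rather than as free-floating local features.
#' The test set is every trained object that contains a straight contour on
#' the right side; the control set contains their mirror images, reflected
#' about the retinal x-position of that right straight contour so that the
#' reflected (now left-side) straight contour occupies the same retinal
#' pixels as the original.  A cell coding "straight contour on the right of
#' an object" responds to the originals but not to the mirrored controls.
#'
#' @param net A trained `contour_network`.
#' @param shapes Shape table the network was trained on; the family must
#'   contain a `"straight"` conformation.
#' @param radius Circumradius used at rendering.  The default is
#'   `0.15 * min(retina)`, smaller than the rendering default, because the
#'   mirrored set occupies the half-retina beyond the reflection axis.
#' @param layers Layers to record (default `"top"`).
#' @return List with `original` and `mirrored` [response_table()]s (equal
#'   row counts, aligned by object and frame) and `axis` (the reflection
#'   x-position).
#' @export
run_mirror_test <- function(net, shapes, radius = NULL, layers = "top") {
  stopifnot(inherits(net, "contour_network"))
  fam <- shapes$shape[[1]]$family
  if (!"straight" %in% fam$labels) {
    stop("shape family has no 'straight' conformation: mirror test undefined",
         call. = FALSE)
  }
  retina <- net$config$retina
  if (is.null(radius)) radius <- 0.15 * min(retina)
  center <- (rev(retina) - 1) / 2
  keep <- vapply(shapes$elements, function(e) any(e == "straight"), TRUE)
  test <- shapes[keep, ]
  # retinal x of the right-side straight contour: the rightmost side chord
  # is vertical at center_x + radius * cos(pi / n)
  axis <- center[1] + radius * cos(pi / fam$n)
  seq_o <- make_sequence(test, retina = retina, radius = radius)
  seq_m <- make_sequence_mirror(test, retina = retina, radius = radius,
                                axis = axis)
  list(original = response_table(net, seq_o, layers = layers),
       mirrored = response_table(net, seq_m, layers = layers),
       axis = axis)
}

make_sequence_mirror <- function(shapes, retina, radius, axis) {
  seqd <- make_sequence(shapes, retina = retina, radius = radius)
  center <- (rev(as_retina(retina)) - 1) / 2
  for (i in seq_len(nrow(seqd$frames))) {
    key <- seqd$frames$key[i]
    img <- render_shape(shapes$shape[[match(seqd$frames$object_id[i],
                                            shapes$object_id)]],
                        retina = retina,
                        center = c(seqd$frames$center_x[i],
                                   seqd$frames$center_y[i]),
                        orientation = seqd$frames$orientation[i],
                        mirror = TRUE, mirror_axis = axis, radius = radius)
    seqd$images[[key]] <- unclass_image(img)
  }
  seqd
}
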
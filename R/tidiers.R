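#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network's synaptic structure
#'
#' One row per layer with weight-distribution summaries.
#'
#' @param x A `contour_network`.
#' @param ... Unused.
#' @return A tibble `layer`, `n_neurons`, `n_afferents`, `radius`,
#'   `in_radius_frac`, `w_mean`, `w_max`, `lateral`, `percentile`, `beta`.
#' @export
tidy.contour_network <- function(x, ...) {
  purrr::map_dfr(seq_along(x$layers), function(l) {
    ly <- x$layers[[l]]
    tibble::tibble(
      layer = l, n_neurons = prod(ly$dims), n_afferents = ly$map$n_conn,
      radius = ly$map$radius,
      in_radius_frac = mean(ly$map$dist <= ly$map$radius),
      w_mean = mean(ly$map$w), w_max = max(ly$map$w),
      lateral = ly$lateral$mode,
      percentile = ly$sigmoid$percentile, beta = ly$sigmoid$beta)
  })
}

#' One-row summary of a network
#'
#' @param x A `contour_network`.
#' @param ... Unused.
#' @return A tibble with retina size, layer count, lateral mode, total
#'   synapse count and training state.
#' @export
glance.contour_network <- function(x, ...) {
  tibble::tibble(
    preset = x$config$name,
    retina = paste(x$config$retina, collapse = "x"),
    n_layers = length(x$layers),
    lateral = x$config$mode,
    n_synapses = sum(vapply(x$layers,
                            function(l) length(l$map$w), 0)),
    trained = if (is.null(attr(x, "trained"))) "untrained"
              else attr(x, "trained"))
}

#' Tidy a study result
#'
#' Element-selectivity counts before and after training in long form.
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return A tibble `element`, `phase` (untrained/trained), `n_selective`.
#' @export
tidy.study_result <- function(x, ...) {
  if (is.null(x$selectivity$trained)) {
    return(tibble::tibble(element = character(), phase = character(),
                          n_selective = integer()))
  }
  dplyr::bind_rows(
    dplyr::mutate(x$selectivity$untrained, phase = "untrained"),
    dplyr::mutate(x$selectivity$trained, phase = "trained")
  )[, c("element", "phase", "n_selective")]
}

#' One-row summary of a study result
#'
#' @param x A `study_result`.
#' @param ... Unused.
#' @return A tibble with study id, seed, object count, total selective-cell
#'   counts and the count of cells at maximal information before/after
#'   training.
#' @export
glance.study_result <- function(x, ...) {
  n_max <- function(info) {
    if (is.null(info)) return(NA_integer_)
    p <- x$config$n_conformations
    crv <- information_curve(info)
    sum(crv$info >= log2(p) - 1e-6)
  }
  tibble::tibble(
    study = x$config$study, rule = x$config$rule, seed = x$config$seed,
    n_objects = length(unique(x$responses$trained$object_id)),
    selective_untrained = if (is.null(x$selectivity$untrained)) NA_integer_
                          else sum(x$selectivity$untrained$n_selective),
    selective_trained = if (is.null(x$selectivity$trained)) NA_integer_
                        else sum(x$selectivity$trained$n_selective),
    max_info_untrained = n_max(x$information$untrained),
    max_info_trained = n_max(x$information$trained))
}
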
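#' Load a study configuration from a YAML file
#'
#' The file holds [study_config()] fields.  A `preset` key both names the
#' network preset and, when it matches a study id, seeds the remaining
#' defaults, which individual keys then override.  Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
load_study_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("grid", "orientations")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.numeric(unlist(raw[[k]]))
  }
  do.call(study_config, raw)
}

#' Save a study configuration to YAML
#'
#' Round-trips with [load_study_config()].
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Save the artifacts of a study run
#'
#' Writes the trained network (serialized weights and connectivity), the
#' untrained/trained response tables and analysis tables as CSV, a JSON
#' summary, and a run manifest listing every written file with its MD5
#' checksum.  Re-running an identical configuration and seed reproduces
#' identical artifacts.
#'
#' @param result A [run_study()] result.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (`file`, `md5`), also written to
#'   `manifest.json`.
#' @export
save_artifacts <- function(result, out_dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(fname, fun) {
    p <- file.path(out_dir, fname)
    ok <- tryCatch({ fun(p); TRUE },
                   error = function(e) {
                     stop(sprintf("failed writing %s: %s", p,
                                  conditionMessage(e)), call. = FALSE)
                   })
    written <<- c(written, p)
    p
  }
  wr("network.rds", function(p) saveRDS(result$network, p))
  wr("responses_untrained.csv",
     function(p) utils::write.csv(result$responses$untrained, p,
                                  row.names = FALSE))
  wr("responses_trained.csv",
     function(p) utils::write.csv(result$responses$trained, p,
                                  row.names = FALSE))
  if (!is.null(result$selectivity$trained)) {
    wr("selectivity_trained.csv",
       function(p) utils::write.csv(result$selectivity$trained, p,
                                    row.names = FALSE))
    wr("selectivity_untrained.csv",
       function(p) utils::write.csv(result$selectivity$untrained, p,
                                    row.names = FALSE))
    wr("information_trained.csv",
       function(p) utils::write.csv(result$information$trained, p,
                                    row.names = FALSE))
    wr("information_untrained.csv",
       function(p) utils::write.csv(result$information$untrained, p,
                                    row.names = FALSE))
  }
  wr("config.yaml", function(p) save_study_config(result$config, p))
  summary <- list(
    study = result$config$study, hash = result$hash,
    seed = result$config$seed,
    n_objects = length(unique(result$responses$trained$object_id)),
    selective_untrained =
      if (!is.null(result$selectivity$untrained))
        sum(result$selectivity$untrained$n_selective) else NA,
    selective_trained =
      if (!is.null(result$selectivity$trained))
        sum(result$selectivity$trained$n_selective) else NA)
  wr("summary.json",
     function(p) jsonlite::write_json(summary, p, auto_unbox = TRUE,
                                      pretty = TRUE, digits = NA))
  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  manifest
}

#' Write a rendered stimulus as a plain-text PGM image
#'
#' Portable graymap (P2, ASCII), readable by any image tool and by
#' [read_pgm()].
#'
#' @param img Image matrix with values in `[0, 1]`.
#' @param path Output path.
#' @param maxval Gray levels (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  v <- round(pmin(pmax(as.matrix(img), 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), as.character(maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text PGM image
#'
#' @param path Path to a P2 (ASCII) PGM file.
#' @return Image matrix with values in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  w <- tok[1]; h <- tok[2]; maxval <- tok[3]
  stopifnot(txt[1] == "P2", length(tok) == 3 + w * h)
  matrix(tok[-(1:3)], nrow = h, ncol = w, byrow = TRUE) / maxval
}
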
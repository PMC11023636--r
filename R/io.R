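#' Read and write model parameter configurations
#'
#' Parameters are stored as flat YAML whose keys are exactly the fields of
#' [model_params()]. Unknown keys are rejected (with the offending key
#' named), missing keys fall back to the documented defaults, and all
#' range constraints are enforced on load -- in particular adhesion above
#' 0.66 is refused because it breaks positivity of the scalar diffusion
#' polynomial.
#'
#' @param path File path.
#' @return `read_params()` returns a [model_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) rlang::abort("config must be a YAML mapping")
  known <- names(formals(model_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(model_params, raw)
}

#' @rdname read_params
#' @param params A [model_params()] object.
#' @export
write_params <- function(params, path) {
  validate_model_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Read a trajectory table
#'
#' Reads a tracking export CSV with columns `track_id`, `frame`, `x_um`,
#' `y_um` (coordinates in micrometres at a fixed frame interval). Tracks
#' with skipped frames are split at every gap into separate trajectories
#' (suffix `.1`, `.2`, ...) rather than interpolated.
#'
#' @param path CSV file path.
#' @return A tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    rlang::abort(paste0("trajectory file misses column(s): ",
                        paste(miss, collapse = ", ")))
  }
  bad <- which(!complete.cases(df[, req]))
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed trajectory rows (line ",
                        paste(head(bad + 1, 5), collapse = ", "), " ...)"))
  }
  df <- dplyr::arrange(tibble::as_tibble(df[, req]), .data$track_id,
                       .data$frame)
  df |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(segment = cumsum(c(0, diff(.data$frame) != 1))) |>
    dplyr::ungroup() |>
    dplyr::mutate(track_id = ifelse(.data$segment == 0, .data$track_id,
                                    paste0(.data$track_id, ".",
                                           .data$segment))) |>
    dplyr::select(-"segment")
}

#' @rdname read_tracks
#' @param tracks Trajectory tibble.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "frame", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and write PIV vector fields
#'
#' Tidy CSV with columns `x_um`, `y_um` (regular grid, micrometres), `u`,
#' `v` (velocity components) and an optional logical `mask`; masked-out
#' vectors are excluded from every statistic.
#'
#' @param path CSV file path.
#' @return A tibble with columns `x_um`, `y_um`, `u`, `v`, `mask`.
#' @export
read_field <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x_um", "y_um", "u", "v")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    rlang::abort(paste0("vector-field file misses column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (!"mask" %in% names(df)) df$mask <- TRUE
  df$mask <- as.logical(df$mask)
  tibble::as_tibble(df[, c(req, "mask")])
}

#' @rdname read_field
#' @param field Vector-field tibble.
#' @export
write_field <- function(field, path) {
  utils::write.csv(field, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, next to every simulation or analysis output, the seed, the
#' parameter hash, the package version, the invoking command and timestamps,
#' so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param params The parameter object (hashed into the manifest).
#' @param seed Seed used.
#' @param command Free-form description of the invocation.
#' @param outputs Character vector of output paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, params, seed, command = "",
                           outputs = character()) {
  manifest <- list(
    package = "woundsim",
    version = as.character(utils::packageVersion("woundsim")),
    config_hash = rlang::hash(unclass(params)),
    seed = seed,
    command = command,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Synthetic single-cell fold-change table
#'
#' Loads the packaged *synthetic* stand-in for a single-cell migration
#' fold-change dataset (retraction duration, inter-retraction duration,
#' retraction strength and motility ratios of each perturbed condition over
#' its control). The numbers are illustrative placeholders whose signs
#' follow the qualitative single-cell observations (knockout: all four up;
#' gain-of-function: duration and strength up, idle time down, motility
#' unchanged; agonist-treated: strength up, durations down, motility
#' unchanged); they are not measured data.
#'
#' @return A tibble with columns `condition`, `parameter`, `fold`.
#' @export
synthetic_fold_changes <- function() {
  path <- system.file("extdata", "single_cell_folds_synthetic.csv",
                      package = "woundsim")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
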
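# Single configuration object covering all analysis stages; readable from
# YAML or JSON with sections landmark, enhancement, geometry,
# classification, stats.

#' Analysis configuration
#'
#' Bundles the per-stage settings used by [analyze_swallow()] and
#' [run_exam()].
#'
#' @param landmark List: `likelihood_threshold` (default 0.70),
#'   `max_low_fraction` (default 0.50), `adequacy_method` (`"all"` or
#'   `"mean"`), `fps` (default 30), `frame_count_slack` (tolerated
#'   mismatch between frame images and CSV rows, default 2).
#' @param enhance An [enhance_params()] or a list of overrides for it.
#' @param geometry A [geometry_config()] or a list of overrides.
#' @param classification List: `cell_presence_threshold` (default 0.01),
#'   `severe_includes_50` (default `FALSE`).
#' @param stats List: `kappa_weights` for ordinal agreement (default
#'   `"linear"`), `fisher_method` (default `"point"`).
#' @return An object of class `feesr_config`.
#' @export
feesr_config <- function(landmark = list(), enhance = list(),
                         geometry = list(), classification = list(),
                         stats = list()) {
  merge_defaults <- function(user, defaults) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  lm <- merge_defaults(landmark, list(likelihood_threshold = 0.70,
                                      max_low_fraction = 0.50,
                                      adequacy_method = "all",
                                      fps = 30, frame_count_slack = 2))
  ep <- if (inherits(enhance, "enhance_params")) enhance
        else do.call(enhance_params, enhance)
  gc <- if (inherits(geometry, "geometry_config")) geometry
        else {
          if (!is.null(geometry$central_cells) &&
              !is.list(geometry$central_cells[[1]])) {
            geometry$central_cells <- lapply(geometry$central_cells, unlist)
          }
          do.call(geometry_config, geometry)
        }
  cl <- merge_defaults(classification, list(cell_presence_threshold = 0.01,
                                            severe_includes_50 = FALSE))
  st <- merge_defaults(stats, list(kappa_weights = "linear",
                                   fisher_method = "point"))
  structure(list(landmark = lm, enhance = ep, geometry = gc,
                 classification = cl, stats = st),
            class = "feesr_config")
}

#' Read an analysis configuration file
#'
#' @param path YAML or JSON file with any of the sections `landmark`,
#'   `enhancement`, `geometry`, `classification`, `stats`; missing
#'   settings fall back to the package defaults.
#' @return A [feesr_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  feesr_config(landmark = raw$landmark %||% list(),
               enhance = raw$enhancement %||% list(),
               geometry = raw$geometry %||% list(),
               classification = raw$classification %||% list(),
               stats = raw$stats %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
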
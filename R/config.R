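# Run configuration: every tunable with its default, YAML round trip, and
# a provenance hash for output headers.

#' Default run configuration
#'
#' All tunables with their default values: overlap tolerance eps 0.35 rad
#' (relaxed to 0.7 after f = 5 consecutive transition failures), adjacency
#' margin xi 0.35 rad, density radius zeta 0.2 rad, heuristic weights
#' w1 = w2 = 1, collision overlap factor 0.65, bonded exclusion depth 3,
#' theta tuning grid 0.05 rad, chain-break threshold 2.0 Angstrom.
#'
#' @return named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    eps = 0.35,
    eps_relaxed = 0.7,
    f = 5L,
    xi = 0.35,
    zeta = 0.2,
    w1 = 1,
    w2 = 1,
    overlap_factor = 0.65,
    exclusion_depth = 3L,
    theta_grid_step = 0.05,
    central_norm = "per-angle",
    break_threshold = 2.0,
    max_recursions = 1000000L,
    seed = 1L
  ), class = "run_config")
}

#' Serialise a configuration as YAML
#'
#' @param config a `run_config` (default: [default_config()]).
#' @param file optional output path; when `NULL` the YAML text is
#'   returned.
#' @return the YAML string (invisibly when written to a file).
#' @export
dump_config <- function(config = default_config(), file = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Load a configuration file
#'
#' Unknown keys are an error; missing keys fall back to defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(unclass(base), vals)
  stopifnot(out$eps > 0, out$eps_relaxed >= out$eps, out$f >= 1,
            out$zeta > 0, out$xi >= 0,
            out$overlap_factor > 0, out$overlap_factor < 1)
  structure(out, class = "run_config")
}

config_hash <- function(config) {
  txt <- dump_config(config)
  # small stable polynomial content hash over the YAML text
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
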
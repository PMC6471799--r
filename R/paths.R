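# Path metrics, intermediate-state extraction, and path/state text I/O.

state_sequence <- function(path) {
  if (length(path$states) > 0) return(path$states)
  s <- path$s0
  out <- list(s)
  tr <- path$transitions
  for (r in seq_len(nrow(tr))) {
    s[tr$var[r]] <- tr$to[r]
    out[[r + 1]] <- s
  }
  out
}

#' Metrics of a transition path
#'
#' Steps (number of elementary transitions), distance (sum of the adjacency
#' edge lengths d along the path), and path density: the average of the
#' density of all the state variables along the path, i.e. the mean over
#' visited states of the mean rho across that state's variables
#' (`density_per_state`). A per-transition weighting (mean rho of the newly
#' adopted values) is reported alongside as `density_per_transition`.
#'
#' @param path a `transition_path`.
#' @param db the indexed `tripeptide_db` the path was computed against.
#' @return list with `steps`, `distance`, `density_per_state`,
#'   `density_per_transition`.
#' @export
path_metrics <- function(path, db) {
  stopifnot(inherits(path, "transition_path"))
  tr <- path$transitions
  keys <- path$keys
  libs <- lapply(keys, function(k) query_conformations(db, k))
  state_rho <- function(s)
    mean(vapply(seq_along(s), function(i) {
      rho <- libs[[i]]$rho
      if (is.null(rho)) stop("database not indexed for key ", keys[i])
      as.numeric(rho[s[i]])
    }, numeric(1)))
  states <- state_sequence(path)
  dens_state <- mean(vapply(states, state_rho, numeric(1)))
  dens_trans <- if (nrow(tr) > 0)
    mean(vapply(seq_len(nrow(tr)), function(r)
      as.numeric(libs[[tr$var[r]]]$rho[tr$to[r]]), numeric(1)))
  else NA_real_
  list(steps = nrow(tr),
       distance = if (nrow(tr) > 0) sum(tr$d) else 0,
       density_per_state = dens_state,
       density_per_transition = dens_trans)
}

#' Intermediate states at regular distance fractions
#'
#' Selects k + 1 states (endpoints included) at cumulative d-length
#' fractions j/k of the path's total length, snapping each fraction to the
#' nearest realized state (earlier state on ties) and enforcing
#' monotonicity along the path.
#'
#' @param path a successful `transition_path`.
#' @param k number of segments (default 10, i.e. a step size of 1/10th of
#'   the total length).
#' @return list of state assignments; when the path has fewer than `k`
#'   steps all its states are returned with attribute `note`.
#' @export
select_intermediates <- function(path, k = 10) {
  stopifnot(k >= 1)
  states <- state_sequence(path)
  m <- length(states) - 1
  if (m < k) {
    attr(states, "note") <- sprintf(
      "path has %d steps < k = %d; returning all states", m, k)
    return(states)
  }
  cum <- c(0, cumsum(path$transitions$d))
  total <- cum[length(cum)]
  targets <- seq(0, total, length.out = k + 1)
  idx <- integer(k + 1)
  prev <- 1L
  for (j in seq_along(targets)) {
    cand <- which.min(abs(cum - targets[j]))
    idx[j] <- max(cand, prev)
    prev <- idx[j]
  }
  idx[1] <- 1L
  idx[k + 1] <- length(states)
  states[idx]
}

# --- text I/O ---------------------------------------------------------------

#' Write / read a state assignment as text
#'
#' One line per state variable: tripeptide key and 1-based conformation
#' index, whitespace-separated. `#` comment lines are ignored on read.
#'
#' @param state integer assignment.
#' @param keys tripeptide keys of the protein (same length).
#' @param path file path.
#' @return `write_state`: `path` invisibly; `read_state`: list with
#'   `keys`, `state`.
#' @export
write_state <- function(state, keys, path) {
  stopifnot(length(state) == length(keys))
  writeLines(paste(keys, state), path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(parts, `[[`, character(1), 1)
  state <- as.integer(vapply(parts, `[[`, character(1), 2))
  stopifnot(all(valid_key(keys)), !anyNA(state), all(state >= 1))
  list(keys = keys, state = state)
}

#' Write a transition path as a JSON-lines log
#'
#' First line: a provenance header (sequence, parameters, seed, status,
#' metrics, diagnostics). Then one JSON object per elementary transition
#' (`var`, `from`, `to`, `d`, `eps`). Deterministic: identical problem and
#' seed produce byte-identical logs.
#'
#' @param path a `transition_path`.
#' @param file output file path.
#' @return `file`, invisibly.
#' @export
write_path_log <- function(path, file) {
  stopifnot(inherits(path, "transition_path"))
  header <- list(format = "tripath-path", version = 1L,
                 sequence = path$sequence, keys = path$keys,
                 status = path$status,
                 s0 = path$s0, sg = path$sg,
                 params = path$params,
                 metrics = path$metrics,
                 diagnostics = path$diagnostics)
  tr <- path$transitions
  lines <- c(
    as.character(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17),
                                  null = "null")),
    vapply(seq_len(nrow(tr)), function(r)
      as.character(jsonlite::toJSON(
        list(var = tr$var[r], from = tr$from[r], to = tr$to[r],
             d = tr$d[r], eps = tr$eps[r]),
        auto_unbox = TRUE, digits = I(17))), character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Read a JSON-lines path log written by [write_path_log()]
#'
#' @param file log file path.
#' @return a `transition_path` (without the `states` expansion; it is
#'   rebuilt on demand from `s0` and the transitions).
#' @export
read_path_log <- function(file) {
  lines <- readLines(file)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$format, "tripath-path"))
    stop("not a tripath path log: ", file)
  tr <- if (length(lines) > 1) {
    rows <- lapply(lines[-1], jsonlite::fromJSON, simplifyVector = TRUE)
    do.call(rbind, lapply(rows, as.data.frame))
  } else {
    data.frame(var = integer(0), from = integer(0), to = integer(0),
               d = numeric(0), eps = numeric(0))
  }
  structure(list(status = header$status, transitions = tr,
                 states = list(),
                 s0 = as.integer(header$s0), sg = as.integer(header$sg),
                 keys = header$keys, sequence = header$sequence,
                 params = header$params, metrics = header$metrics,
                 diagnostics = header$diagnostics),
            class = "transition_path")
}
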
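# Persist and query the tripeptide conformation library: the finite domains
# of every three-residue sequence key, grouped from extraction records.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

# parent-type mapping for common modified residues; anything else is
# non-standard and excluded at extraction time
AA3_TO_1 <- c(structure(names(AA3), names = unname(AA3)),
              MSE = "M", SEC = "C", PYL = "K")

#' All possible tripeptide sequence keys
#'
#' @return character vector of the 20^3 = 8000 three-letter (one-letter
#'   code) tripeptide keys, lexicographically ordered.
#' @export
all_tripeptide_keys <- function() {
  g <- expand.grid(c3 = AA1, c2 = AA1, c1 = AA1, stringsAsFactors = FALSE)
  sort(paste0(g$c1, g$c2, g$c3))
}

#' Convert tripeptide keys between one- and three-letter codes
#'
#' @param key character vector of keys, e.g. `"GYD"` or `"Gly-Tyr-Asp"`.
#' @return the keys in the other convention.
#' @export
key_to_three <- function(key) {
  vapply(key, function(k) {
    paste(AA3[strsplit(k, "")[[1]]], collapse = "-")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname key_to_three
#' @export
key_to_one <- function(key) {
  vapply(key, function(k) {
    parts <- toupper(strsplit(k, "-", fixed = TRUE)[[1]])
    one <- AA3_TO_1[parts]
    if (anyNA(one)) stop("unknown residue in key: ", k)
    paste(one, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

valid_key <- function(key) {
  nchar(key) == 3 & !grepl(paste0("[^", paste(AA1, collapse = ""), "]"), key)
}

#' Group tripeptide records into a database
#'
#' Records are grouped by sequence key; within each key, conformations are
#' ordered deterministically by source id, chain and start position, and
#' exact duplicate source windows are stored once. The conformation index
#' within a key is the value id used everywhere else (state assignments,
#' adjacency graphs).
#'
#' @param records data frame as returned by [extract_tripeptides()]:
#'   columns `key`, `phi1`, `psi1`, `phi2`, `psi2`, `phi3`, `psi3`,
#'   `omega_flags`, `source_id`, `chain`, `start`.
#' @param meta named list of build metadata merged into the database
#'   metadata (e.g. `manifest_hash`, `synthetic`).
#' @return an object of class `tripeptide_db`.
#' @export
build_database <- function(records, meta = list()) {
  libs <- list()
  if (is.null(records) || nrow(records) == 0) {
    warning("no records: building an empty database")
  } else {
    stopifnot(all(valid_key(records$key)))
    ord <- order(records$source_id, records$chain, records$start)
    records <- records[ord, , drop = FALSE]
    src <- paste(records$source_id, records$chain, records$start, sep = "|")
    records <- records[!duplicated(src), , drop = FALSE]
    for (k in sort(unique(records$key))) {
      r <- records[records$key == k, , drop = FALSE]
      conf <- as.matrix(r[, TRIPEP_ANGLE_NAMES])
      dimnames(conf) <- list(NULL, TRIPEP_ANGLE_NAMES)
      conf[] <- wrap_angle(conf)
      libs[[k]] <- list(
        conf = conf,
        source = paste(r$source_id, r$chain, r$start, sep = "|"),
        omega_flags = if ("omega_flags" %in% names(r)) r$omega_flags
                      else rep("tt", nrow(r)),
        graph = NULL, rho = NULL, theta = NA_real_)
    }
  }
  meta <- utils::modifyList(
    list(format_version = 1L, synthetic = FALSE, params = list()), meta)
  structure(list(libraries = libs, meta = meta), class = "tripeptide_db")
}

#' Look up the conformation library of one tripeptide key
#'
#' @param db a `tripeptide_db`.
#' @param key a single tripeptide key (one-letter codes).
#' @return the library (list with `conf` matrix, `source`, optional
#'   `graph`, `rho`, `theta`), or `NULL` if the key has no recorded
#'   conformations. Callers that require a non-empty domain must treat
#'   `NULL` as an error; [transition_problem()] and friends do.
#' @export
query_conformations <- function(db, key) {
  stopifnot(inherits(db, "tripeptide_db"), length(key) == 1, valid_key(key))
  db$libraries[[key]]
}

#' Per-key conformation counts and summary
#'
#' @param db a `tripeptide_db`.
#' @param keys optional character vector restricting the report.
#' @return list with `per_key` (data frame `key`, `count`), `n_keys`,
#'   `n_conformations`, `min`, `max`, `mean`.
#' @export
database_stats <- function(db, keys = NULL) {
  stopifnot(inherits(db, "tripeptide_db"))
  if (is.null(keys)) keys <- names(db$libraries)
  counts <- vapply(keys, function(k) {
    lib <- db$libraries[[k]]
    if (is.null(lib)) 0L else nrow(lib$conf)
  }, integer(1))
  per_key <- data.frame(key = keys, count = unname(counts),
                        stringsAsFactors = FALSE)
  list(per_key = per_key,
       n_keys = length(keys),
       n_conformations = sum(counts),
       min = if (length(counts)) min(counts) else NA_integer_,
       max = if (length(counts)) max(counts) else NA_integer_,
       mean = if (length(counts)) mean(counts) else NA_real_)
}

#' @export
print.tripeptide_db <- function(x, ...) {
  st <- database_stats(x)
  cat("Tripeptide conformation database\n")
  cat(sprintf("  keys: %d   conformations: %d\n", st$n_keys,
              st$n_conformations))
  if (st$n_keys > 0)
    cat(sprintf("  per-key count: min %d / mean %.1f / max %d\n",
                st$min, st$mean, st$max))
  idx <- sum(vapply(x$libraries, function(l) !is.null(l$graph), logical(1)))
  cat(sprintf("  indexed keys (adjacency graph + density): %d\n", idx))
  if (isTRUE(x$meta$synthetic)) cat("  [synthetic database]\n")
  invisible(x)
}

# --- serialization (versioned JSON container) -------------------------------

lib_to_list <- function(lib) {
  out <- list(conf = apply(lib$conf, 1, function(r) as.numeric(r),
                           simplify = FALSE),
              source = as.character(lib$source),
              omega_flags = as.character(lib$omega_flags),
              theta = lib$theta)
  if (!is.null(lib$graph)) {
    g <- lib$graph
    out$graph <- list(n = g$n, theta = g$theta, xi = g$xi,
                      central_norm = g$central_norm,
                      u = as.integer(g$edges[, 1]),
                      v = as.integer(g$edges[, 2]),
                      d = as.numeric(g$edges[, 3]))
  }
  if (!is.null(lib$rho)) {
    out$rho <- as.integer(lib$rho)
    out$zeta <- lib$zeta
  }
  out
}

list_to_lib <- function(l) {
  conf <- do.call(rbind, lapply(l$conf, as.numeric))
  if (is.null(conf)) conf <- matrix(numeric(0), 0, 6)
  dimnames(conf) <- list(NULL, TRIPEP_ANGLE_NAMES)
  lib <- list(conf = conf, source = as.character(l$source),
              omega_flags = as.character(l$omega_flags),
              graph = NULL, rho = NULL,
              theta = if (is.null(l$theta)) NA_real_ else l$theta)
  if (!is.null(l$graph)) {
    g <- l$graph
    lib$graph <- structure(list(
      n = as.integer(g$n),
      edges = cbind(u = as.integer(g$u), v = as.integer(g$v),
                    d = as.numeric(g$d)),
      theta = as.numeric(g$theta), xi = as.numeric(g$xi),
      central_norm = as.character(g$central_norm)),
      class = "adjacency_graph")
  }
  if (!is.null(l$rho)) {
    lib$rho <- as.integer(l$rho)
    lib$zeta <- as.numeric(l$zeta)
  }
  lib
}

#' Write a tripeptide database to disk
#'
#' Single-file versioned JSON container, one block per tripeptide key
#' (six angles per conformation as full-precision floats in radians, source
#' ids, and, when indexed, the adjacency graph, theta and densities). Keys
#' are written in sorted order so that save/load/save is byte-identical.
#'
#' @param db a `tripeptide_db`.
#' @param path output file path (conventional extension `.tpd.json`).
#' @return `path`, invisibly.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "tripeptide_db"))
  keys <- sort(names(db$libraries))
  payload <- list(
    format = "tripath-db",
    format_version = db$meta$format_version,
    meta = db$meta[setdiff(names(db$meta), "format_version")],
    keys = keys,
    libraries = lapply(db$libraries[keys], lib_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read a tripeptide database written by [write_db()]
#'
#' @param path file path.
#' @return a `tripeptide_db`.
#' @export
read_db <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "tripath-db"))
    stop("not a tripath database file: ", path)
  libs <- lapply(p$libraries, list_to_lib)
  names(libs) <- unlist(p$keys)
  meta <- p$meta
  meta$format_version <- as.integer(p$format_version)
  # undo auto_unbox on scalar params
  structure(list(libraries = libs, meta = meta), class = "tripeptide_db")
}
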
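# Extraction of tripeptide dihedral records from protein structure files.
# Curation policy: first model only; highest-occupancy altloc (ties -> "A");
# waters and hetero residues skipped; chain break declared when the peptide
# C-N distance exceeds `break_threshold` or a backbone atom is missing;
# modified residues mapped to their parent type where a standard mapping
# exists, otherwise the window is skipped.

#' Extraction filters
#'
#' @param break_threshold peptide C-N distance (Angstrom) above which a
#'   chain break is declared (default 2.0).
#' @param cis_cutoff |omega| below this (radians) labels a peptide bond
#'   cis (default pi/2); the label is provenance only, geometry treats all
#'   bonds as trans.
#' @return list of class `extraction_filters`.
#' @export
extraction_filters <- function(break_threshold = 2.0, cis_cutoff = pi / 2) {
  stopifnot(break_threshold > 0)
  structure(list(break_threshold = break_threshold,
                 cis_cutoff = cis_cutoff), class = "extraction_filters")
}

#' Extract tripeptide dihedral records from a structure
#'
#' Every window of three consecutive observed standard residues with no
#' chain break and all six backbone dihedrals defined yields one record.
#' phi of a chain's first residue and psi of its last are undefined, so the
#' two terminal windows of an isolated chain are skipped along with any
#' window overlapping a break, a non-standard residue, or missing backbone
#' atoms.
#'
#' @param pdb a file path or a `bio3d` pdb object.
#' @param filters an [extraction_filters()] object.
#' @param source_id provenance tag; defaults to the file base name.
#' @return data frame of records: `key`, the six angles (`phi1` ... `psi3`,
#'   radians), `omega_flags` (cis/trans letters for the window's two
#'   internal peptide bonds), `source_id`, `chain`, `start` (residue number
#'   of the window's first residue). Zero valid windows give an empty data
#'   frame, not an error.
#' @export
extract_tripeptides <- function(pdb, filters = extraction_filters(),
                                source_id = NULL) {
  if (is.character(pdb)) {
    path <- pdb
    if (is.null(source_id))
      source_id <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path))
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                    error = function(e)
                      stop("cannot parse structure file ", path, ": ",
                           conditionMessage(e)))
    if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
      stop("cannot parse structure file ", basename(path),
           ": no atom records")
  }
  if (is.null(source_id)) source_id <- "structure"
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) return(empty_records())
  # altloc resolution: keep the highest-occupancy alternate per atom site,
  # ties broken in favour of "A" (then alphabetically)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(site, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(site[ord]), , drop = FALSE]
  # restore chain order (the site sort is lexicographic)
  ins <- at$insert
  ins[is.na(ins)] <- ""
  at <- at[order(at$chain, at$resno, ins), , drop = FALSE]

  recs <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    res_id <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
    res_ids <- unique(res_id)
    L <- length(res_ids)
    if (L < 3) next
    one <- character(L)
    resno <- integer(L)
    xyz <- array(NA_real_, c(L, 3, 3),
                 dimnames = list(NULL, c("N", "CA", "C"), NULL))
    for (k in seq_len(L)) {
      rr <- ca[res_id == res_ids[k], , drop = FALSE]
      one[k] <- if (rr$resid[1] %in% names(AA3_TO_1))
        AA3_TO_1[[rr$resid[1]]] else NA_character_
      resno[k] <- rr$resno[1]
      for (a in c("N", "CA", "C")) {
        hit <- which(rr$elety == a)
        if (length(hit) >= 1)
          xyz[k, a, ] <- as.numeric(rr[hit[1], c("x", "y", "z")])
      }
    }
    complete <- apply(xyz, 1, function(m) all(is.finite(m)))
    # chain break between k and k+1: missing atoms or long C-N bond
    broken <- vapply(seq_len(L - 1), function(k) {
      if (!complete[k] || !complete[k + 1]) return(TRUE)
      sqrt(sum((xyz[k, "C", ] - xyz[k + 1, "N", ])^2)) >
        filters$break_threshold
    }, logical(1))
    dih <- chain_dihedrals_with_breaks(xyz, broken, complete)
    for (i in seq_len(L - 2)) {
      ks <- i:(i + 2)
      if (anyNA(one[ks])) next
      if (any(!complete[ks])) next
      if (any(broken[i:(i + 1)])) next
      phi <- dih$phi[ks]
      psi <- dih$psi[ks]
      if (anyNA(phi) || anyNA(psi)) next
      om <- dih$omega[i:(i + 1)]
      flags <- paste(ifelse(abs(om) < filters$cis_cutoff, "c", "t"),
                     collapse = "")
      recs[[length(recs) + 1L]] <- data.frame(
        key = paste(one[ks], collapse = ""),
        phi1 = phi[1], psi1 = psi[1], phi2 = phi[2], psi2 = psi[2],
        phi3 = phi[3], psi3 = psi[3],
        omega_flags = flags, source_id = source_id, chain = ch,
        start = resno[i], stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) empty_records() else do.call(rbind, recs)
}

empty_records <- function() {
  data.frame(key = character(0), phi1 = numeric(0), psi1 = numeric(0),
             phi2 = numeric(0), psi2 = numeric(0), phi3 = numeric(0),
             psi3 = numeric(0), omega_flags = character(0),
             source_id = character(0), chain = character(0),
             start = integer(0), stringsAsFactors = FALSE)
}

# per-residue phi/psi/omega with breaks masked out
chain_dihedrals_with_breaks <- function(xyz, broken, complete) {
  L <- dim(xyz)[1]
  phi <- psi <- omega <- rep(NA_real_, L)
  linked <- function(k) k >= 1 && k <= L - 1 && !broken[k]
  for (k in seq_len(L)) {
    if (!complete[k]) next
    if (k > 1 && linked(k - 1))
      phi[k] <- torsion_angle(xyz[k - 1, "C", ], xyz[k, "N", ],
                              xyz[k, "CA", ], xyz[k, "C", ])
    if (k < L && linked(k)) {
      psi[k] <- torsion_angle(xyz[k, "N", ], xyz[k, "CA", ],
                              xyz[k, "C", ], xyz[k + 1, "N", ])
      omega[k] <- torsion_angle(xyz[k, "CA", ], xyz[k, "C", ],
                                xyz[k + 1, "N", ], xyz[k + 1, "CA", ])
    }
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Build a database from a manifest of structure files
#'
#' @param manifest text file listing one structure path per line (`#`
#'   comments and blank lines ignored; relative paths resolved against the
#'   manifest's directory).
#' @param filters an [extraction_filters()].
#' @return a `tripeptide_db`; its metadata records the manifest content
#'   hash.
#' @export
build_db_from_manifest <- function(manifest, filters = extraction_filters()) {
  lines <- trimws(readLines(manifest))
  paths <- lines[nzchar(lines) & !startsWith(lines, "#")]
  base <- dirname(manifest)
  paths <- ifelse(file.exists(paths), paths, file.path(base, paths))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("structure file(s) not found: ", paste(missing, collapse = ", "))
  recs <- do.call(rbind, lapply(paths, extract_tripeptides,
                                filters = filters))
  hash <- sum(utf8ToInt(paste(basename(paths), collapse = ";"))) %% 1e9
  build_database(recs, meta = list(manifest_hash = hash,
                                   n_structures = length(paths)))
}
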
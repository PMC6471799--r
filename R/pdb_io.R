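# PDB output for assembled chains: single models and multi-model
# trajectories (one MODEL per state along a path).

pdb_atom_line <- function(serial, name, resid3, chain, resno, xyz) {
  # PDB v3.3 fixed columns; element right-justified in 77-78
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, resid3, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(name, 1, 1))
}

chain_to_pdb_lines <- function(chain, chain_id = "A") {
  n <- length(chain$sequence)
  lines <- character(0)
  serial <- 0L
  for (k in seq_len(n)) {
    res3 <- AA3[[chain$sequence[k]]]
    for (a in c("N", "CA", "C", "O", "CB")) {
      if (a == "CB" && chain$sequence[k] == "G") next
      serial <- serial + 1L
      lines <- c(lines,
                 pdb_atom_line(serial, a, res3, chain_id, k, chain[[a]][k, ]))
    }
  }
  c(lines, sprintf("TER   %5d      %3s %1s%4d",
                   serial + 1L, AA3[[chain$sequence[n]]], chain_id, n))
}

#' Write chains as a (multi-model) PDB file
#'
#' A single `chain_coords` writes one model; a list writes one MODEL /
#' ENDMDL block per element (e.g. the intermediates of a transition path).
#' Glycine's virtual pseudo-atom is not emitted.
#'
#' @param chains a `chain_coords` or list of them.
#' @param file output path.
#' @param chain_id one-character PDB chain identifier.
#' @param remark optional character vector written as REMARK lines.
#' @return `file`, invisibly.
#' @export
write_chain_pdb <- function(chains, file, chain_id = "A", remark = NULL) {
  if (inherits(chains, "chain_coords")) chains <- list(chains)
  out <- character(0)
  if (!is.null(remark))
    out <- sprintf("REMARK   6 %s", remark)
  multi <- length(chains) > 1
  for (m in seq_along(chains)) {
    if (multi) out <- c(out, sprintf("MODEL %8d", m))
    out <- c(out, chain_to_pdb_lines(chains[[m]], chain_id))
    if (multi) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}
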
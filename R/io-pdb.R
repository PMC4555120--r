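#' Read atom records from a PDB coordinate file
#'
#' Parses ATOM and HETATM records (via `bio3d`) into a plain data frame of
#' atom records.  Only the first alternate location of each atom is kept and
#' insertion codes are ignored; hydrogens are retained here and excluded at
#' the contact-analysis stage.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier; if given, only that chain's
#'   records are returned.
#' @return A data frame with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `het`.
#' @export
read_pdb_atoms <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_ctx("PDB file not found: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop_ctx("could not parse PDB file %s: %s",
                                               path, conditionMessage(e)))
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- substr(gsub("[0-9]", "", a$elety[miss]), 1, 1)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    res_seq = as.integer(a$resno),
    res_name = a$resid,
    atom_name = a$elety,
    element = toupper(trimws(elem)),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop_ctx("non-numeric coordinate in %s", path)
  }
  if (!is.null(chain)) atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write atom records to a PDB coordinate file
#'
#' Emits fixed-column ATOM/HETATM records (coordinates at the standard 0.001
#' angstrom precision) followed by END.
#'
#' @param atoms Data frame as returned by [read_pdb_atoms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  # standard columns: name 13-16, altLoc 17, resName 18-20, chainID 22,
  # resSeq 23-26, iCode 27, x/y/z 31-54, occupancy/B 55-66, element 77-78
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom_name) < 4, paste0(" ", atoms$atom_name), atoms$atom_name),
    atoms$res_name, atoms$chain, atoms$res_seq,
    atoms$x, atoms$y, atoms$z, 1, 0, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
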
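# Heavy atoms only (contact criteria are heavy-atom minimum distances).
heavy_atoms <- function(atoms) atoms[atoms$element != "H", , drop = FALSE]

# Atoms of one annotated helix range.
helix_atoms <- function(atoms, helix) {
  sel <- atoms$chain == helix$chain &
    atoms$res_seq >= helix$res_start & atoms$res_seq <= helix$res_end &
    !atoms$het
  atoms[sel, , drop = FALSE]
}

#' Interhelical residue contacts from coordinates
#'
#' A residue pair is a contact iff the residues lie on different annotated
#' helices and their minimum heavy-atom distance is at most `cutoff`
#' (4.5 angstrom by default, the common van der Waals contact convention;
#' the criterion is configurable).  Hydrogens are excluded.  Each unordered
#' residue pair is listed once.
#'
#' @param atoms Atom data frame from [read_pdb_atoms()].
#' @param helices Data frame with `label`, `chain`, `res_start`, `res_end`
#'   (author residue numbering, inclusive).
#' @param cutoff Distance cutoff in angstrom.
#' @return Data frame with `res_i`, `helix_i`, `res_j`, `helix_j`,
#'   `distance`, sorted by residue numbers.
#' @export
interhelical_contacts <- function(atoms, helices, cutoff = 4.5) {
  atoms <- heavy_atoms(atoms)
  hx <- split(helices, seq_len(nrow(helices)))
  per_helix <- lapply(hx, function(h) {
    a <- helix_atoms(atoms, h)
    if (nrow(a) == 0L) {
      stop_ctx("helix %s (%s %d-%d) matches no atoms", h$label, h$chain,
               h$res_start, h$res_end)
    }
    a
  })
  labels <- vapply(hx, function(h) h$label, character(1))
  out <- list()
  for (i in seq_along(per_helix)) {
    for (j in seq_along(per_helix)) {
      if (j <= i) next
      ai <- per_helix[[i]]
      aj <- per_helix[[j]]
      d2 <- outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
        outer(ai$z, aj$z, "-")^2
      within <- which(d2 <= cutoff^2, arr.ind = TRUE)
      if (nrow(within) == 0L) next
      pair_key <- paste(ai$res_seq[within[, 1]], aj$res_seq[within[, 2]])
      dmin <- tapply(sqrt(d2[within]), pair_key, min)
      parts <- do.call(rbind, strsplit(names(dmin), " ", fixed = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        res_i = as.integer(parts[, 1]), helix_i = labels[i],
        res_j = as.integer(parts[, 2]), helix_j = labels[j],
        distance = as.numeric(dmin), stringsAsFactors = FALSE,
        row.names = NULL)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(res_i = integer(0), helix_i = character(0),
               res_j = integer(0), helix_j = character(0),
               distance = numeric(0))
  }
  res <- res[order(res$res_i, res$res_j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Protein residues contacting a bound ligand
#'
#' Protein residues (ATOM records) with any heavy atom within `cutoff` of
#' any heavy atom of the named HETATM ligand.
#'
#' @param atoms Atom data frame from [read_pdb_atoms()].
#' @param ligand_resname 3-letter residue name of the ligand.
#' @param cutoff Distance cutoff in angstrom.
#' @return Sorted integer vector of contacting residue numbers.
#' @export
ligand_contacts <- function(atoms, ligand_resname, cutoff = 4.5) {
  atoms <- heavy_atoms(atoms)
  lig <- atoms[atoms$het & atoms$res_name == ligand_resname, , drop = FALSE]
  if (nrow(lig) == 0L) stop_ctx("ligand '%s' not found", ligand_resname)
  prot <- atoms[!atoms$het, , drop = FALSE]
  d2 <- outer(prot$x, lig$x, "-")^2 + outer(prot$y, lig$y, "-")^2 +
    outer(prot$z, lig$z, "-")^2
  hit <- apply(d2 <= cutoff^2, 1L, any)
  sort(unique(prot$res_seq[hit]))
}
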
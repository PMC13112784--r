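#' Symmetry-aware side-chain RMSD and crystal-likeness labeling
#'
#' RMSD between a modeled and a reference side chain is computed over
#' side-chain heavy atoms excluding C-beta, matched by atom name and
#' minimized over the residue's chemically indistinguishable atom-name
#' permutations (ring flips of Phe/Tyr, carboxylate oxygens of Asp/Glu,
#' guanidinium nitrogens of Arg).  No superposition is performed: the
#' modeled side chain lives on the same backbone as the reference, so
#' the shared frame is the comparison frame.
#'
#' @name structure_labeling
NULL

#' Side-chain atom-name equivalence permutations
#'
#' Each permutation is an involution on the residue's side-chain atom
#' names; the identity is always included.
#'
#' @return named list residue name -> list of named character vectors
#'   (old name -> new name).
#' @export
equivalence_table <- function() {
  list(
    PHE = list(c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")),
    TYR = list(c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")),
    ASP = list(c(OD1 = "OD2", OD2 = "OD1")),
    GLU = list(c(OE1 = "OE2", OE2 = "OE1")),
    ARG = list(c(NH1 = "NH2", NH2 = "NH1"))
  )
}

.sidechain_coords <- function(res_atoms, exclude = c("CB")) {
  bb <- c("N", "CA", "C", "O", "OXT")
  keep <- !(res_atoms$name %in% c(bb, exclude)) & res_atoms$element != "H"
  sc <- res_atoms[keep, , drop = FALSE]
  stats::setNames(split(as.matrix(sc[, c("x", "y", "z")]),
                        seq_len(nrow(sc))), sc$name)
}

#' Symmetry-minimized side-chain RMSD
#'
#' @param model,reference data frames of residue atoms (columns name,
#'   element, x, y, z, resname) or a `mol_system` residue subset.
#' @param table equivalence permutations ([equivalence_table()]).
#' @param threshold crystal-likeness threshold in Angstrom (default 1.0).
#' @param exclude atom names excluded from the comparison (default CB).
#' @return list with `rmsd` (Angstrom), `mapping` (the permutation
#'   used), `label` (`"crystal_like"` iff `rmsd < threshold`) and
#'   `threshold`.
#' @export
sidechain_rmsd_symm <- function(model, reference, table = equivalence_table(),
                                threshold = 1.0, exclude = c("CB")) {
  if (model$resname[1] != reference$resname[1])
    stop(sprintf("residue type mismatch: %s vs %s",
                 model$resname[1], reference$resname[1]))
  mc <- .sidechain_coords(model, exclude)
  rc <- .sidechain_coords(reference, exclude)
  if (!setequal(names(mc), names(rc)) || length(mc) == 0)
    stop("sidechain_rmsd_symm: incomplete or mismatched side-chain atoms")
  perms <- c(list(identity = character(0)),
             table[[model$resname[1]]] %||% list())
  best <- NULL
  for (pi_ in seq_along(perms)) {
    perm <- perms[[pi_]]
    sq <- 0
    for (nm in names(mc)) {
      ref_nm <- if (nm %in% names(perm)) perm[[nm]] else nm
      d <- mc[[nm]] - rc[[ref_nm]]
      sq <- sq + sum(d * d)
    }
    r <- sqrt(sq / length(mc))
    if (is.null(best) || r < best$rmsd)
      best <- list(rmsd = r, mapping = perm)
  }
  best$label <- if (best$rmsd < threshold) "crystal_like" else "non_crystal_like"
  best$threshold <- threshold
  best
}

#' Crystal-likeness label for a residue pair
#'
#' A double-point-mutation structure is crystal-like iff both residues
#' are below the threshold, i.e. iff `max(rmsd1, rmsd2) < threshold`.
#'
#' @param rmsd1,rmsd2 per-residue RMSDs (Angstrom).
#' @param threshold Angstrom; 0.8 / 1.0 / 1.2 are the values used for
#'   robustness sweeps.
#' @return `"crystal_like"` or `"non_crystal_like"`.
#' @export
label_pair <- function(rmsd1, rmsd2, threshold = 1.0) {
  if (max(rmsd1, rmsd2) < threshold) "crystal_like" else "non_crystal_like"
}

#' Joint RMSD over the pooled atoms of two residues
#'
#' Alternative DPM labeling: one RMSD over both side chains' atoms
#' pooled, each residue still minimized over its own symmetry
#' permutations (permutations act within a residue only).
#'
#' @inheritParams sidechain_rmsd_symm
#' @param model1,model2,reference1,reference2 residue atom tables.
#' @return list with `rmsd`, `label`, `threshold`.
#' @export
pair_rmsd_joint <- function(model1, reference1, model2, reference2,
                            table = equivalence_table(), threshold = 1.0,
                            exclude = c("CB")) {
  r1 <- sidechain_rmsd_symm(model1, reference1, table, threshold, exclude)
  r2 <- sidechain_rmsd_symm(model2, reference2, table, threshold, exclude)
  n1 <- length(.sidechain_coords(model1, exclude))
  n2 <- length(.sidechain_coords(model2, exclude))
  rmsd <- sqrt((n1 * r1$rmsd^2 + n2 * r2$rmsd^2) / (n1 + n2))
  list(rmsd = rmsd,
       label = if (rmsd < threshold) "crystal_like" else "non_crystal_like",
       threshold = threshold)
}

#' Extract one residue's atoms from a system
#'
#' @param sys `mol_system`; `reskey` residue key.
#' @return data frame of the residue's atoms.
#' @export
residue_atoms <- function(sys, reskey) {
  out <- sys$atoms[sys$atoms$reskey == reskey, , drop = FALSE]
  if (nrow(out) == 0) stop(sprintf("residue %s not found", reskey))
  out
}
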
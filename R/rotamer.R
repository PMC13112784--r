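#' Backbone-dependent rotamer energies
#'
#' Parses a backbone-dependent rotamer library in the standard
#' whitespace-separated layout (residue, phi, psi, count, four rotamer
#' indices, probability, four chi means, four chi sigmas) and converts
#' rotamer probabilities into a pseudo-energy
#' `E = -RT ln(p / p_max)` (kcal/mol), where `p_max` is the largest
#' rotamer probability at the same backbone bin.  For a residue pair the
#' probabilities are assumed independent and multiplied, so the pair
#' energy is exactly the sum of the single-residue energies.
#'
#' @name rotamer_energy
NULL

GAS_CONSTANT_KCAL <- 0.001987  # kcal/(mol K)

#' Parse a backbone-dependent rotamer library file
#'
#' @param path text file; `#` comment lines are skipped.  Each record
#'   has at least 9 whitespace-separated fields: residue name, phi, psi,
#'   count, r1-r4, probability (chi means/sigmas may follow).
#' @return object of class `rotamer_library`: a data frame of records
#'   plus the inferred backbone bin width.
#' @export
parse_rotamer_library <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  recs <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 9)
  if (length(bad))
    stop(sprintf("rotamer library parse error at line %d: fewer than 9 fields",
                 recs[bad[1]]))
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f[-1])))
  badnum <- which(vapply(num, function(x) anyNA(x[1:8]), logical(1)))
  if (length(badnum))
    stop(sprintf("rotamer library parse error at line %d: non-numeric field",
                 recs[badnum[1]]))
  df <- data.frame(
    resname = toupper(vapply(fields, `[[`, "", 1)),
    phi = vapply(num, `[[`, 0, 1),
    psi = vapply(num, `[[`, 0, 2),
    count = vapply(num, `[[`, 0, 3),
    r1 = vapply(num, `[[`, 0, 4), r2 = vapply(num, `[[`, 0, 5),
    r3 = vapply(num, `[[`, 0, 6), r4 = vapply(num, `[[`, 0, 7),
    prob = vapply(num, `[[`, 0, 8))
  chi <- t(vapply(num, function(x) {
    out <- rep(NA_real_, 4)
    if (length(x) >= 9) out[seq_len(min(4, length(x) - 8))] <-
        x[9:min(12, length(x))]
    out
  }, numeric(4)))
  df$chi1 <- chi[, 1]; df$chi2 <- chi[, 2]
  df$chi3 <- chi[, 3]; df$chi4 <- chi[, 4]
  if (any(df$prob < 0 | df$prob > 1))
    stop("rotamer library: probability outside [0, 1]")
  phis <- sort(unique(df$phi))
  width <- if (length(phis) > 1) min(diff(phis)) else 10
  # per-bin maximum probability, precomputed
  bin <- paste(df$resname, df$phi, df$psi)
  df$p_max <- stats::ave(df$prob, bin, FUN = max)
  structure(list(records = df, bin_width = width),
            class = "rotamer_library")
}

# nearest existing bin value by wrapped angular distance; exact
# half-bin ties round away from zero (toward the larger-magnitude bin)
.nearest_bin <- function(x, values) {
  values <- sort(unique(values))
  d <- abs((x - values + 180) %% 360 - 180)
  cand <- values[d == min(d)]
  cand[which.max(abs(cand))]
}

#' Look up rotamer probability at a backbone geometry
#'
#' Maps (phi, psi) to the nearest library bin.  When `chi` angles are
#' given, the record with the smallest wrapped chi distance is chosen;
#' otherwise the most probable rotamer of the bin is returned.
#'
#' @param lib a `rotamer_library`.
#' @param resname residue name (e.g. `"ARG"`).
#' @param phi,psi backbone dihedrals in degrees.
#' @param chi numeric vector of observed chi angles (degrees), optional.
#' @return list with `p`, `p_max` and the matched record row.
#' @export
lookup_rotamer <- function(lib, resname, phi, psi, chi = NULL) {
  df <- lib$records[lib$records$resname == toupper(resname), , drop = FALSE]
  if (nrow(df) == 0)
    stop(sprintf("rotamer library has no bin for %s at (%g, %g)",
                 resname, phi, psi))
  bphi <- .nearest_bin(phi, df$phi)
  sub <- df[df$phi == bphi, , drop = FALSE]
  bpsi <- .nearest_bin(psi, sub$psi)
  rows <- sub[sub$psi == bpsi, , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("rotamer library has no bin for %s at (%g, %g)",
                 resname, bphi, bpsi))
  if (is.null(chi)) {
    i <- which.max(rows$prob)
  } else {
    wrap <- function(d) abs((d + 180) %% 360 - 180)
    dsum <- rep(0, nrow(rows))
    for (k in seq_along(chi)) {
      cm <- rows[[paste0("chi", k)]]
      if (all(is.na(cm))) break
      dsum <- dsum + wrap(chi[k] - cm)
    }
    i <- which.min(dsum)
  }
  list(p = rows$prob[i], p_max = rows$p_max[i], record = rows[i, ])
}

#' Rotamer pseudo-energy from a probability ratio
#'
#' `E = -RT ln(p / p_max)`, non-negative, zero iff the conformation is
#' the most probable rotamer of its backbone bin.
#'
#' @param p rotamer probability; `p_max` the bin's maximum probability.
#' @param temperature Kelvin (default 300).
#' @param p_floor probabilities of exactly zero are clamped here (with a
#'   warning) so the energy stays finite.
#' @return energy in kcal/mol.
#' @export
rotamer_energy <- function(p, p_max, temperature = 300, p_floor = 1e-6) {
  if (temperature <= 0) stop("rotamer_energy: temperature must be positive")
  if (p > p_max) stop("rotamer_energy: p exceeds p_max")
  if (p == 0) {
    warning(sprintf("rotamer_energy: p = 0 clamped to %g", p_floor))
    p <- p_floor
  }
  -GAS_CONSTANT_KCAL * temperature * log(p / p_max)
}

#' Pair rotamer energy under the independence assumption
#'
#' Probabilities of the two residues are multiplied before applying the
#' energy formula, which makes the pair energy exactly the sum of the
#' two single-residue energies.
#'
#' @param lookup1,lookup2 lists with `p` and `p_max` (e.g. from
#'   [lookup_rotamer()]).
#' @param temperature Kelvin.
#' @return energy in kcal/mol.
#' @export
pair_rotamer_energy <- function(lookup1, lookup2, temperature = 300) {
  rotamer_energy(lookup1$p * lookup2$p, lookup1$p_max * lookup2$p_max,
                 temperature)
}

# standard chi dihedral atom definitions (heavy atoms)
.chi_atoms <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

#' Chi angles of a residue from its coordinates
#'
#' @param sys `mol_system`; `reskey` the residue.
#' @return numeric vector of chi angles (degrees); length 0 for
#'   Gly/Ala (no rotamers).
#' @export
residue_chi_angles <- function(sys, reskey) {
  a <- sys$atoms[sys$atoms$reskey == reskey, , drop = FALSE]
  defs <- .chi_atoms[[a$resname[1]]]
  if (is.null(defs)) {
    if (a$resname[1] %in% c("GLY", "ALA"))
      stop(sprintf("residue %s (%s) has no side-chain rotamers",
                   reskey, a$resname[1]))
    stop(sprintf("no chi definition for residue type %s", a$resname[1]))
  }
  vapply(defs, function(nm) {
    i <- match(nm, a$name)
    if (anyNA(i)) stop(sprintf("residue %s missing atom(s) %s for chi",
                               reskey, paste(nm[is.na(i)], collapse = ",")))
    dihedral_deg(as.numeric(a[i[1], c("x", "y", "z")]),
                 as.numeric(a[i[2], c("x", "y", "z")]),
                 as.numeric(a[i[3], c("x", "y", "z")]),
                 as.numeric(a[i[4], c("x", "y", "z")]))
  }, numeric(1))
}
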
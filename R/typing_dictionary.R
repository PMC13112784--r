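#' SYBYL typing dictionary
#'
#' Maps (residue name, PDB atom name) pairs to a SYBYL atom type and a
#' template partial charge, and carries per-residue covalent bond
#' templates.  Covers the 20 canonical amino acids, the disulfide
#' cysteine variant (CYX) and water (HOH/WAT).  Hydrogen names are
#' generated from heavy-atom attachment following either the pdb2pqr or
#' the GROMACS ff99SB-ildn naming convention, selectable via `dialect`.
#'
#' Partial charges are an internally consistent Gasteiger-like template
#' set; the only charge-sensitive rule predicate is the dipole gap gate
#' (|dq| >= 0.2), which carbonyl, carboxylate and amide groups clear by a
#' wide margin under any published Gasteiger set.
#'
#' @name typing_dictionary
NULL

# heavy side-chain atoms: name, sybyl, charge, n hydrogens
.sidechain_def <- list(
  ALA = "CB C.3 -0.060 3",
  ARG = c("CB C.3 -0.030 2", "CG C.3 -0.020 2", "CD C.3 0.060 2",
          "NE N.pl3 -0.280 1", "CZ C.cat 0.350 0",
          "NH1 N.pl3 -0.320 2", "NH2 N.pl3 -0.320 2"),
  ASN = c("CB C.3 -0.040 2", "CG C.2 0.280 0", "OD1 O.2 -0.270 0",
          "ND2 N.am -0.340 2"),
  ASP = c("CB C.3 -0.040 2", "CG C.2 0.300 0", "OD1 O.co2 -0.450 0",
          "OD2 O.co2 -0.450 0"),
  CYS = c("CB C.3 -0.020 2", "SG S.3 -0.120 1"),
  CYX = c("CB C.3 -0.020 2", "SG S.3 -0.050 0"),
  GLN = c("CB C.3 -0.040 2", "CG C.3 -0.030 2", "CD C.2 0.280 0",
          "OE1 O.2 -0.270 0", "NE2 N.am -0.340 2"),
  GLU = c("CB C.3 -0.040 2", "CG C.3 -0.030 2", "CD C.2 0.300 0",
          "OE1 O.co2 -0.450 0", "OE2 O.co2 -0.450 0"),
  GLY = character(0),
  HIS = c("CB C.3 -0.030 2", "CG C.ar 0.020 0", "ND1 N.ar -0.250 1",
          "CD2 C.ar 0.060 1", "CE1 C.ar 0.120 1", "NE2 N.ar -0.250 1"),
  ILE = c("CB C.3 -0.020 1", "CG1 C.3 -0.030 2", "CG2 C.3 -0.050 3",
          "CD1 C.3 -0.060 3"),
  LEU = c("CB C.3 -0.030 2", "CG C.3 -0.020 1", "CD1 C.3 -0.060 3",
          "CD2 C.3 -0.060 3"),
  LYS = c("CB C.3 -0.030 2", "CG C.3 -0.030 2", "CD C.3 -0.020 2",
          "CE C.3 0.080 2", "NZ N.4 -0.300 3"),
  MET = c("CB C.3 -0.030 2", "CG C.3 0.010 2", "SD S.3 -0.150 0",
          "CE C.3 0.020 3"),
  PHE = c("CB C.3 -0.030 2", "CG C.ar 0.010 0", "CD1 C.ar 0.000 1",
          "CD2 C.ar 0.000 1", "CE1 C.ar 0.000 1", "CE2 C.ar 0.000 1",
          "CZ C.ar 0.000 1"),
  PRO = c("CB C.3 -0.030 2", "CG C.3 -0.030 2", "CD C.3 0.030 2"),
  SER = c("CB C.3 0.040 2", "OG O.3 -0.390 1"),
  THR = c("CB C.3 0.070 1", "OG1 O.3 -0.390 1", "CG2 C.3 -0.050 3"),
  TRP = c("CB C.3 -0.030 2", "CG C.ar 0.000 0", "CD1 C.ar 0.060 1",
          "CD2 C.ar 0.000 0", "NE1 N.ar -0.300 1", "CE2 C.ar 0.080 0",
          "CE3 C.ar 0.000 1", "CZ2 C.ar 0.000 1", "CZ3 C.ar 0.000 1",
          "CH2 C.ar 0.000 1"),
  TYR = c("CB C.3 -0.030 2", "CG C.ar 0.010 0", "CD1 C.ar 0.000 1",
          "CD2 C.ar 0.000 1", "CE1 C.ar 0.000 1", "CE2 C.ar 0.000 1",
          "CZ C.ar 0.090 0", "OH O.3 -0.360 1"),
  VAL = c("CB C.3 -0.020 1", "CG1 C.3 -0.050 3", "CG2 C.3 -0.050 3")
)

.sidechain_bonds <- list(
  ALA = character(0),
  ARG = c("CB CG 1", "CG CD 1", "CD NE 1", "NE CZ ar", "CZ NH1 ar",
          "CZ NH2 ar"),
  ASN = c("CB CG 1", "CG OD1 2", "CG ND2 am"),
  ASP = c("CB CG 1", "CG OD1 ar", "CG OD2 ar"),
  CYS = "CB SG 1",
  CYX = "CB SG 1",
  GLN = c("CB CG 1", "CG CD 1", "CD OE1 2", "CD NE2 am"),
  GLU = c("CB CG 1", "CG CD 1", "CD OE1 ar", "CD OE2 ar"),
  GLY = character(0),
  HIS = c("CB CG 1", "CG ND1 ar", "CG CD2 ar", "ND1 CE1 ar",
          "CD2 NE2 ar", "CE1 NE2 ar"),
  ILE = c("CB CG1 1", "CB CG2 1", "CG1 CD1 1"),
  LEU = c("CB CG 1", "CG CD1 1", "CG CD2 1"),
  LYS = c("CB CG 1", "CG CD 1", "CD CE 1", "CE NZ 1"),
  MET = c("CB CG 1", "CG SD 1", "SD CE 1"),
  PHE = c("CB CG 1", "CG CD1 ar", "CG CD2 ar", "CD1 CE1 ar",
          "CD2 CE2 ar", "CE1 CZ ar", "CE2 CZ ar"),
  PRO = c("CB CG 1", "CG CD 1", "CD N 1"),
  SER = "CB OG 1",
  THR = c("CB OG1 1", "CB CG2 1"),
  TRP = c("CB CG 1", "CG CD1 ar", "CG CD2 ar", "CD1 NE1 ar",
          "NE1 CE2 ar", "CD2 CE2 ar", "CD2 CE3 ar", "CE3 CZ3 ar",
          "CZ3 CH2 ar", "CH2 CZ2 ar", "CZ2 CE2 ar"),
  TYR = c("CB CG 1", "CG CD1 ar", "CG CD2 ar", "CD1 CE1 ar",
          "CD2 CE2 ar", "CE1 CZ ar", "CE2 CZ ar", "CZ OH 1"),
  VAL = c("CB CG1 1", "CB CG2 1")
)

# aromatic-ring atom-name templates per residue
.ring_templates <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

.h_charge <- c(C = 0.030, N = 0.180, O = 0.210, S = 0.100)

.parse_def <- function(lines) {
  if (length(lines) == 0)
    return(data.frame(atom = character(0), sybyl = character(0),
                      charge = numeric(0), nh = integer(0)))
  f <- do.call(rbind, strsplit(lines, " +"))
  data.frame(atom = f[, 1], sybyl = f[, 2],
             charge = as.numeric(f[, 3]), nh = as.integer(f[, 4]))
}

# hydrogen names for nh hydrogens attached to heavy atom `atom` of
# element `elem`, under the given naming dialect
.h_names <- function(atom, elem, nh, dialect) {
  if (nh == 0) return(character(0))
  suffix <- substring(atom, 2)
  if (atom == "N" && elem == "N") return("H")
  if (nh == 1) return(paste0("H", suffix))
  if (nh == 3) return(paste0("H", suffix, 1:3))
  # nh == 2: N-attached pairs are numbered 1/2 in both conventions;
  # C-attached pairs are 2/3 under pdb2pqr and 1/2 under GROMACS
  if (elem == "N") return(paste0("H", suffix, 1:2))
  if (dialect == "pdb2pqr") paste0("H", suffix, 2:3) else paste0("H", suffix, 1:2)
}

#' Build the default typing dictionary
#'
#' @param dialect hydrogen-naming convention: `"pdb2pqr"` (default) or
#'   `"gmx"` (GROMACS ff99SB-ildn via pdb2gmx).
#' @return object of class `typing_dictionary` with elements `entries`
#'   (resname, atom, element, sybyl, charge), `bonds` (resname, a, b,
#'   type; includes X-H bonds), `ring_templates` and `dialect`.
#' @export
default_typing_dictionary <- function(dialect = c("pdb2pqr", "gmx")) {
  dialect <- match.arg(dialect)
  entries <- list(); bonds <- list()
  backbone <- .parse_def(c("N N.am -0.350 1", "CA C.3 0.080 1",
                           "C C.2 0.320 0", "O O.2 -0.280 0"))
  for (res in names(.sidechain_def)) {
    bb <- backbone
    if (res == "GLY") bb$nh[bb$atom == "CA"] <- 2L
    if (res == "PRO") bb$nh[bb$atom == "N"] <- 0L
    side <- .parse_def(.sidechain_def[[res]])
    heavy <- rbind(bb, side)
    heavy$element <- substring(heavy$atom, 1, 1)
    bnd <- c("N CA 1", "CA C 1", "C O 2",
             if (nrow(side) > 0) "CA CB 1",
             .sidechain_bonds[[res]])
    for (i in seq_len(nrow(heavy))) {
      hn <- .h_names(heavy$atom[i], heavy$element[i], heavy$nh[i], dialect)
      for (h in hn) {
        heavy <- rbind(heavy, data.frame(
          atom = h, sybyl = "H",
          charge = unname(.h_charge[heavy$element[i]]),
          nh = 0L, element = "H"))
        bnd <- c(bnd, paste(heavy$atom[i], h, "1"))
      }
    }
    heavy$resname <- res
    entries[[res]] <- heavy[, c("resname", "atom", "element", "sybyl", "charge")]
    bf <- do.call(rbind, strsplit(bnd, " +"))
    bonds[[res]] <- data.frame(resname = res, a = bf[, 1], b = bf[, 2],
                               type = bf[, 3])
  }
  # water: one oxygen, two hydrogens
  for (wres in c("HOH", "WAT")) {
    entries[[wres]] <- data.frame(
      resname = wres, atom = c("O", "H1", "H2"), element = c("O", "H", "H"),
      sybyl = c("O.3", "H", "H"), charge = c(-0.410, 0.205, 0.205))
    bonds[[wres]] <- data.frame(resname = wres, a = c("O", "O"),
                                b = c("H1", "H2"), type = c("1", "1"))
  }
  dict <- list(entries = do.call(rbind, entries),
               bonds = do.call(rbind, bonds),
               ring_templates = .ring_templates,
               dialect = dialect)
  rownames(dict$entries) <- NULL
  rownames(dict$bonds) <- NULL
  class(dict) <- "typing_dictionary"
  dict
}

#' Look up one dictionary entry
#'
#' @param dict a `typing_dictionary`.
#' @param resname 3-letter residue name.
#' @param atom PDB atom name.
#' @return one-row data frame, or `NULL` when the pair is unknown.
#' @export
dictionary_lookup <- function(dict, resname, atom) {
  hit <- dict$entries[dict$entries$resname == resname &
                      dict$entries$atom == atom, , drop = FALSE]
  if (nrow(hit) == 0) NULL else hit[1, ]
}

#' Write a typing dictionary to its structured text format
#'
#' One `ATOM res name sybyl charge` line per entry and one
#' `BOND res a b type` line per template bond.
#'
#' @param dict a `typing_dictionary`.
#' @param path output file path.
#' @export
write_typing_dictionary <- function(dict, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# typing dictionary, dialect:", dict$dialect), con)
  writeLines(sprintf("ATOM %s %s %s %.4f", dict$entries$resname,
                     dict$entries$atom, dict$entries$sybyl,
                     dict$entries$charge), con)
  writeLines(sprintf("BOND %s %s %s %s", dict$bonds$resname,
                     dict$bonds$a, dict$bonds$b, dict$bonds$type), con)
  invisible(path)
}

#' Read a typing dictionary from its structured text format
#'
#' @param path file written by [write_typing_dictionary()].
#' @return a `typing_dictionary` (ring templates are the built-in ones).
#' @export
read_typing_dictionary <- function(path) {
  lines <- readLines(path)
  dialect <- "pdb2pqr"
  dl <- grep("^# typing dictionary, dialect:", lines, value = TRUE)
  if (length(dl)) dialect <- trimws(sub(".*dialect:", "", dl[1]))
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), " +")
  bad <- which(vapply(fields, function(f)
    !(f[1] %in% c("ATOM", "BOND")) || length(f) != 5, logical(1)))
  if (length(bad))
    stop(sprintf("typing dictionary: malformed record '%s'", lines[bad[1]]))
  m <- do.call(rbind, fields)
  at <- m[m[, 1] == "ATOM", , drop = FALSE]
  bd <- m[m[, 1] == "BOND", , drop = FALSE]
  dict <- list(
    entries = data.frame(resname = at[, 2], atom = at[, 3],
                         element = ifelse(at[, 4] == "H", "H",
                                          substring(at[, 3], 1, 1)),
                         sybyl = at[, 4], charge = as.numeric(at[, 5])),
    bonds = data.frame(resname = bd[, 2], a = bd[, 3], b = bd[, 4],
                       type = bd[, 5]),
    ring_templates = .ring_templates,
    dialect = dialect)
  class(dict) <- "typing_dictionary"
  dict
}
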
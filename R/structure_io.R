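#' Molecular system container
#'
#' A `mol_system` holds a protein complex as three data frames:
#' `atoms` (serial, name, element, sybyl, x, y, z, charge, chain, resno,
#' icode, resname, reskey, is_water), `bonds` (a, b, type: serials plus a
#' SYBYL bond type in 1/2/3/am/ar) and `residues` (one row per residue,
#' with the partner class once assigned).  Residue identity is
#' (chain, resseq, icode); no renumbering is ever performed.
#'
#' @name mol_system
NULL

res_key <- function(chain, resno, icode) {
  ic <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, ic)
}

.water_names <- c("HOH", "WAT")

#' Construct a molecular system from atom and bond tables
#'
#' @param atoms data frame with at least name, element, x, y, z, chain,
#'   resno, resname; optional sybyl, charge, icode, serial.
#' @param bonds data frame with columns a, b (atom serials) and type, or
#'   `NULL` for an unbonded (untyped-stage) system.
#' @param validate run structural validation.
#' @return object of class `mol_system`.
#' @export
mol_system <- function(atoms, bonds = NULL, validate = TRUE) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  if (is.null(atoms$sybyl)) atoms$sybyl <- NA_character_
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  atoms$reskey <- res_key(atoms$chain, atoms$resno, atoms$icode)
  atoms$is_water <- atoms$resname %in% .water_names
  if (is.null(bonds))
    bonds <- data.frame(a = integer(0), b = integer(0), type = character(0))
  residues <- unique(atoms[, c("reskey", "chain", "resno", "icode",
                               "resname", "is_water")])
  residues$class <- NA_character_
  rownames(residues) <- NULL
  sys <- structure(list(atoms = atoms, bonds = bonds, residues = residues),
                   class = "mol_system")
  if (validate) validate_system(sys)
  sys
}

#' Validate a molecular system
#'
#' Checks finite coordinates, bond referential integrity, absence of
#' self-bonds, element/SYBYL consistency, single-bonded hydrogens and
#' single-oxygen waters.  Typed-only checks are skipped while `sybyl`
#' is still absent.
#'
#' @param sys a `mol_system`.
#' @return `sys`, invisibly.
#' @export
validate_system <- function(sys) {
  a <- sys$atoms
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("system validation: non-finite coordinates")
  if (anyDuplicated(a$serial)) stop("system validation: duplicate serials")
  b <- sys$bonds
  if (nrow(b) > 0) {
    if (any(b$a == b$b)) stop("system validation: self-bond")
    if (!all(c(b$a, b$b) %in% a$serial))
      stop("system validation: bond references missing atom")
  }
  typed <- !anyNA(a$sybyl)
  if (typed) {
    lead <- sub("\\..*$", "", a$sybyl)
    if (!all(lead == a$element))
      stop("system validation: SYBYL type does not match element")
    if (nrow(b) > 0) {
      deg <- table(factor(c(b$a, b$b), levels = a$serial))
      nh <- deg[as.character(a$serial[a$element == "H"])]
      if (length(nh) && !all(nh == 1))
        stop("system validation: hydrogen without exactly one covalent bond")
    }
  }
  for (k in unique(a$reskey[a$is_water])) {
    w <- a[a$reskey == k, ]
    if (sum(w$element == "O") != 1)
      stop(sprintf("system validation: water %s does not have exactly one O", k))
  }
  invisible(sys)
}

.element_from_name <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- trimws(elesy)
    ok <- !is.na(e) & nzchar(e)
    out <- ifelse(ok, paste0(toupper(substring(e, 1, 1)),
                             tolower(substring(e, 2))), NA)
  } else out <- rep(NA_character_, length(name))
  miss <- is.na(out)
  nm <- sub("^[0-9]+", "", trimws(name[miss]))
  out[miss] <- ifelse(grepl("^H", nm), "H", substring(nm, 1, 1))
  out
}

#' Read a PDB file into an untyped molecular system
#'
#' Parsing is delegated to [bio3d::read.pdb()].  Records with an
#' alternate-location indicator other than blank or `'A'` are dropped; a
#' residue left without atoms by that policy is an error.  HOH/WAT
#' residues are flagged as water.
#'
#' @param path PDB file.
#' @return untyped `mol_system` (no SYBYL types, charges or bonds yet).
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop(sprintf("PDB format error in '%s': %s",
                                     path, conditionMessage(e))))
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  keep <- at$alt %in% c("", " ", "A")
  all_keys <- unique(res_key(at$chain, at$resno, at$insert))
  at <- at[keep, , drop = FALSE]
  kept_keys <- unique(res_key(at$chain, at$resno, at$insert))
  lost <- setdiff(all_keys, kept_keys)
  if (length(lost))
    stop(sprintf("read_pdb: residue(s) %s have only non-'A' altLoc records",
                 paste(lost, collapse = ", ")))
  at$elena <- trimws(at$elety)
  key <- res_key(at$chain, at$resno, at$insert)
  dup <- duplicated(paste(key, at$elena))
  if (any(dup))
    stop(sprintf("read_pdb: duplicate atom name %s in residue %s",
                 at$elena[dup][1], key[dup][1]))
  atoms <- data.frame(
    serial = at$eleno, name = at$elena,
    element = .element_from_name(at$elena, at$elesy),
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", trimws(at$insert)),
    resname = trimws(at$resid))
  mol_system(atoms, validate = FALSE)
}

#' Apply SYBYL typing, template charges and template bonds
#'
#' Fills each atom's SYBYL type and partial charge from the dictionary,
#' instantiates intra-residue bonds from the residue bond templates,
#' infers inter-residue peptide bonds (C-N of consecutive residues in a
#' chain, within 1.8 A) and adds declared disulfide SG-SG bonds (those
#' cysteines are typed with the disulfide CYX variant).
#'
#' @param sys untyped `mol_system`.
#' @param dict a `typing_dictionary`.
#' @param disulfides list of length-2 character vectors of residue keys
#'   (`"chain:resno"`) forming S-S bridges.
#' @param hydrogen_fallback match unknown hydrogen names to their nearest
#'   heavy atom (within 1.3 A) instead of erroring.  Off by default.
#' @return typed `mol_system`.
#' @export
apply_typing <- function(sys, dict = default_typing_dictionary(),
                         disulfides = NULL, hydrogen_fallback = FALSE) {
  a <- sys$atoms
  ss_keys <- unique(unlist(disulfides))
  lookup_res <- ifelse(a$resname == "CYS" & a$reskey %in% ss_keys,
                       "CYX", a$resname)
  idx <- match(paste(lookup_res, a$name),
               paste(dict$entries$resname, dict$entries$atom))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    h_miss <- miss[a$element[miss] == "H"]
    hard <- setdiff(miss, if (hydrogen_fallback) h_miss else integer(0))
    if (length(hard))
      stop(sprintf("apply_typing: unknown (residue, atom) pair(s): %s",
                   paste(unique(paste0("(", lookup_res[hard], ", ",
                                       a$name[hard], ")")), collapse = " ")))
  }
  a$sybyl <- dict$entries$sybyl[idx]
  a$charge <- dict$entries$charge[idx]
  a$element <- ifelse(is.na(idx), a$element,
                      dict$entries$element[idx])

  bonds <- list()
  xyz <- as.matrix(a[, c("x", "y", "z")])
  fallback_pairs <- NULL
  for (k in unique(a$reskey)) {
    ra <- which(a$reskey == k)
    tpl <- dict$bonds[dict$bonds$resname == lookup_res[ra[1]], , drop = FALSE]
    ia <- match(tpl$a, a$name[ra]); ib <- match(tpl$b, a$name[ra])
    ok <- !is.na(ia) & !is.na(ib)
    if (any(ok))
      bonds[[k]] <- data.frame(a = a$serial[ra][ia[ok]],
                               b = a$serial[ra][ib[ok]], type = tpl$type[ok])
    # fallback-typed hydrogens: bond to nearest heavy atom in residue
    if (hydrogen_fallback) {
      hf <- ra[is.na(idx[ra]) & a$element[ra] == "H"]
      for (h in hf) {
        heavies <- ra[a$element[ra] != "H"]
        d <- sqrt(colSums((t(xyz[heavies, , drop = FALSE]) - xyz[h, ])^2))
        j <- heavies[which.min(d)]
        if (min(d) > 1.3)
          stop(sprintf("apply_typing: hydrogen %s in %s has no heavy atom within 1.3 A",
                       a$name[h], k))
        a$sybyl[h] <- "H"
        a$charge[h] <- unname(.h_charge[a$element[j]])
        fallback_pairs <- rbind(fallback_pairs,
                                data.frame(a = a$serial[j], b = a$serial[h],
                                           type = "1"))
      }
    }
  }
  bonds <- do.call(rbind, c(bonds, list(fallback_pairs)))

  # peptide bonds between consecutive residues of a chain (file order)
  resdf <- sys$residues[!sys$residues$is_water, , drop = FALSE]
  pep <- NULL
  for (ch in unique(resdf$chain)) {
    keys <- resdf$reskey[resdf$chain == ch]
    if (length(keys) < 2) next
    for (i in seq_len(length(keys) - 1)) {
      ci <- which(a$reskey == keys[i] & a$name == "C")
      ni <- which(a$reskey == keys[i + 1] & a$name == "N")
      if (length(ci) != 1 || length(ni) != 1) {
        warning(sprintf("apply_typing: missing backbone atom between %s and %s; peptide bond skipped",
                        keys[i], keys[i + 1]))
        next
      }
      if (dist3(xyz[ci, ], xyz[ni, ]) < 1.8)
        pep <- rbind(pep, data.frame(a = a$serial[ci], b = a$serial[ni],
                                     type = "am"))
    }
  }
  ssb <- NULL
  for (p in disulfides) {
    s1 <- which(a$reskey == p[1] & a$name == "SG")
    s2 <- which(a$reskey == p[2] & a$name == "SG")
    if (length(s1) != 1 || length(s2) != 1)
      stop(sprintf("apply_typing: disulfide %s-%s lacks an SG atom", p[1], p[2]))
    ssb <- rbind(ssb, data.frame(a = a$serial[s1], b = a$serial[s2],
                                 type = "1"))
  }
  out <- sys
  out$atoms <- a
  out$bonds <- rbind(bonds, pep, ssb)
  rownames(out$bonds) <- NULL
  validate_system(out)
  out
}

.subst_name <- function(resname, chain, resno, icode)
  paste0(resname, "_", chain, "_", resno, ifelse(icode == "", "", icode))

#' Write a typed system as a TRIPOS MOL2 file
#'
#' Requires a fully typed system (SYBYL types and charges on every
#' atom).  Substructure ids are 1-based per residue in file order; chain
#' and insertion code are encoded in the substructure name
#' (`RES_chain_resno[icode]`) so that reading the file back restores
#' residue identity.
#'
#' @param sys typed `mol_system`.
#' @param path output file.
#' @export
write_mol2 <- function(sys, path) {
  a <- sys$atoms
  if (anyNA(a$sybyl) || anyNA(a$charge))
    stop("write_mol2: system is not fully typed (missing SYBYL types or charges)")
  subst <- match(a$reskey, unique(a$reskey))
  mol <- list(
    atom = data.frame(
      eleno = a$serial, elena = a$name, x = a$x, y = a$y, z = a$z,
      elety = a$sybyl, resno = subst,
      resid = .subst_name(a$resname, a$chain, a$resno, a$icode),
      charge = a$charge, statbit = NA),
    bond = if (nrow(sys$bonds) > 0)
      data.frame(id = seq_len(nrow(sys$bonds)), origin = sys$bonds$a,
                 target = sys$bonds$b, type = sys$bonds$type, statbit = NA)
    else data.frame(id = integer(0), origin = integer(0),
                    target = integer(0), type = character(0), statbit = NA),
    substructure = NULL,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    info = c(nrow(a), nrow(sys$bonds), length(unique(subst)), NA, NA),
    name = "nciprofiler")
  class(mol) <- "mol2"
  bio3d::write.mol2(mol, file = path)
  invisible(path)
}

#' Read a TRIPOS MOL2 file into a typed molecular system
#'
#' Parsing is delegated to [bio3d::read.mol2()].  The charge column is
#' mandatory.  Substructure names written by [write_mol2()] restore
#' chain/resno/icode; other MOL2 files fall back to `RES123`-style
#' parsing with chain `"A"`.
#'
#' @param path MOL2 file.
#' @return typed `mol_system`.
#' @export
read_mol2 <- function(path) {
  txt <- readLines(path)
  if (!any(grepl("@<TRIPOS>ATOM", txt, fixed = TRUE)))
    stop(sprintf("MOL2 format error in '%s': missing @<TRIPOS>ATOM section", path))
  mol <- suppressWarnings(bio3d::read.mol2(path))
  at <- mol$atom
  if (is.null(at$charge) || anyNA(at$charge))
    stop(sprintf("read_mol2: '%s' lacks the mandatory charge column", path))
  rid <- as.character(at$resid)
  m <- regmatches(rid, regexec("^([A-Za-z0-9]+)_([A-Za-z0-9])_([0-9]+)([A-Za-z]?)$", rid))
  ok <- lengths(m) == 5
  resname <- ifelse(ok, vapply(m, function(x) x[2], ""), sub("[0-9]+$", "", rid))
  chain <- ifelse(ok, vapply(m, function(x) x[3], ""), "A")
  resno_s <- ifelse(ok, vapply(m, function(x) x[4], ""),
                    sub("^[A-Za-z]*", "", rid))
  icode <- ifelse(ok, vapply(m, function(x) x[5], ""), "")
  resno <- suppressWarnings(as.integer(resno_s))
  resno[is.na(resno)] <- at$resno[is.na(resno)]
  atoms <- data.frame(
    serial = at$eleno, name = at$elena,
    element = sub("\\..*$", "", at$elety),
    sybyl = at$elety, x = at$x, y = at$y, z = at$z, charge = at$charge,
    chain = chain, resno = resno, icode = icode, resname = resname)
  bonds <- if (!is.null(mol$bond) && nrow(mol$bond) > 0)
    data.frame(a = mol$bond$origin, b = mol$bond$target,
               type = as.character(mol$bond$type))
  else NULL
  mol_system(atoms, bonds)
}

#' Read a target specification config (YAML)
#'
#' The file carries a `targets:` list of residue keys
#' (`chain:resseq[:icode]`) and a `chains:` map of chain id to partner
#' class (`Ab` or `Ag`), plus an optional `default:` class.
#'
#' @param path YAML file.
#' @return list usable as the `spec` of [assign_partner_classes()].
#' @export
read_target_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$targets)) stop("target spec: missing 'targets'")
  spec$chains <- unlist(spec$chains)
  spec
}

.parse_target_key <- function(t) {
  f <- strsplit(t, ":")[[1]]
  if (length(f) < 2) stop(sprintf("bad target '%s' (want chain:resseq[:icode])", t))
  paste0(f[1], ":", f[2], if (length(f) >= 3) f[3] else "")
}

#' Assign partner classes (M / Ab / Ag / S / other)
#'
#' Waters become `S`; residues listed in `spec$targets` become `M` (one
#' for an SPM analysis, two for a DPM pair); all remaining residues take
#' the class mapped to their chain in `spec$chains` (or `spec$default`).
#'
#' @param sys `mol_system`.
#' @param spec list with `targets` (character vector of
#'   `chain:resseq[:icode]`), `chains` (named character vector chain ->
#'   `Ab`/`Ag`) and optional `default`; or a path to a YAML file.
#' @return `sys` with `residues$class` filled.
#' @export
assign_partner_classes <- function(sys, spec) {
  if (is.character(spec) && length(spec) == 1) spec <- read_target_spec(spec)
  targets <- vapply(spec$targets, .parse_target_key, "")
  if (length(targets) == 0) stop("assign_partner_classes: empty target list")
  res <- sys$residues
  missing_t <- setdiff(targets, res$reskey)
  if (length(missing_t))
    stop(sprintf("assign_partner_classes: target residue(s) %s absent from structure",
                 paste(missing_t, collapse = ", ")))
  cls <- rep(NA_character_, nrow(res))
  cls[res$is_water] <- "S"
  mapped <- spec$chains[res$chain]
  unmapped <- is.na(cls) & (is.na(mapped) | is.null(mapped))
  if (any(unmapped)) {
    if (is.null(spec$default))
      stop(sprintf("assign_partner_classes: chain(s) %s unmapped and no default class",
                   paste(unique(res$chain[unmapped]), collapse = ", ")))
    mapped[unmapped] <- spec$default
  }
  cls[is.na(cls)] <- mapped[is.na(cls)]
  cls[res$reskey %in% targets] <- "M"
  sys$residues$class <- cls
  sys
}

#' Side-chain atom indices of a residue
#'
#' @param sys `mol_system`.
#' @param reskey residue key.
#' @param include_backbone include N, CA, C, O (and their hydrogens).
#' @return integer row indices into `sys$atoms`.
#' @keywords internal
analyzed_atoms <- function(sys, reskey, include_backbone = FALSE) {
  a <- sys$atoms
  ra <- which(a$reskey == reskey)
  if (include_backbone) return(ra)
  bb_heavy <- c("N", "CA", "C", "O", "OXT")
  heavy <- ra[!(a$name[ra] %in% bb_heavy) & a$element[ra] != "H"]
  hs <- ra[a$element[ra] == "H"]
  if (length(hs) && nrow(sys$bonds)) {
    b <- sys$bonds
    parent <- function(h) {
      s <- a$serial[h]
      p <- c(b$b[b$a == s], b$a[b$b == s])
      p[1]
    }
    keep_h <- hs[vapply(hs, function(h) {
      p <- parent(h)
      !is.na(p) && p %in% a$serial[heavy]
    }, logical(1))]
  } else keep_h <- integer(0)
  sort(c(heavy, keep_h))
}
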
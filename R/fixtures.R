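#' Synthetic probe systems
#'
#' Generates minimal, fully typed systems that satisfy or violate each
#' interaction rule by construction, plus a small toy
#' antibody-antigen-water complex with a known hit multiset.  Probes use
#' idealized bond lengths (C-H 1.09, O-H 0.96, S-H 1.34, C=O 1.23 A)
#' and dictionary-style template charges; geometric margins to every
#' threshold are at least 0.05 A / 2 degrees so accept/reject decisions
#' are never boundary cases.
#'
#' @name synthetic_fixtures
NULL

.row <- function(name, sybyl, x, y, z, q, chain, resno, resname) {
  data.frame(name = name,
             element = if (sybyl == "H") "H" else sub("\\..*$", "", sybyl),
             sybyl = sybyl, x = x, y = y, z = z, charge = q,
             chain = chain, resno = resno, resname = resname)
}

# donor fragments: heavy anchor chain ending in D-H along +x, D at origin
.donor_frag <- function(elem, chain = "A", resno = 1) {
  r <- function(...) .row(..., chain = chain, resno = resno,
                          resname = switch(elem, C = "ALA", O = "SER",
                                           N = "LYS", S = "CYS"))
  switch(elem,
    C = list(atoms = rbind(r("CA", "C.3", -1.2, -0.9, 0, 0.08),
                           r("CB", "C.3", 0, 0, 0, -0.06),
                           r("HB1", "H", 1.09, 0, 0, 0.03)),
             bonds = rbind(c("CA", "CB", "1"), c("CB", "HB1", "1")),
             d = "CB", h = "HB1", hx = 1.09),
    O = list(atoms = rbind(r("CA", "C.3", -2.3, -1.0, 0, 0.08),
                           r("CB", "C.3", -1.2, -0.7, 0, 0.04),
                           r("OG", "O.3", 0, 0, 0, -0.39),
                           r("HG", "H", 0.96, 0, 0, 0.21)),
             bonds = rbind(c("CA", "CB", "1"), c("CB", "OG", "1"),
                           c("OG", "HG", "1")),
             d = "OG", h = "HG", hx = 0.96),
    N = list(atoms = rbind(r("CA", "C.3", -2.4, -1.2, 0, 0.08),
                           r("CE", "C.3", -1.3, -0.8, 0, 0.08),
                           r("NZ", "N.4", 0, 0, 0, -0.30),
                           r("HZ1", "H", 0.96, 0, 0, 0.18)),
             bonds = rbind(c("CA", "CE", "1"), c("CE", "NZ", "1"),
                           c("NZ", "HZ1", "1")),
             d = "NZ", h = "HZ1", hx = 0.96),
    S = list(atoms = rbind(r("CA", "C.3", -2.4, -1.2, 0, 0.08),
                           r("CB", "C.3", -1.33, -0.75, 0, -0.02),
                           r("SG", "S.3", 0, 0, 0, -0.12),
                           r("HG", "H", 1.34, 0, 0, 0.10)),
             bonds = rbind(c("CA", "CB", "1"), c("CB", "SG", "1"),
                           c("SG", "HG", "1")),
             d = "SG", h = "HG", hx = 1.34))
}

# acceptor fragments at heavy-atom distance `d` along +x from the donor
.acceptor_frag <- function(kind, d, chain = "B", resno = 1) {
  r <- function(...) .row(..., chain = chain, resno = resno,
                          resname = switch(kind, O2 = "GLY", O3 = "SER",
                                           N = "HIS", S = "MET"))
  switch(kind,
    O2 = list(atoms = rbind(r("O", "O.2", d, 0, 0, -0.28),
                            r("C", "C.2", d + 0.7, 1.2, 0, 0.32)),
              bonds = rbind(c("C", "O", "2")), a = "O"),
    O3 = list(atoms = rbind(r("OG", "O.3", d, 0, 0, -0.39),
                            r("CB", "C.3", d + 0.7, 1.2, 0, 0.04)),
              bonds = rbind(c("CB", "OG", "1")), a = "OG"),
    N = list(atoms = rbind(r("ND1", "N.2", d, 0, 0, -0.25),
                           r("CG", "C.2", d + 0.7, 1.2, 0, 0.06)),
             bonds = rbind(c("CG", "ND1", "1")), a = "ND1"),
    S = list(atoms = rbind(r("SD", "S.3", d, 0, 0, -0.15),
                           r("CG", "C.3", d + 0.9, 1.3, 0, 0.01),
                           r("CE", "C.3", d + 0.9, -1.3, 0, 0.02)),
             bonds = rbind(c("SD", "CG", "1"), c("SD", "CE", "1")), a = "SD"))
}

# aromatic six-ring (PHE template names) in the z = z0 plane
.ring_frag <- function(cx = 0, cy = 0, z0 = 0, chain = "B", resno = 1,
                       radius = 1.39, tilt_x_deg = 0) {
  nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  th <- seq(0, by = pi / 3, length.out = 6)
  co <- cbind(radius * cos(th), radius * sin(th), 0)
  if (tilt_x_deg != 0) {
    a <- tilt_x_deg * pi / 180
    rot <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3)
    co <- co %*% t(rot)
  }
  co <- sweep(co, 2, c(cx, cy, z0), "+")
  atoms <- do.call(rbind, lapply(seq_len(6), function(i)
    .row(nm[i], "C.ar", co[i, 1], co[i, 2], co[i, 3], 0.0, chain, resno,
         "PHE")))
  bonds <- rbind(c("CG", "CD1", "ar"), c("CD1", "CE1", "ar"),
                 c("CE1", "CZ", "ar"), c("CZ", "CE2", "ar"),
                 c("CE2", "CD2", "ar"), c("CD2", "CG", "ar"))
  list(atoms = atoms, bonds = bonds)
}

.assemble <- function(frags, targets = "A:1",
                      chains = c(A = "Ab", B = "Ab"), jitter = 0, seed = 1) {
  atoms <- do.call(rbind, lapply(frags, `[[`, "atoms"))
  rownames(atoms) <- NULL
  atoms$serial <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno)
  bonds <- do.call(rbind, lapply(frags, function(f) {
    if (is.null(f$bonds)) return(NULL)
    b <- matrix(f$bonds, ncol = 3)
    sel <- key == paste(f$atoms$chain[1], f$atoms$resno[1])
    data.frame(
      a = atoms$serial[sel][match(b[, 1], atoms$name[sel])],
      b = atoms$serial[sel][match(b[, 2], atoms$name[sel])],
      type = b[, 3])
  }))
  if (jitter > 0) {
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(3 * nrow(atoms), sd = jitter), ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  sys <- mol_system(atoms, bonds)
  assign_partner_classes(sys, list(targets = as.list(targets),
                                   chains = chains))
}

# shift a fragment rigidly
.shift <- function(frag, dx = 0, dy = 0, dz = 0) {
  frag$atoms$x <- frag$atoms$x + dx
  frag$atoms$y <- frag$atoms$y + dy
  frag$atoms$z <- frag$atoms$z + dz
  frag
}

# acceptor placed to break the D-H-A angle (88 degrees) while keeping
# every distance condition satisfied
.angle_violating_acceptor <- function(kind, hx) {
  f <- .acceptor_frag(kind, d = 0)
  u <- c(-cos(88 * pi / 180), sin(88 * pi / 180), 0)
  pos <- c(hx, 0, 0) + 2.31 * u
  ax <- f$atoms$name == f$a
  f$atoms$x <- f$atoms$x - f$atoms$x[ax][1] + pos[1]
  f$atoms$y[ax] <- pos[2]
  f$atoms$y[!ax] <- pos[2] + 1.2
  f$atoms$z <- 0
  f
}

#' Generate a single-rule probe system
#'
#' Builds a minimal two-residue (target + partner) system whose
#' geometry satisfies (`satisfy = TRUE`) or violates exactly the named
#' rule.  With `satisfy = TRUE`, [detect_interactions()] yields exactly
#' one hit carrying `label`; with `satisfy = FALSE`, zero hits of that
#' label (other labels, e.g. residual vdW contacts, may still occur).
#'
#' @param label one of the 36 registry labels.
#' @param satisfy build a satisfying (default) or violating geometry.
#' @param jitter coordinate noise sd in Angstrom (default 0:
#'   deterministic coordinates).
#' @param seed RNG seed used when `jitter > 0`.
#' @return partner-classed `mol_system` (target residue `A:1`, class M).
#' @export
make_probe <- function(label, satisfy = TRUE, jitter = 0, seed = 1) {
  registry <- default_registry()
  if (!label %in% names(registry)) stop(sprintf("unknown label '%s'", label))
  rl <- registry[[label]]
  tpl <- rl$template
  ch <- function(partner = "Ab") c(A = "Ab", B = partner)

  if (tpl %in% c("polar", "xh_y")) {
    don <- .donor_frag(rl$donor)
    hx <- don$hx
    dist <- if (tpl == "polar") {
      if (startsWith(label, "HB")) 2.85 else 3.5
    } else if (rl$donor == "C") 3.40 else if (rl$donor %in% c("O", "N")) 3.56 else {
      if (rl$acceptor == "S") 4.14 else 3.94
    }
    kind <- switch(rl$acceptor, O = if (rl$donor == "S") "O3" else "O2",
                   N = "N", S = "S")
    acc <- if (satisfy) .acceptor_frag(kind, d = dist)
           else .angle_violating_acceptor(kind, hx)
    return(.assemble(list(don, acc), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  if (tpl == "xh_pi") {
    don <- .donor_frag(rl$donor)
    hx <- don$hx
    dz <- if (rl$donor == "C") 3.80 else if (rl$donor == "S") 4.00 else 3.60
    # rotate donor to point -z: D above ring center, H below D
    don$atoms$z <- dz + don$atoms$x * -1
    don$atoms$x <- -don$atoms$y    # anchors swing out of the ring axis
    don$atoms$y <- 0.3
    dsel <- don$atoms$name == don$d; hsel <- don$atoms$name == don$h
    don$atoms[dsel, c("x", "y", "z")] <- c(0, 0, dz)
    don$atoms[hsel, c("x", "y", "z")] <- c(0, 0, dz - hx)
    ring <- .ring_frag(cx = if (satisfy) 0 else 2.5, z0 = 0)
    return(.assemble(list(don, ring), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  if (tpl == "s_pi") {
    r <- function(...) .row(..., chain = "A", resno = 1, resname = "MET")
    tgt <- list(atoms = rbind(r("CA", "C.3", -2.2, -1.6, 4.6, 0.08),
                              r("CG", "C.3", -1.2, -0.8, 4.1, 0.01),
                              r("SD", "S.3", 0, 0, 3.3, -0.15),
                              r("CE", "C.3", 1.2, -0.8, 4.1, 0.02)),
                bonds = rbind(c("CA", "CG", "1"), c("CG", "SD", "1"),
                              c("SD", "CE", "1")))
    ring <- .ring_frag(cx = if (satisfy) 0 else 2.5, z0 = 0)
    return(.assemble(list(tgt, ring), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  if (tpl == "pi_pi") {
    r <- function(...) .row(..., chain = "A", resno = 1, resname = "PHE")
    ring1 <- .ring_frag(0, 0, 0, chain = "A", resno = 1)
    anchor <- list(atoms = rbind(r("CA", "C.3", 3.7, 1.4, 0, 0.08),
                                 r("CB", "C.3", 2.6, 0.9, 0, -0.03)),
                   bonds = rbind(c("CA", "CB", "1")))
    # bond CB-CG joins the two target fragments after assembly; omitted
    ring2 <- .ring_frag(0.8, 0, 3.5, chain = "B", resno = 1,
                        tilt_x_deg = if (satisfy) 0 else 60)
    return(.assemble(list(ring1, anchor, ring2), chains = ch(),
                     jitter = jitter, seed = seed))
  }
  if (tpl == "chalcogen") {
    r <- function(...) .row(..., chain = "A", resno = 1, resname = "MET")
    tgt <- list(atoms = rbind(r("CA", "C.3", -2.3, -2.0, 0, 0.08),
                              r("CG", "C.3", -1.2, -1.2, 0, 0.01),
                              r("SD", "S.3", 0, 0, 0, -0.15),
                              r("CE", "C.3", 1.2, -1.2, 0, 0.02)),
                bonds = rbind(c("CA", "CG", "1"), c("CG", "SD", "1"),
                              c("SD", "CE", "1")))
    d0 <- if (label == "S_S") 3.5 else 3.2
    if (!satisfy) d0 <- 5.0
    p <- function(...) .row(..., chain = "B", resno = 1,
                            resname = switch(rl$acceptor, O = "GLY",
                                             N = "HIS", S = "MET"))
    par <- switch(rl$acceptor,
      O = list(atoms = rbind(p("O", "O.2", 0, d0, 0, -0.28),
                             p("C", "C.2", 0.8, d0 + 1.0, 0, 0.32)),
               bonds = rbind(c("C", "O", "2"))),
      N = list(atoms = rbind(p("ND1", "N.2", 0, d0, 0, -0.25),
                             p("CG", "C.2", 0.8, d0 + 1.0, 0, 0.06)),
               bonds = rbind(c("CG", "ND1", "1"))),
      S = list(atoms = rbind(p("SD", "S.3", 0, d0, 0, -0.15),
                             p("CG", "C.3", -1.2, d0 + 1.2, 0, 0.01),
                             p("CE", "C.3", 1.2, d0 + 1.2, 0, 0.02)),
               bonds = rbind(c("SD", "CG", "1"), c("SD", "CE", "1"))))
    return(.assemble(list(tgt, par), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  if (tpl == "omulpol") {
    r <- function(...) .row(..., chain = "A", resno = 1, resname = "ASN")
    q_cg <- if (satisfy) 0.25 else 0.10
    q_od <- if (satisfy) -0.27 else -0.05
    tgt <- list(atoms = rbind(r("CA", "C.3", -2.0, -1.9, -2.0, 0.08),
                              r("CB", "C.3", -0.9, -1.1, -1.6, 0.10),
                              r("CG", "C.2", 0, 0, -1.23, q_cg),
                              r("OD1", "O.2", 0, 0, 0, q_od)),
                bonds = rbind(c("CA", "CB", "1"), c("CB", "CG", "1"),
                              c("CG", "OD1", "2")))
    p <- function(...) .row(..., chain = "B", resno = 1, resname = "GLY")
    par <- list(atoms = rbind(p("CA", "C.3", -0.75, -1.0, 3, 0.12),
                              p("C", "C.2", 0, 0, 3, 0.28),
                              p("O", "O.2", 1.23, 0, 3, -0.27)),
                bonds = rbind(c("CA", "C", "1"), c("C", "O", "2")))
    return(.assemble(list(tgt, par), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  if (tpl == "dipo") {
    r <- function(...) .row(..., chain = "A", resno = 1, resname = "ASN")
    tgt <- list(atoms = rbind(r("CA", "C.3", -2.1, -1.3, 0, 0.08),
                              r("CB", "C.3", -1.0, -0.9, 0, 0.10),
                              r("CG", "C.2", 0, 0, 0, 0.25),
                              r("OD1", "O.2", 1.23, 0, 0, -0.27)),
                bonds = rbind(c("CA", "CB", "1"), c("CB", "CG", "1"),
                              c("CG", "OD1", "2")))
    p <- function(...) .row(..., chain = "B", resno = 1, resname = "GLY")
    o2x <- if (satisfy) 0 else 2.46   # violating: parallel, not antiparallel
    par <- list(atoms = rbind(p("CA", "C.3", 1.98, 3.95, 0, 0.12),
                              p("C", "C.2", 1.23, 3.0, 0, 0.28),
                              p("O", "O.2", o2x, 3.0, 0, -0.27)),
                bonds = rbind(c("CA", "C", "1"), c("C", "O", "2")))
    return(.assemble(list(tgt, par), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  if (tpl == "vdw") {
    r <- function(...) .row(..., chain = "A", resno = 1, resname = "ALA")
    tgt <- list(atoms = rbind(r("CA", "C.3", -1.2, -0.9, 0, 0.08),
                              r("CB", "C.3", 0, 0, 0, -0.06)),
                bonds = rbind(c("CA", "CB", "1")))
    d0 <- if (satisfy) 4.0 else 4.55
    p <- function(...) .row(..., chain = "B", resno = 1, resname = "ALA")
    par <- list(atoms = rbind(p("CB", "C.3", d0, 0, 0, -0.06),
                              p("CA", "C.3", d0 + 1.2, 0.9, 0, 0.08)),
                bonds = rbind(c("CA", "CB", "1")))
    return(.assemble(list(tgt, par), chains = ch(), jitter = jitter,
                     seed = seed))
  }
  # metals and ions
  elem <- rl$metal
  is_ion <- rl$category == "ion"
  d0 <- if (is_ion) {
    if (satisfy) 3.2 else 3.9
  } else {
    if (satisfy) 2.2 else 3.4
  }
  if (label == "Cl_A") {
    don <- .donor_frag("N")
    met <- list(atoms = .row("CL", "Cl", 3.2 + (if (satisfy) 0 else 0.7),
                             0, 0, -1.0, "B", 1, "CL"))
    return(.assemble(list(don, met), chains = ch("Ag"), jitter = jitter,
                     seed = seed))
  }
  r <- function(...) .row(..., chain = "A", resno = 1, resname = "ASP")
  tgt <- list(atoms = rbind(r("CA", "C.3", -2.4, -0.2, 0, 0.08),
                            r("CB", "C.3", -1.3, 0.2, 0, -0.04),
                            r("CG", "C.2", -1.25, 0, 0, 0.30),
                            r("OD1", "O.co2", 0, 0, 0, -0.45),
                            r("OD2", "O.co2", -1.9, -1.1, 0, -0.45)),
              bonds = rbind(c("CA", "CB", "1"), c("CB", "CG", "1"),
                            c("CG", "OD1", "ar"), c("CG", "OD2", "ar")))
  met <- list(atoms = .row(toupper(elem), elem, 0, d0, 0,
                           if (is_ion) 1.0 else 2.0, "B", 1, toupper(elem)))
  .assemble(list(tgt, met), chains = ch("Ag"), jitter = jitter, seed = seed)
}

#' Build the toy antibody-antigen-water complex
#'
#' A lysine-like target residue (`H:57`, class M) surrounded by two
#' antibody residues (a CH...O acceptor and a long-range electrostatic
#' acceptor), an antibody aromatic ring (CH...pi), an antigen hydrogen-
#' bond acceptor, one water bridging the target to a second antigen
#' residue, and one water touching only the target.  The expected
#' grouped descriptor vector is packaged alongside.
#'
#' @param seed RNG seed (used only when `jitter > 0`).
#' @param jitter coordinate noise sd in Angstrom.
#' @return list with `system` (partner-classed `mol_system`),
#'   `expected_grouped` (named counts over the 30 grouped keys),
#'   `n_hits` and `n_bridges`.
#' @export
make_toy_complex <- function(seed = 1, jitter = 0) {
  r <- function(name, sybyl, x, y, z, q, chain, resno, resname)
    .row(name, sybyl, x, y, z, q, chain, resno, resname)
  mres <- list(atoms = rbind(
    r("CA", "C.3", -1.2, -0.9, 0, 0.08, "H", 57, "LYS"),
    r("CB", "C.3", 0, 0, 0, -0.15, "H", 57, "LYS"),
    r("HB2", "H", 1.09, 0, 0, 0.03, "H", 57, "LYS"),
    r("HB3", "H", 0, 0, -1.09, 0.03, "H", 57, "LYS"),
    r("NZ", "N.4", 0, 4.0, 0, -0.30, "H", 57, "LYS"),
    r("HZ1", "H", 0, 4.96, 0, 0.18, "H", 57, "LYS"),
    r("HZ2", "H", 0.96, 4.0, 0, 0.18, "H", 57, "LYS"),
    r("HZ3", "H", -0.768, 3.424, 0, 0.18, "H", 57, "LYS")),
    bonds = rbind(c("CA", "CB", "1"), c("CB", "HB2", "1"),
                  c("CB", "HB3", "1"), c("CB", "NZ", "1"),
                  c("NZ", "HZ1", "1"), c("NZ", "HZ2", "1"),
                  c("NZ", "HZ3", "1")))
  ab_cho <- list(atoms = rbind(      # CH...O acceptor (M -> Ab)
    r("O", "O.2", 3.40, 0, 0, -0.28, "A", 10, "GLY"),
    r("C", "C.2", 4.30, 1.2, 0, 0.32, "A", 10, "GLY")),
    bonds = rbind(c("C", "O", "2")))
  ab_ele <- list(atoms = rbind(      # electrostatic acceptor (M -> Ab)
    r("O", "O.2", 3.5, 4.0, 0, -0.28, "A", 11, "GLY"),
    r("C", "C.2", 4.2, 5.2, 0, 0.32, "A", 11, "GLY")),
    bonds = rbind(c("C", "O", "2")))
  # ring center slightly off the CB-HB3 axis so one ring atom is
  # strictly the nearest qualifying acceptor (no ties under rotation)
  ab_ring <- .ring_frag(0.25, 0, -3.80, chain = "A", resno = 12)  # CH...pi
  ag_hb <- list(atoms = rbind(       # hydrogen-bond acceptor (M -> Ag)
    r("O", "O.2", -2.28, 2.29, 0, -0.28, "B", 6, "GLY"),
    r("C", "C.2", -4.5, 0.8, 0, 0.32, "B", 6, "GLY")),
    bonds = rbind(c("C", "O", "2")))
  ag_w <- list(atoms = rbind(        # water-bridged acceptor (S -> Ag)
    r("O", "O.2", 2.015, 8.865, 0, -0.28, "B", 5, "GLY"),
    r("C", "C.2", 3.4, 9.6, 0, 0.32, "B", 5, "GLY")),
    bonds = rbind(c("C", "O", "2")))
  w1 <- list(atoms = rbind(          # bridging water
    r("O", "O.3", 0, 6.85, 0, -0.41, "W", 301, "HOH"),
    r("H1", "H", 0.679, 7.529, 0, 0.205, "W", 301, "HOH"),
    r("H2", "H", 0.5, 7.6, -0.3, 0.205, "W", 301, "HOH")),
    bonds = rbind(c("O", "H1", "1"), c("O", "H2", "1")))
  w2 <- list(atoms = rbind(          # vdW-only water (M leg only)
    r("O", "O.3", 0, 0, 4.2, -0.41, "W", 302, "HOH"),
    r("H1", "H", 0.7, 0.66, 4.5, 0.205, "W", 302, "HOH"),
    r("H2", "H", -0.7, 0.66, 4.5, 0.205, "W", 302, "HOH")),
    bonds = rbind(c("O", "H1", "1"), c("O", "H2", "1")))
  sys <- .assemble(list(mres, ab_cho, ab_ele, ab_ring, ag_hb, ag_w, w1, w2),
                   targets = "H:57", chains = c(H = "Ab", A = "Ab", B = "Ag"),
                   jitter = jitter, seed = seed)
  expected <- stats::setNames(integer(30), descriptor_keys("grouped"))
  expected["M#HB_NH_O#"] <- 1L   # NZ-HZ3 to the B:6 carbonyl oxygen
  expected["M#Ele_NH_O#"] <- 1L  # NZ-HZ2 to A:11 at 3.5 A
  expected["M#CH_O#"] <- 1L      # CB-HB2 to the A:10 carbonyl oxygen
  expected["M#CH_PI#"] <- 1L     # CB-HB3 into the A:12 ring
  expected["M#vdW#"] <- 6L       # 5 residual ring contacts + CB...B:6 O
  expected["M##S"] <- 2L         # HB to W301 + vdW contact with W302
  expected["M##S##"] <- 1L       # H:57 - W301 - B:5 bridge
  list(system = sys, expected_grouped = expected,
       n_hits = 12L, n_bridges = 1L)
}

#' Synthetic descriptor classification task
#'
#' Generates a descriptor table with two Gaussian count profiles: the
#' two classes differ by `shift` standard deviations on
#' `n_informative` features, making the task separable by construction;
#' the remaining features are uninformative noise.  Rows are assigned
#' to clusters at random (balanced), emulating the CDR-cluster grouping
#' of real descriptor tables.
#'
#' @param n rows (structures); `n_features` descriptor columns;
#'   `n_informative` class-separated columns; `shift` class mean
#'   separation in sd units; `n_clusters` group count; `seed` RNG seed.
#' @return list with `x` (n x n_features count matrix), `y` (0/1
#'   labels) and `groups` (cluster ids).
#' @export
make_synthetic_descriptor_task <- function(n = 400, n_features = 30,
                                           n_informative = 3, shift = 4,
                                           n_clusters = 20, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    x <- matrix(stats::rnorm(n * n_features, mean = 5, sd = 1.5),
                n, n_features)
    for (j in seq_len(n_informative))
      x[y == 1, j] <- x[y == 1, j] + shift * 1.5
    x <- round(pmax(x, 0))   # descriptor vectors are non-negative counts
    colnames(x) <- paste0("d", seq_len(n_features))
    groups <- sample(rep(seq_len(n_clusters), length.out = n))
    list(x = x, y = y, groups = groups)
  })
}

#' Apply a rigid motion to a system
#'
#' Rotates (about the origin) and translates every atom; used by the
#' invariance property tests.
#'
#' @param sys `mol_system`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed system.
#' @export
transform_system <- function(sys, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(sys$atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  sys$atoms$x <- xyz[, 1]; sys$atoms$y <- xyz[, 2]; sys$atoms$z <- xyz[, 3]
  sys
}

#' Random rotation matrix
#'
#' @param seed RNG seed.
#' @return 3x3 rotation matrix (determinant +1).
#' @export
random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
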
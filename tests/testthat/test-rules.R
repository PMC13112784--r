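# direct system builder for evaluator-level tests
mini_system <- function(atoms, bonds = NULL) {
  atoms$chain <- atoms$chain %||% "A"
  mol_system(atoms, bonds)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("registry holds exactly the 36 labels in their categories", {
  reg <- default_registry()
  expect_length(reg, 36)
  expect_false(anyDuplicated(names(reg)) > 0)
  cat <- vapply(reg, `[[`, "", "category")
  expect_equal(sum(cat == "metal"), 5)
  expect_equal(sum(cat == "ion"), 3)
  expect_length(direct_labels(reg), 28)
  expect_setequal(direct_labels(reg), c(
    "HB_OH_O", "HB_NH_O", "HB_OH_N", "HB_NH_N",
    "Ele_OH_O", "Ele_NH_O", "Ele_OH_N", "Ele_NH_N",
    "PI_PI", "CH_PI", "NH_PI", "S_PI",
    "CH_O", "CH_N", "CH_S", "OH_S", "NH_S", "SH_O", "SH_N", "SH_S",
    "OH_PI", "SH_PI", "S_O", "S_N", "S_S", "OMulPol", "Dipo", "vdW"))
  expect_setequal(names(reg)[cat == "metal"],
                  c("Fe_A", "Zn_A", "Ca_A", "Mg_A", "Ni_A"))
  expect_setequal(names(reg)[cat == "ion"], c("Na_A", "K_A", "Cl_A"))
  expect_setequal(default_priority(), names(reg))
})

test_that("CH...O predicate reproduces the worked seven-condition case", {
  atoms <- data.frame(
    name = c("CB", "HB1", "CA", "O", "C"),
    element = c("C", "H", "C", "O", "C"),
    sybyl = c("C.3", "H", "C.3", "O.2", "C.2"),
    x = c(0, 1.09, -0.51, 3.40, 4.0),
    y = c(0, 0, 1.31, 0, 1.2), z = 0,
    charge = c(-0.06, 0.03, 0.08, -0.28, 0.32),
    chain = c("A", "A", "A", "B", "B"), resno = 1,
    resname = c("ALA", "ALA", "ALA", "GLY", "GLY"))
  sys <- mol_system(atoms, data.frame(a = c(1, 1, 4), b = c(2, 3, 5),
                                      type = c("1", "1", "2")))
  adj <- nciprofiler:::adjacency(sys)
  params <- default_rule_params(); radii <- default_vdw_radii()
  pr <- evaluate_xh_y(sys, adj, 1, 2, 4, params, radii)
  expect_false(is.null(pr))
  expect_equal(pr$d_DA, 3.40)
  expect_equal(pr$d_HA, 2.31)
  expect_equal(pr$gate, 1.70 + 1.52 + 1.0)

  # acceptor at 90 degrees from the D-H axis: angle < 94.58 rejects
  sys90 <- sys
  sys90$atoms[4, c("x", "y")] <- c(1.09, 2.31)
  expect_null(evaluate_xh_y(sys90, nciprofiler:::adjacency(sys90),
                            1, 2, 4, params, radii))
  # H...A beyond the 3.22 A cap rejects even inside the vdW gate
  sys_far <- sys
  sys_far$atoms[4, "x"] <- 1.09 + 3.30
  expect_null(evaluate_xh_y(sys_far, nciprofiler:::adjacency(sys_far),
                            1, 2, 4, params, radii))
})

test_that("CH...pi predicate: axial approach, scaled-radius gate, OR branch", {
  hexring <- function() {
    th <- seq(0, by = pi / 3, length.out = 6)
    list(cn = c(0, 0, 0), normal = c(0, 0, 1),
         coords = cbind(1.39 * cos(th), 1.39 * sin(th), 0),
         serials = 11:16, radius = 1.39, reskey = "B:1")
  }
  mk <- function(dxyz, hxyz) {
    ring <- hexring()
    atoms <- data.frame(
      name = c("CB", "HB1", paste0("C", 1:6)),
      element = c("C", "H", rep("C", 6)),
      sybyl = c("C.3", "H", rep("C.ar", 6)),
      x = c(dxyz[1], hxyz[1], ring$coords[, 1]),
      y = c(dxyz[2], hxyz[2], ring$coords[, 2]),
      z = c(dxyz[3], hxyz[3], ring$coords[, 3]),
      charge = 0, chain = c("A", "A", rep("B", 6)), resno = 1,
      resname = c("ALA", "ALA", rep("PHE", 6)),
      serial = c(1, 2, 11:16))
    mol_system(atoms, data.frame(a = 1, b = 2, type = "1"))
  }
  params <- default_rule_params(); radii <- default_vdw_radii()
  # axial: d(A:H) = 3.046 <= 3.195, Nr = cn
  sys <- mk(c(0, 0, 3.80), c(0, 0, 2.71))
  pr <- evaluate_xh_pi(sys, nciprofiler:::adjacency(sys), 1, 2, hexring(),
                       params, radii)
  expect_false(is.null(pr))
  expect_equal(pr$d_HA, sqrt(2.71^2 + 1.39^2), tolerance = 1e-6)
  expect_equal(pr$d_Nr_cn, 0, tolerance = 1e-9)
  # foot 2.5 A off-center exceeds 1.4 x ring radius: reject
  sys2 <- mk(c(2.5, 0, 3.80), c(2.5, 0, 2.71))
  expect_null(evaluate_xh_pi(sys2, nciprofiler:::adjacency(sys2), 1, 2,
                             hexring(), params, radii))
  # outer distance window needs the wide-angle condition
  h <- c(0.7, 0, 3.174)                      # nearest ring atom at 3.25 A
  u <- (c(1.39, 0, 0) - h) / 3.25
  sys3 <- mk(h - 1.09 * u, h)                # D-H-A collinear: 180 deg
  pr3 <- evaluate_xh_pi(sys3, nciprofiler:::adjacency(sys3), 1, 2,
                        hexring(), params, radii)
  expect_false(is.null(pr3))
  expect_gt(pr3$d_HA, params$ch_pi_ha_inner)
  w <- c(0.9766, 0, 0.2123)                  # 110 deg: below 124.455, reject
  v <- -0.342 * u + 0.940 * w
  sys4 <- mk(h + 1.09 * v, h)
  expect_null(evaluate_xh_pi(sys4, nciprofiler:::adjacency(sys4), 1, 2,
                             hexring(), params, radii))
})

test_that("orthogonal multipolar predicate follows the angle windows", {
  mk <- function(q_cg = 0.25, q_od = -0.27, od1 = c(0, 0, 0)) {
    atoms <- data.frame(
      name = c("CB", "CG", "OD1", "CA", "C", "O"),
      element = c("C", "C", "O", "C", "C", "O"),
      sybyl = c("C.3", "C.2", "O.2", "C.3", "C.2", "O.2"),
      x = c(-0.9, od1[1], od1[1], -0.75, 0, 1.23),
      y = c(-1.1, od1[2], od1[2], -1.0, 0, 0),
      z = c(-1.6, od1[3] - 1.23, od1[3], 3, 3, 3),
      charge = c(0.10, q_cg, q_od, 0.12, 0.28, -0.27),
      chain = c("A", "A", "A", "B", "B", "B"), resno = 1,
      resname = c("ASN", "ASN", "ASN", "GLY", "GLY", "GLY"))
    mol_system(atoms, data.frame(a = c(1, 2, 4, 5), b = c(2, 3, 5, 6),
                                 type = c("1", "2", "1", "2")))
  }
  params <- default_rule_params(); radii <- default_vdw_radii()
  sys <- mk()
  pr <- evaluate_omulpol(sys, nciprofiler:::adjacency(sys),
                         list(plus = 2, minus = 3),
                         list(plus = 5, minus = 6), params, radii)
  expect_false(is.null(pr))
  expect_equal(pr$d_Dp1m_Dp2p, 3.0)
  expect_equal(pr$ang_perp, 90, tolerance = 1e-6)
  expect_equal(pr$ang_Nr_Dp2p, 0, tolerance = 1e-6)
  expect_equal(pr$ang_Nr_Dp1p, 180, tolerance = 1e-6)
  # dipole-1 charge gap 0.15 < 0.2: reject
  sysq <- mk(q_cg = 0.10, q_od = -0.05)
  expect_null(evaluate_omulpol(sysq, nciprofiler:::adjacency(sysq),
                               list(plus = 2, minus = 3),
                               list(plus = 5, minus = 6), params, radii))
  # 60-degree approach angle falls outside [75, 105]: reject
  sys60 <- mk(od1 = c(1.5, 0, 3 - 3 * sin(pi / 3)))
  expect_null(evaluate_omulpol(sys60, nciprofiler:::adjacency(sys60),
                               list(plus = 2, minus = 3),
                               list(plus = 5, minus = 6), params, radii))
})

test_that("polar contacts split into HB and electrostatic at 3.2 A", {
  mk <- function(d) {
    atoms <- data.frame(
      name = c("CE", "NZ", "HZ1", "O", "C"),
      element = c("C", "N", "H", "O", "C"),
      sybyl = c("C.3", "N.4", "H", "O.2", "C.2"),
      x = c(-1.3, 0, 0.96, d, d + 0.7),
      y = c(-0.8, 0, 0, 0, 1.2), z = 0,
      charge = c(0.08, -0.30, 0.18, -0.28, 0.32),
      chain = c("A", "A", "A", "B", "B"), resno = 1,
      resname = c("LYS", "LYS", "LYS", "GLY", "GLY"))
    mol_system(atoms, data.frame(a = c(1, 2, 4), b = c(2, 3, 5),
                                 type = c("1", "1", "2")))
  }
  params <- default_rule_params(); radii <- default_vdw_radii()
  cl <- function(d) {
    sys <- mk(d)
    r <- classify_polar_contact(sys, nciprofiler:::adjacency(sys),
                                2, 3, 4, params, radii)
    if (is.null(r)) NA_character_ else r$kind
  }
  expect_equal(cl(2.85), "HB")
  expect_equal(cl(3.20), "HB")       # the boundary itself is a hydrogen bond
  expect_equal(cl(3.21), "Ele")
  expect_equal(cl(3.90), "Ele")      # long-range salt-bridge-like contact
  expect_true(is.na(cl(4.50)))       # beyond RvdW(N)+RvdW(O)+1 = 4.07
  # carbon donors are rejected outright
  sys <- mk(2.85)
  expect_error(classify_polar_contact(sys, nciprofiler:::adjacency(sys),
                                      1, 3, 4, params, radii), "N or O")
})

test_that("vdW contacts gate on the radii sum plus buffer", {
  mk <- function(d) {
    atoms <- data.frame(name = c("CB", "CB"), element = "C", sybyl = "C.3",
                        x = c(0, d), y = 0, z = 0, charge = -0.06,
                        chain = c("A", "B"), resno = 1, resname = "ALA")
    mol_system(atoms)
  }
  params <- default_rule_params(); radii <- default_vdw_radii()
  expect_false(is.null(evaluate_vdw_contact(mk(4.0), 1, 2, params, radii)))
  expect_null(evaluate_vdw_contact(mk(4.5), 1, 2, params, radii))
})

test_that("config files override parameters and validate their content", {
  crit <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("vdw_buffer: 0.8", "rules:", "  CH_O:", "    ha_max: 3.0"),
             crit)
  params <- read_criteria(crit)
  expect_equal(params$vdw_buffer, 0.8)
  expect_equal(params$per_rule$CH_O$ha_max, 3.0)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_parameter: 1", bad)
  expect_error(read_criteria(bad), "unknown parameter")

  rad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# custom radii", "C 1.75", "O 1.40"), rad)
  r <- read_vdw_radii(rad)
  expect_equal(unname(r["C"]), 1.75)
  expect_equal(unname(r["N"]), default_vdw_radii()[["N"]])

  pri <- withr::local_tempfile(fileext = ".txt")
  writeLines(rev(default_priority()), pri)
  expect_equal(read_priority(pri), rev(default_priority()))
  writeLines(c("CH_O", "vdW"), pri)
  expect_error(read_priority(pri), "permutation")
})
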
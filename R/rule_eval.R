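#' Interaction predicate evaluators
#'
#' Each evaluator takes explicit role atoms (by serial), measures the
#' geometry from raw coordinates and returns either `NULL` (reject) or a
#' named list of measured quantities (the geometry probe).  Distances in
#' Angstrom, angles in degrees.  Conditions on absent neighbor atoms are
#' vacuously true.
#'
#' @name rule_evaluators
NULL

# adjacency list serial -> bonded serials
adjacency <- function(sys) {
  adj <- new.env(parent = emptyenv())
  b <- sys$bonds
  for (i in seq_len(nrow(b))) {
    ka <- as.character(b$a[i]); kb <- as.character(b$b[i])
    assign(ka, c(get0(ka, adj, ifnotfound = integer(0)), b$b[i]), envir = adj)
    assign(kb, c(get0(kb, adj, ifnotfound = integer(0)), b$a[i]), envir = adj)
  }
  adj
}

neighbors_of <- function(adj, serial)
  get0(as.character(serial), adj, ifnotfound = integer(0))

heavy_neighbors <- function(sys, adj, serial) {
  nb <- neighbors_of(adj, serial)
  nb[sys$atoms$element[match(nb, sys$atoms$serial)] != "H"]
}

xyz_of <- function(sys, serial) {
  i <- match(serial, sys$atoms$serial)
  as.numeric(sys$atoms[i, c("x", "y", "z")])
}

rvdw <- function(radii, element) {
  r <- radii[element]
  if (anyNA(r)) stop(sprintf("no vdW radius for element '%s'",
                             element[is.na(r)][1]))
  unname(r)
}

vdw_gate <- function(sys, radii, s1, s2, buffer) {
  e <- sys$atoms$element[match(c(s1, s2), sys$atoms$serial)]
  rvdw(radii, e[1]) + rvdw(radii, e[2]) + buffer
}

#' X-H...Y predicate (CH...O template)
#'
#' Accepts iff all of: heavy-atom distance within the vdW-sum-plus-
#' buffer gate; D closer to A than any heavy neighbor of D; D closer to
#' A than A is to each of its heavy neighbors; H closer to A than D is;
#' H:A within `ha_max`; D-H-A angle at least `angle_min`.
#'
#' @param sys typed `mol_system`; `adj` adjacency from [adjacency()].
#' @param d,h,a serials of donor heavy atom, hydrogen, acceptor.
#' @param params,radii rule parameters and vdW radii.
#' @param ha_max,angle_min,buffer per-rule thresholds.
#' @return probe list or `NULL`.
#' @export
evaluate_xh_y <- function(sys, adj, d, h, a, params, radii,
                          ha_max = params$ch_o_ha_max,
                          angle_min = params$ch_o_angle_min,
                          buffer = params$vdw_buffer) {
  pd <- xyz_of(sys, d); ph <- xyz_of(sys, h); pa <- xyz_of(sys, a)
  d_da <- dist3(pd, pa)
  gate <- vdw_gate(sys, radii, d, a, buffer)
  if (d_da > gate) return(NULL)
  for (dn in setdiff(heavy_neighbors(sys, adj, d), a))
    if (d_da > dist3(xyz_of(sys, dn), pa)) return(NULL)
  for (an in setdiff(heavy_neighbors(sys, adj, a), d))
    if (d_da > dist3(pd, xyz_of(sys, an))) return(NULL)
  d_ha <- dist3(ph, pa)
  if (d_ha > d_da) return(NULL)
  if (d_ha > ha_max) return(NULL)
  ang <- angle_deg(pd, ph, pa)
  if (ang < angle_min || ang > 180) return(NULL)
  list(d_DA = d_da, d_HA = d_ha, ang_DHA = ang, gate = gate)
}

#' Polar contact classifier (hydrogen bond vs. electrostatic)
#'
#' Applies the X-H...Y template with the polar angle threshold, then
#' splits on the heavy-atom distance: `<= hb_ele_cutoff` (3.2 A) is a
#' hydrogen bond, beyond that but inside the vdW gate is electrostatic.
#'
#' @inheritParams evaluate_xh_y
#' @return list with `label` (`"HB"` or `"Ele"`) and the probe, or `NULL`.
#' @export
classify_polar_contact <- function(sys, adj, d, h, a, params, radii) {
  del <- sys$atoms$element[match(d, sys$atoms$serial)]
  if (!del %in% c("N", "O"))
    stop("classify_polar_contact: donor must be N or O")
  probe <- evaluate_xh_y(sys, adj, d, h, a, params, radii,
                         ha_max = Inf, angle_min = params$polar_angle_min)
  if (is.null(probe)) return(NULL)
  kind <- if (probe$d_DA <= params$hb_ele_cutoff) "HB" else "Ele"
  list(kind = kind, probe = probe)
}

#' X-H...pi predicate (CH...pi template)
#'
#' Per ring atom A: vdW gate on d(D:A); D closer to A than D's heavy
#' neighbors; d(H:A) <= d(D:A); the perpendicular foot Nr of H on the
#' ring plane within `ring_radius_factor` times d(cn:A) of the centroid;
#' and either d(A:H) inside the inner cap, or inside the outer cap with
#' the D-H-A angle above `angle_min`.  At most one hit per (D, ring),
#' reported at the nearest qualifying ring atom.
#'
#' @param ring ring system from [find_rings()].
#' @inheritParams evaluate_xh_y
#' @return probe list (with `a` = accepting ring atom serial) or `NULL`.
#' @export
evaluate_xh_pi <- function(sys, adj, d, h, ring, params, radii,
                           buffer = params$vdw_buffer) {
  pd <- xyz_of(sys, d); ph <- xyz_of(sys, h)
  nr <- foot_of_perpendicular(ph, ring)
  d_nr_cn <- dist3(nr, ring$cn)
  dn <- heavy_neighbors(sys, adj, d)
  best <- NULL
  for (i in seq_along(ring$serials)) {
    a <- ring$serials[i]
    pa <- ring$coords[i, ]
    d_da <- dist3(pd, pa)
    if (d_da > vdw_gate(sys, radii, d, a, buffer)) next
    skip <- FALSE
    for (x in setdiff(dn, a))
      if (d_da > dist3(xyz_of(sys, x), pa)) { skip <- TRUE; break }
    if (skip) next
    d_ha <- dist3(ph, pa)
    if (d_ha > d_da) next
    if (d_nr_cn > params$ring_radius_factor * dist3(ring$cn, pa)) next
    ang <- angle_deg(pd, ph, pa)
    inner <- d_ha <= params$ch_pi_ha_inner
    outer <- d_ha > params$ch_pi_ha_inner && d_ha <= params$ch_pi_ha_outer &&
      ang >= params$ch_pi_angle_min
    if (!(inner || outer)) next
    if (is.null(best) || d_ha < best$d_HA)
      best <- list(a = a, d_DA = d_da, d_HA = d_ha, ang_DHA = ang,
                   d_Nr_cn = d_nr_cn)
  }
  best
}

#' Sulfur-pi predicate
#'
#' Sulfur above an aromatic ring: vdW gate to some ring atom and the
#' perpendicular foot of the sulfur within the scaled ring radius.
#'
#' @param s sulfur serial; `ring` a ring system.
#' @inheritParams evaluate_xh_y
#' @export
evaluate_s_pi <- function(sys, adj, s, ring, params, radii,
                          buffer = params$vdw_buffer) {
  ps <- xyz_of(sys, s)
  nr <- foot_of_perpendicular(ps, ring)
  d_nr_cn <- dist3(nr, ring$cn)
  best <- NULL
  for (i in seq_along(ring$serials)) {
    a <- ring$serials[i]
    pa <- ring$coords[i, ]
    d_sa <- dist3(ps, pa)
    if (d_sa > vdw_gate(sys, radii, s, a, buffer)) next
    if (d_nr_cn > params$ring_radius_factor * dist3(ring$cn, pa)) next
    if (is.null(best) || d_sa < best$d_SA)
      best <- list(a = a, d_SA = d_sa, d_Nr_cn = d_nr_cn)
  }
  best
}

#' Face-to-face pi stacking predicate
#'
#' Centroid separation within `pi_pi_max_dist` and interplanar angle
#' (folded to `[0, 90]`) within `pi_pi_max_angle`.
#'
#' @param ring1,ring2 ring systems.
#' @param params rule parameters.
#' @export
evaluate_pi_pi <- function(ring1, ring2, params) {
  d_cc <- dist3(ring1$cn, ring2$cn)
  if (d_cc > params$pi_pi_max_dist) return(NULL)
  cosang <- abs(sum(ring1$normal * ring2$normal))
  ang <- acos(min(1, cosang)) * 180 / pi
  if (ang > params$pi_pi_max_angle) return(NULL)
  list(d_cn_cn = d_cc, interplanar = ang)
}

#' Chalcogen contact predicate (S...O / S...N / S...S)
#'
#' Heavy-atom distance within the vdW gate; the acceptor must carry an
#' sp2 or charged SYBYL type (divalent sulfur allowed for S...S), which
#' keeps sp3 water oxygen ineligible.
#'
#' @param s donor sulfur serial, `a` acceptor serial.
#' @param acceptor_sybyl allowed acceptor SYBYL types.
#' @inheritParams evaluate_xh_y
#' @export
evaluate_chalcogen <- function(sys, adj, s, a, acceptor_sybyl, params, radii,
                               buffer = params$vdw_buffer) {
  ia <- match(a, sys$atoms$serial)
  if (!(sys$atoms$sybyl[ia] %in% acceptor_sybyl)) return(NULL)
  d_sa <- dist3(xyz_of(sys, s), xyz_of(sys, a))
  if (d_sa > vdw_gate(sys, radii, s, a, buffer)) return(NULL)
  list(d_SA = d_sa)
}

#' Orthogonal multipolar predicate
#'
#' Both bond dipoles must have a partial-charge gap of at least
#' `dipole_charge_gap`; the negative pole of dipole 1 approaches the
#' positive pole of dipole 2 inside a tightened vdW gate, closer than
#' the positive pole does; and three angle windows enforce the
#' perpendicular approach, with Nr the foot of the perpendicular from
#' Dp1- onto the sp2 plane of dipole 2's group.
#'
#' @param dp1 list with `plus`, `minus` serials (dipole 1).
#' @param dp2 list with `plus`, `minus` serials (dipole 2); dipole 2's
#'   group must be sp2 so its plane is defined.
#' @inheritParams evaluate_xh_y
#' @export
evaluate_omulpol <- function(sys, adj, dp1, dp2, params, radii) {
  at <- sys$atoms
  q <- function(s) at$charge[match(s, at$serial)]
  if (anyNA(c(q(dp1$plus), q(dp1$minus), q(dp2$plus), q(dp2$minus))))
    stop("evaluate_omulpol: missing partial charges")
  gap1 <- q(dp1$plus) - q(dp1$minus)
  gap2 <- q(dp2$plus) - q(dp2$minus)
  if (gap1 < params$dipole_charge_gap || gap2 < params$dipole_charge_gap)
    return(NULL)
  # dipole 2's group must be sp2 so that its plane is defined
  sy2 <- at$sybyl[match(dp2$plus, at$serial)]
  if (!grepl("\\.(2|ar|cat|co2|am)$", sy2)) return(NULL)
  p1m <- xyz_of(sys, dp1$minus); p1p <- xyz_of(sys, dp1$plus)
  p2m <- xyz_of(sys, dp2$minus); p2p <- xyz_of(sys, dp2$plus)
  d_mp <- dist3(p1m, p2p)
  if (d_mp > vdw_gate(sys, radii, dp1$minus, dp2$plus, params$omulpol_buffer))
    return(NULL)
  if (d_mp > dist3(p1p, p2p)) return(NULL)
  ang_perp <- angle_deg(p2m, p2p, p1m)
  w <- params$omulpol_perp_window
  if (ang_perp < w[1] || ang_perp > w[2]) return(NULL)
  plane2 <- .sp2_plane(sys, adj, dp2)
  if (is.null(plane2)) return(NULL)
  nr <- foot_of_perpendicular(p1m, plane2)
  if (dist3(nr, p1m) < 1e-8) return(NULL)  # Dp1- in-plane: approach not perpendicular
  ang_nr2 <- angle_deg(nr, p1m, p2p)
  w <- params$omulpol_nr_dp2_window
  if (ang_nr2 < w[1] || ang_nr2 > w[2]) return(NULL)
  ang_nr1 <- angle_deg(nr, p1m, p1p)
  w <- params$omulpol_nr_dp1_window
  if (ang_nr1 < w[1] || ang_nr1 > w[2]) return(NULL)
  list(d_Dp1m_Dp2p = d_mp, ang_perp = ang_perp, ang_Nr_Dp2p = ang_nr2,
       ang_Nr_Dp1p = ang_nr1, gap1 = gap1, gap2 = gap2)
}

# best-fit plane of dipole 2's sp2 group: Dp2+, Dp2- and Dp2+'s other
# heavy neighbors; NULL when fewer than 3 points or degenerate
.sp2_plane <- function(sys, adj, dp2) {
  pts <- unique(c(dp2$plus, dp2$minus, heavy_neighbors(sys, adj, dp2$plus)))
  if (length(pts) < 3) return(NULL)
  co <- do.call(rbind, lapply(pts, function(s) xyz_of(sys, s)))
  tryCatch(ring_center_normal(co, planarity_tol = Inf), error = function(e) NULL)
}

#' Antiparallel bond-dipole predicate
#'
#' Both charge gaps at least `dipole_charge_gap`; the opposing poles
#' within the vdW gate; and the two dipole vectors (+ to -) antiparallel
#' within `dipo_align_window`.
#'
#' @inheritParams evaluate_omulpol
#' @export
evaluate_dipo <- function(sys, adj, dp1, dp2, params, radii) {
  at <- sys$atoms
  q <- function(s) at$charge[match(s, at$serial)]
  gap1 <- q(dp1$plus) - q(dp1$minus)
  gap2 <- q(dp2$plus) - q(dp2$minus)
  if (gap1 < params$dipole_charge_gap || gap2 < params$dipole_charge_gap)
    return(NULL)
  p1m <- xyz_of(sys, dp1$minus); p1p <- xyz_of(sys, dp1$plus)
  p2m <- xyz_of(sys, dp2$minus); p2p <- xyz_of(sys, dp2$plus)
  d_mp <- dist3(p1m, p2p)
  if (d_mp > vdw_gate(sys, radii, dp1$minus, dp2$plus, params$vdw_buffer))
    return(NULL)
  v1 <- p1m - p1p; v2 <- p2m - p2p
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  w <- params$dipo_align_window
  if (ang < w[1] || ang > w[2]) return(NULL)
  list(d_Dp1m_Dp2p = d_mp, align = ang, gap1 = gap1, gap2 = gap2)
}

#' van der Waals contact predicate
#'
#' Heavy-atom distance within the vdW-sum-plus-buffer gate.  The engine
#' keeps a vdW hit only when the pair carries no other assigned label
#' (priority resolution).
#'
#' @param a1,a2 heavy-atom serials.
#' @inheritParams evaluate_xh_y
#' @export
evaluate_vdw_contact <- function(sys, a1, a2, params, radii,
                                 buffer = params$vdw_buffer) {
  d <- dist3(xyz_of(sys, a1), xyz_of(sys, a2))
  if (d > vdw_gate(sys, radii, a1, a2, buffer)) return(NULL)
  list(d = d)
}

#' Metal / ion coordination predicate
#'
#' A metal or ion atom within the coordination cutoff of an N, O or S
#' atom of the analyzed residue.
#'
#' @param m metal/ion serial; `a` coordinating atom serial.
#' @param cutoff coordination distance cutoff (Angstrom).
#' @inheritParams evaluate_xh_y
#' @export
evaluate_coordination <- function(sys, m, a, cutoff) {
  ia <- match(a, sys$atoms$serial)
  if (!(sys$atoms$element[ia] %in% c("N", "O", "S"))) return(NULL)
  d <- dist3(xyz_of(sys, m), xyz_of(sys, a))
  if (d > cutoff) return(NULL)
  list(d = d)
}

# enumerate bond dipoles of a residue-atom subset: bonded heavy pairs
# whose charge gap meets the threshold; sp2_only restricts to groups
# whose positive pole is sp2 (carbonyl-like)
find_dipoles <- function(sys, adj, serials, gap, sp2_only = FALSE) {
  at <- sys$atoms
  out <- list()
  for (s in serials) {
    i <- match(s, at$serial)
    if (at$element[i] == "H") next
    for (nb in heavy_neighbors(sys, adj, s)) {
      if (nb %in% serials && nb < s) next   # each bonded pair once
      j <- match(nb, at$serial)
      qs <- at$charge[i]; qn <- at$charge[j]
      if (is.na(qs) || is.na(qn) || abs(qs - qn) < gap) next
      plus <- if (qs > qn) s else nb
      minus <- if (qs > qn) nb else s
      if (sp2_only) {
        sy <- at$sybyl[match(plus, at$serial)]
        if (!grepl("\\.(2|ar|cat|co2|am)$", sy)) next
      }
      out[[length(out) + 1]] <- list(plus = plus, minus = minus)
    }
  }
  out
}
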
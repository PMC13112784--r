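# Independent brute-force oracle: re-derives every interaction
# assignment from raw coordinates with plain arithmetic, no culling,
# looping over all atom pairs.  Used to cross-check the engine on the
# fixture systems (whose rings are single planar hexagons/pentagons).

o_xyz <- function(sys, s)
  as.numeric(sys$atoms[match(s, sys$atoms$serial), c("x", "y", "z")])
o_dist <- function(a, b) sqrt(sum((a - b)^2))
o_elem <- function(sys, s) sys$atoms$element[match(s, sys$atoms$serial)]
o_sybyl <- function(sys, s) sys$atoms$sybyl[match(s, sys$atoms$serial)]
o_charge <- function(sys, s) sys$atoms$charge[match(s, sys$atoms$serial)]
o_nb <- function(sys, s) {
  b <- sys$bonds
  c(b$b[b$a == s], b$a[b$b == s])
}
o_heavy_nb <- function(sys, s) {
  nb <- o_nb(sys, s)
  nb[o_elem(sys, nb) != "H"]
}
o_h_nb <- function(sys, s) {
  nb <- o_nb(sys, s)
  nb[o_elem(sys, nb) == "H"]
}
o_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) /
                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

o_gate <- function(sys, radii, s1, s2, buffer)
  radii[o_elem(sys, s1)] + radii[o_elem(sys, s2)] + buffer

# full X-H...Y condition list (vdW gate, neighbor conditions, H:A cap,
# D-H-A angle window)
o_xh <- function(sys, d, h, a, radii, buffer, ha_max, ang_min) {
  pd <- o_xyz(sys, d); ph <- o_xyz(sys, h); pa <- o_xyz(sys, a)
  dda <- o_dist(pd, pa)
  if (dda > o_gate(sys, radii, d, a, buffer)) return(NULL)
  for (dn in setdiff(o_heavy_nb(sys, d), a))
    if (dda > o_dist(o_xyz(sys, dn), pa)) return(NULL)
  for (an in setdiff(o_heavy_nb(sys, a), d))
    if (dda > o_dist(pd, o_xyz(sys, an))) return(NULL)
  dha <- o_dist(ph, pa)
  if (dha > dda || dha > ha_max) return(NULL)
  ang <- o_angle(pd, ph, pa)
  if (ang < ang_min || ang > 180) return(NULL)
  list(d_DA = dda, d_HA = dha, ang = ang)
}

# planar fixture ring: all aromatic atoms of one residue
o_rings <- function(sys, reskey) {
  a <- sys$atoms[sys$atoms$reskey == reskey, , drop = FALSE]
  ar <- a[grepl("\\.ar$", a$sybyl), , drop = FALSE]
  if (nrow(ar) < 5) return(list())
  co <- as.matrix(ar[, c("x", "y", "z")])
  cn <- colMeans(co)
  n <- pracma::cross(co[2, ] - co[1, ], co[3, ] - co[1, ])
  n <- n / sqrt(sum(n^2))
  list(list(serials = ar$serial, coords = co, cn = cn, normal = n))
}

o_foot <- function(p, cn, n) p - sum((p - cn) * n) * n

.o_acc_O <- c("O.2", "O.3", "O.co2")
.o_acc_N <- c("N.2", "N.ar")
.o_acc_S <- c("S.3", "S.2")
.o_sp2_O <- c("O.2", "O.co2")
.o_sp2_N <- c("N.2", "N.ar")

# every label whose predicate holds for the unordered pair, with the
# pair key it would be booked under
oracle_candidates <- function(sys, probe_set, env_set, params, radii) {
  out <- list()
  add <- function(label, s1, s2)
    out[[length(out) + 1]] <<- list(label = label,
                                    pair = c(min(s1, s2), max(s1, s2)))
  at <- sys$atoms
  p_heavy <- probe_set[o_elem(sys, probe_set) != "H"]
  e_heavy <- env_set[o_elem(sys, env_set) != "H"]
  bu <- params$vdw_buffer

  xh_pair <- function(dset, aset) {
    for (d in dset[o_elem(sys, dset) != "H"]) {
      hs <- intersect(o_h_nb(sys, d), dset)
      if (!length(hs)) next
      de <- o_elem(sys, d)
      for (a in aset) {
        ae <- o_elem(sys, a); asy <- o_sybyl(sys, a)
        for (h in hs) {
          # canonical polar contacts
          if (de %in% c("N", "O") &&
              ((ae == "O" && asy %in% .o_acc_O) ||
               (ae == "N" && asy %in% .o_acc_N))) {
            r <- o_xh(sys, d, h, a, radii, bu, Inf, params$polar_angle_min)
            if (!is.null(r)) {
              kind <- if (r$d_DA <= params$hb_ele_cutoff) "HB" else "Ele"
              add(sprintf("%s_%sH_%s", kind, de, ae), d, a)
            }
          }
          # weak hydrogen bonds
          weak <- c(C_O = "CH_O", C_N = "CH_N", C_S = "CH_S",
                    O_S = "OH_S", N_S = "NH_S", S_O = "SH_O",
                    S_N = "SH_N", S_S = "SH_S")
          lbl <- weak[paste0(de, "_", ae)]
          acc_ok <- (ae == "O" && asy %in% .o_acc_O) ||
            (ae == "N" && asy %in% .o_acc_N) ||
            (ae == "S" && asy %in% .o_acc_S)
          if (!is.na(lbl) && acc_ok) {
            r <- o_xh(sys, d, h, a, radii, bu, params$ch_o_ha_max,
                      params$ch_o_angle_min)
            if (!is.null(r)) add(unname(lbl), d, a)
          }
        }
      }
    }
  }
  xh_pair(probe_set, e_heavy)
  xh_pair(env_set, p_heavy)

  # chalcogen: sigma-hole sulfur donor (divalent, no H), sp2 acceptor
  chal <- function(sset, aset) {
    for (s in sset[o_elem(sys, sset) == "S"]) {
      if (length(o_h_nb(sys, s)) > 0 || length(o_heavy_nb(sys, s)) < 2) next
      for (a in aset) {
        if (a == s) next
        ae <- o_elem(sys, a); asy <- o_sybyl(sys, a)
        lbl <- if (ae == "O" && asy %in% .o_sp2_O) "S_O"
          else if (ae == "N" && asy %in% .o_sp2_N) "S_N"
          else if (ae == "S" && asy %in% .o_acc_S &&
                   length(o_heavy_nb(sys, a)) >= 2) "S_S"
          else NA
        if (is.na(lbl)) next
        if (o_dist(o_xyz(sys, s), o_xyz(sys, a)) <=
            o_gate(sys, radii, s, a, bu)) add(lbl, s, a)
      }
    }
  }
  chal(p_heavy, e_heavy)
  chal(e_heavy, p_heavy)

  # pi family
  probe_res <- unique(at$reskey[match(probe_set, at$serial)])
  env_res <- unique(at$reskey[match(env_set, at$serial)])
  pi_rules <- c(C = "CH_PI", N = "NH_PI", O = "OH_PI", S = "SH_PI")
  xh_ring <- function(dset, rings) {
    for (rg in rings) for (d in dset[o_elem(sys, dset) != "H"]) {
      hs <- intersect(o_h_nb(sys, d), dset)
      lbl <- pi_rules[o_elem(sys, d)]
      if (is.na(lbl) || !length(hs)) next
      for (h in hs) {
        ph <- o_xyz(sys, h); pd <- o_xyz(sys, d)
        nr <- o_foot(ph, rg$cn, rg$normal)
        best <- NULL
        for (i in seq_along(rg$serials)) {
          a <- rg$serials[i]; pa <- rg$coords[i, ]
          dda <- o_dist(pd, pa)
          if (dda > o_gate(sys, radii, d, a, bu)) next
          bad <- FALSE
          for (dn in setdiff(o_heavy_nb(sys, d), a))
            if (dda > o_dist(o_xyz(sys, dn), pa)) { bad <- TRUE; break }
          if (bad) next
          dha <- o_dist(ph, pa)
          if (dha > dda) next
          if (o_dist(nr, rg$cn) >
              params$ring_radius_factor * o_dist(rg$cn, pa)) next
          ang <- o_angle(pd, ph, pa)
          okd <- dha <= params$ch_pi_ha_inner ||
            (dha <= params$ch_pi_ha_outer && ang >= params$ch_pi_angle_min)
          if (!okd) next
          if (is.null(best) || dha < best$dha) best <- list(a = a, dha = dha)
        }
        if (!is.null(best)) add(unname(lbl), d, best$a)
      }
    }
  }
  s_ring <- function(sset, rings) {
    for (rg in rings) for (s in sset[o_elem(sys, sset) == "S"]) {
      ps <- o_xyz(sys, s)
      nr <- o_foot(ps, rg$cn, rg$normal)
      best <- NULL
      for (i in seq_along(rg$serials)) {
        a <- rg$serials[i]; pa <- rg$coords[i, ]
        dsa <- o_dist(ps, pa)
        if (dsa > o_gate(sys, radii, s, a, bu)) next
        if (o_dist(nr, rg$cn) >
            params$ring_radius_factor * o_dist(rg$cn, pa)) next
        if (is.null(best) || dsa < best$dsa) best <- list(a = a, dsa = dsa)
      }
      if (!is.null(best)) add("S_PI", s, best$a)
    }
  }
  env_rings <- do.call(c, lapply(env_res, function(k) o_rings(sys, k)))
  probe_rings <- do.call(c, lapply(probe_res, function(k) o_rings(sys, k)))
  xh_ring(probe_set, env_rings)
  xh_ring(env_set, probe_rings)
  s_ring(p_heavy, env_rings)
  s_ring(e_heavy, probe_rings)
  for (r1 in probe_rings) for (r2 in env_rings) {
    dcc <- o_dist(r1$cn, r2$cn)
    ang <- acos(min(1, abs(sum(r1$normal * r2$normal)))) * 180 / pi
    if (dcc <= params$pi_pi_max_dist && ang <= params$pi_pi_max_angle) {
      dm <- outer(seq_along(r1$serials), seq_along(r2$serials),
                  Vectorize(function(i, j) o_dist(r1$coords[i, ],
                                                  r2$coords[j, ])))
      ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
      add("PI_PI", r1$serials[ij[1]], r2$serials[ij[2]])
    }
  }

  # bond dipoles (mirrors the enumeration contract: one entry per
  # bonded heavy pair with |dq| >= gap, poles by charge sign)
  dipoles <- function(serials) {
    res <- list()
    for (s in serials[o_elem(sys, serials) != "H"]) {
      for (nb in o_heavy_nb(sys, s)) {
        if (nb %in% serials && nb < s) next
        qs <- o_charge(sys, s); qn <- o_charge(sys, nb)
        if (abs(qs - qn) < params$dipole_charge_gap) next
        res[[length(res) + 1]] <- list(plus = if (qs > qn) s else nb,
                                       minus = if (qs > qn) nb else s)
      }
    }
    res
  }
  sp2 <- function(s) grepl("\\.(2|ar|cat|co2|am)$", o_sybyl(sys, s))
  omulpol_ok <- function(d1, d2) {
    if (!sp2(d2$plus)) return(FALSE)
    p1m <- o_xyz(sys, d1$minus); p1p <- o_xyz(sys, d1$plus)
    p2m <- o_xyz(sys, d2$minus); p2p <- o_xyz(sys, d2$plus)
    dmp <- o_dist(p1m, p2p)
    if (dmp > o_gate(sys, radii, d1$minus, d2$plus, params$omulpol_buffer))
      return(FALSE)
    if (dmp > o_dist(p1p, p2p)) return(FALSE)
    a1 <- o_angle(p2m, p2p, p1m)
    if (a1 < params$omulpol_perp_window[1] ||
        a1 > params$omulpol_perp_window[2]) return(FALSE)
    pts <- rbind(p2p, p2m,
                 do.call(rbind, lapply(setdiff(o_heavy_nb(sys, d2$plus),
                                               d2$minus),
                                       function(s) o_xyz(sys, s))))
    if (nrow(pts) < 3) return(FALSE)
    n <- pracma::cross(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
    if (sqrt(sum(n^2)) < 1e-8) return(FALSE)
    n <- n / sqrt(sum(n^2))
    nr <- o_foot(p1m, pts[1, ], n)
    if (o_dist(nr, p1m) < 1e-8) return(FALSE)
    a2 <- o_angle(nr, p1m, p2p)
    if (a2 < params$omulpol_nr_dp2_window[1] ||
        a2 > params$omulpol_nr_dp2_window[2]) return(FALSE)
    a3 <- o_angle(nr, p1m, p1p)
    a3 >= params$omulpol_nr_dp1_window[1] &&
      a3 <= params$omulpol_nr_dp1_window[2]
  }
  dipo_ok <- function(d1, d2) {
    p1m <- o_xyz(sys, d1$minus); p1p <- o_xyz(sys, d1$plus)
    p2m <- o_xyz(sys, d2$minus); p2p <- o_xyz(sys, d2$plus)
    if (o_dist(p1m, p2p) > o_gate(sys, radii, d1$minus, d2$plus, bu))
      return(FALSE)
    v1 <- p1m - p1p; v2 <- p2m - p2p
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    ang >= params$dipo_align_window[1] && ang <= params$dipo_align_window[2]
  }
  dp <- dipoles(p_heavy); de <- dipoles(e_heavy)
  for (d1 in dp) for (d2 in de) {
    for (ord in list(list(d1, d2), list(d2, d1))) {
      if (omulpol_ok(ord[[1]], ord[[2]])) {
        add("OMulPol", ord[[1]]$minus, ord[[2]]$plus); break
      }
    }
    for (ord in list(list(d1, d2), list(d2, d1))) {
      if (dipo_ok(ord[[1]], ord[[2]])) {
        add("Dipo", ord[[1]]$minus, ord[[2]]$plus); break
      }
    }
  }

  # metal / ion coordination (metal atom sits in the environment)
  metals <- c(Fe = "Fe_A", Zn = "Zn_A", Ca = "Ca_A", Mg = "Mg_A",
              Ni = "Ni_A", Na = "Na_A", K = "K_A", Cl = "Cl_A")
  for (m in e_heavy[o_elem(sys, e_heavy) %in% names(metals)]) {
    lbl <- metals[o_elem(sys, m)]
    cutoff <- if (lbl %in% c("Na_A", "K_A", "Cl_A")) params$ion_cutoff
      else params$metal_cutoff
    for (a in p_heavy[o_elem(sys, p_heavy) %in% c("N", "O", "S")])
      if (o_dist(o_xyz(sys, m), o_xyz(sys, a)) <= cutoff)
        add(unname(lbl), m, a)
  }

  # residual van der Waals contacts
  for (s1 in p_heavy) for (s2 in e_heavy)
    if (o_dist(o_xyz(sys, s1), o_xyz(sys, s2)) <=
        o_gate(sys, radii, s1, s2, bu)) add("vdW", s1, s2)
  out
}

# full oracle pass: per target residue, all candidates against every
# other residue, highest-priority label per pair, M-M pairs deduplicated
oracle_hits <- function(sys, params = default_rule_params(),
                        radii = default_vdw_radii(),
                        priority = default_priority()) {
  at <- sys$atoms
  res <- sys$residues
  bb <- c("N", "CA", "C", "O", "OXT")
  out <- character(0)
  for (t in res$reskey[res$class == "M"]) {
    t_rows <- which(at$reskey == t)
    heavy <- at$serial[t_rows][!(at$name[t_rows] %in% bb) &
                               at$element[t_rows] != "H"]
    hset <- unlist(lapply(heavy, function(s) o_h_nb(sys, s)))
    probe <- c(heavy, hset[at$reskey[match(hset, at$serial)] == t])
    for (ek in setdiff(unique(at$reskey), t)) {
      env <- at$serial[at$reskey == ek]
      cand <- oracle_candidates(sys, probe, env, params, radii)
      if (!length(cand)) next
      keys <- vapply(cand, function(x) paste(x$pair, collapse = "-"), "")
      rank <- match(vapply(cand, `[[`, "", "label"), priority)
      for (k in unique(keys)) {
        i <- which(keys == k)
        best <- cand[[i[which.min(rank[i])]]]
        pcls <- res$class[res$reskey == ek]
        if (pcls == "M" && t >= ek) next
        out <- c(out, paste(t, ek, best$label, k))
      }
    }
  }
  sort(out)
}

engine_hit_keys <- function(det) {
  sort(vapply(det$hits, function(h)
    paste(h$target, h$partner, h$label, paste(h$pair, collapse = "-")), ""))
}

# re-measure a hit's own rule inequalities from raw coordinates
remeasure_hit <- function(sys, h, params = default_rule_params(),
                          radii = default_vdw_radii()) {
  lab <- h$label
  r <- h$roles
  if (lab %in% c("CH_O", "CH_N", "CH_S", "OH_S", "NH_S", "SH_O", "SH_N",
                 "SH_S"))
    return(!is.null(o_xh(sys, r[["D"]], r[["H"]], r[["A"]], radii,
                         params$vdw_buffer, params$ch_o_ha_max,
                         params$ch_o_angle_min)))
  if (grepl("^(HB|Ele)_", lab)) {
    m <- o_xh(sys, r[["D"]], r[["H"]], r[["A"]], radii, params$vdw_buffer,
              Inf, params$polar_angle_min)
    if (is.null(m)) return(FALSE)
    if (startsWith(lab, "HB")) return(m$d_DA <= params$hb_ele_cutoff)
    return(m$d_DA > params$hb_ele_cutoff)
  }
  TRUE  # pi/dipole/vdw families are covered by the full oracle pass
}
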
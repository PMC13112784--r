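#' Interaction detection engine
#'
#' Enumerates candidate atom pairs between each target (M) residue and
#' its environment (antibody, antigen, solvent, the other M residue in a
#' DPM pair, metals and ions), evaluates every registry rule, keeps only
#' the highest-priority label per atom pair, and chains single-water
#' bridges.  Intra-residue interactions are never extracted.
#'
#' @name interaction_engine
NULL

.new_hit <- function(label, target, partner, partner_class, pair, roles,
                     measured) {
  list(label = label, target = target, partner = partner,
       partner_class = partner_class,
       pair = c(min(pair), max(pair)), roles = roles, measured = measured)
}

# donors of a given element within a serial set: list of (d, h) pairs
.donors <- function(sys, adj, serials, element) {
  at <- sys$atoms
  out <- list()
  for (s in serials) {
    i <- match(s, at$serial)
    if (at$element[i] != element) next
    hs <- neighbors_of(adj, s)
    hs <- hs[at$element[match(hs, at$serial)] == "H"]
    hs <- intersect(hs, serials)  # hydrogen must belong to the analyzed set
    for (h in hs) out[[length(out) + 1]] <- c(d = s, h = h)
  }
  out
}

.acceptors <- function(sys, serials, element, sybyl_set = NULL) {
  at <- sys$atoms
  i <- match(serials, at$serial)
  ok <- at$element[i] == element
  if (!is.null(sybyl_set)) ok <- ok & at$sybyl[i] %in% sybyl_set
  serials[ok]
}

#' Detect interactions around the target residues
#'
#' For every analyzed atom of each M residue, all registry rules are
#' evaluated against environment atoms within the cull radius; per atom
#' pair only the highest-priority qualifying label is retained.  Hits
#' are deterministic and sorted by (target, partner, label, serials).
#' Water bridges (target - single water - partner) are returned
#' alongside the direct hits.
#'
#' @param sys typed, partner-classed `mol_system`.
#' @param params rule parameters ([default_rule_params()]).
#' @param radii vdW radius table ([default_vdw_radii()]).
#' @param priority label priority order ([default_priority()]).
#' @param registry rule registry ([default_registry()]).
#' @param include_backbone analyze backbone atoms of the M residue too.
#' @param cull spatial cull radius in Angstrom between heavy atoms
#'   (default 8; `Inf` disables culling).
#' @return list with `hits` (list of interaction hits) and `bridges`
#'   (list of water bridges, each with `water`, `leg1`, `leg2`).
#' @export
detect_interactions <- function(sys, params = default_rule_params(),
                                radii = default_vdw_radii(),
                                priority = default_priority(),
                                registry = default_registry(),
                                include_backbone = FALSE, cull = 8) {
  res <- sys$residues
  if (anyNA(res$class))
    stop("detect_interactions: partner classes not assigned")
  targets <- res$reskey[res$class == "M"]
  if (length(targets) == 0)
    stop("detect_interactions: no target (M) residue")
  adj <- adjacency(sys)
  rings_all <- find_rings(sys, params = params)
  ring_res <- vapply(rings_all, `[[`, "", "reskey")
  cls <- stats::setNames(res$class, res$reskey)

  hits <- list()
  for (t in targets) {
    t_idx <- analyzed_atoms(sys, t, include_backbone)
    t_ser <- sys$atoms$serial[t_idx]
    if (length(t_ser) == 0) next   # e.g. a glycine target: nothing analyzed
    env_keys <- .culled_residues(sys, t_ser, t, cull)
    cand <- .evaluate_side(sys, adj, params, radii, registry,
                           probe_serials = t_ser, probe_key = t,
                           env_keys = env_keys, rings_all = rings_all,
                           ring_res = ring_res)
    kept <- .resolve_priority(cand, priority)
    for (h in kept) {
      h$target <- t
      h$partner_class <- unname(cls[h$partner])
      hits[[length(hits) + 1]] <- h
    }
  }
  # de-duplicate symmetric M-M pairs (each seen from both targets)
  if (length(targets) > 1 && length(hits)) {
    keys <- vapply(hits, function(h) {
      if (h$partner_class != "M") return(NA_character_)
      rp <- sort(c(h$target, h$partner))
      paste(rp[1], rp[2], h$label, paste(h$pair, collapse = "-"))
    }, "")
    hits <- hits[is.na(keys) | !duplicated(keys)]
  }
  hits <- .sort_hits(hits)

  bridges <- bridge_water(sys, hits, adj, params, radii, priority, registry,
                          rings_all, ring_res, cull)
  list(hits = hits, bridges = bridges)
}

# residues (other than `self`) with any atom within `cull` of the probe atoms
.culled_residues <- function(sys, probe_serials, self, cull) {
  at <- sys$atoms
  keys <- setdiff(unique(at$reskey), self)
  if (!is.finite(cull)) return(keys)
  pm <- as.matrix(at[match(probe_serials, at$serial), c("x", "y", "z")])
  keep <- vapply(keys, function(k) {
    em <- as.matrix(at[at$reskey == k, c("x", "y", "z")])
    for (i in seq_len(nrow(em)))
      if (min(sqrt(rowSums((pm - matrix(em[i, ], nrow(pm), 3,
                                        byrow = TRUE))^2))) <= cull)
        return(TRUE)
    FALSE
  }, logical(1))
  keys[keep]
}

# evaluate every rule between the probe atom set and each environment
# residue, in both role directions; returns unresolved candidates
.evaluate_side <- function(sys, adj, params, radii, registry, probe_serials,
                           probe_key, env_keys, rings_all, ring_res) {
  at <- sys$atoms
  cand <- list()
  add <- function(label, pair, partner, roles, measured)
    cand[[length(cand) + 1]] <<- .new_hit(label, NA, partner, NA, pair,
                                          roles, measured)
  p_heavy <- probe_serials[at$element[match(probe_serials, at$serial)] != "H"]
  probe_rings <- rings_all[ring_res == probe_key]

  for (ek in env_keys) {
    e_ser <- at$serial[at$reskey == ek]
    e_heavy <- e_ser[at$element[match(e_ser, at$serial)] != "H"]
    env_rings <- rings_all[ring_res == ek]

    for (rl in registry) {
      tpl <- rl$template
      if (tpl %in% c("polar", "xh_y")) {
        if (tpl == "polar" && startsWith(rl$label, "Ele_")) next # handled with HB twin
        for (dir in 1:2) {
          dser <- if (dir == 1) probe_serials else e_ser
          aser <- if (dir == 1) e_ser else probe_serials
          accs <- .acceptors(sys, aser, rl$acceptor, rl$acceptor_sybyl)
          if (!length(accs)) next
          for (dh in .donors(sys, adj, dser, rl$donor)) {
            for (a in accs) {
              if (at$reskey[match(dh["d"], at$serial)] ==
                  at$reskey[match(a, at$serial)]) next
              if (tpl == "polar") {
                r <- classify_polar_contact(sys, adj, dh["d"], dh["h"], a,
                                            params, radii)
                if (is.null(r)) next
                lab <- sub("^HB", r$kind, rl$label)
                add(lab, c(dh["d"], a), ek,
                    c(D = unname(dh["d"]), H = unname(dh["h"]), A = a),
                    r$probe)
              } else {
                pr <- evaluate_xh_y(
                  sys, adj, dh["d"], dh["h"], a, params, radii,
                  ha_max = rule_param(params, rl$label, "ha_max",
                                      params$ch_o_ha_max),
                  angle_min = rule_param(params, rl$label, "angle_min",
                                         params$ch_o_angle_min),
                  buffer = rule_param(params, rl$label, "buffer",
                                      params$vdw_buffer))
                if (is.null(pr)) next
                add(rl$label, c(dh["d"], a), ek,
                    c(D = unname(dh["d"]), H = unname(dh["h"]), A = a), pr)
              }
            }
          }
        }
      } else if (tpl == "xh_pi") {
        buf <- rule_param(params, rl$label, "buffer", params$vdw_buffer)
        for (dh in .donors(sys, adj, probe_serials, rl$donor)) {
          for (rg in env_rings) {
            pr <- evaluate_xh_pi(sys, adj, dh["d"], dh["h"], rg, params,
                                 radii, buffer = buf)
            if (is.null(pr)) next
            add(rl$label, c(dh["d"], pr$a), ek,
                c(D = unname(dh["d"]), H = unname(dh["h"]), A = pr$a),
                pr[setdiff(names(pr), "a")])
          }
        }
        for (dh in .donors(sys, adj, e_ser, rl$donor)) {
          for (rg in probe_rings) {
            pr <- evaluate_xh_pi(sys, adj, dh["d"], dh["h"], rg, params,
                                 radii, buffer = buf)
            if (is.null(pr)) next
            add(rl$label, c(dh["d"], pr$a), ek,
                c(D = unname(dh["d"]), H = unname(dh["h"]), A = pr$a),
                pr[setdiff(names(pr), "a")])
          }
        }
      } else if (tpl == "s_pi") {
        buf <- rule_param(params, rl$label, "buffer", params$vdw_buffer)
        for (s in p_heavy[at$element[match(p_heavy, at$serial)] == "S"]) {
          for (rg in env_rings) {
            pr <- evaluate_s_pi(sys, adj, s, rg, params, radii, buffer = buf)
            if (is.null(pr)) next
            add(rl$label, c(s, pr$a), ek, c(S = s, A = pr$a),
                pr[setdiff(names(pr), "a")])
          }
        }
        for (s in e_heavy[at$element[match(e_heavy, at$serial)] == "S"]) {
          for (rg in probe_rings) {
            pr <- evaluate_s_pi(sys, adj, s, rg, params, radii, buffer = buf)
            if (is.null(pr)) next
            add(rl$label, c(s, pr$a), ek, c(S = s, A = pr$a),
                pr[setdiff(names(pr), "a")])
          }
        }
      } else if (tpl == "pi_pi") {
        for (r1 in probe_rings) for (r2 in env_rings) {
          pr <- evaluate_pi_pi(r1, r2, params)
          if (is.null(pr)) next
          # representative pair: closest inter-ring atom pair
          dm <- outer(seq_along(r1$serials), seq_along(r2$serials),
                      Vectorize(function(i, j) dist3(r1$coords[i, ],
                                                     r2$coords[j, ])))
          ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
          add(rl$label, c(r1$serials[ij[1]], r2$serials[ij[2]]), ek,
              c(A1 = r1$serials[ij[1]], A2 = r2$serials[ij[2]]), pr)
        }
      } else if (tpl == "chalcogen") {
        buf <- rule_param(params, rl$label, "buffer", params$vdw_buffer)
        for (dir in 1:2) {
          sset <- if (dir == 1) p_heavy else e_heavy
          aset <- if (dir == 1) e_heavy else p_heavy
          for (s in sset[at$element[match(sset, at$serial)] == "S"]) {
            # sigma-hole donor: divalent sulfur with two heavy
            # substituents and no hydrogen (thioether / disulfide)
            snb <- neighbors_of(adj, s)
            sh <- at$element[match(snb, at$serial)] == "H"
            if (any(sh) || length(snb[!sh]) < 2) next
            for (a in .acceptors(sys, aset, rl$acceptor)) {
              if (a == s) next
              # S...S acceptors must likewise be divalent thioether-like
              if (rl$acceptor == "S" &&
                  length(heavy_neighbors(sys, adj, a)) < 2) next
              pr <- evaluate_chalcogen(sys, adj, s, a, rl$acceptor_sybyl,
                                       params, radii, buffer = buf)
              if (is.null(pr)) next
              add(rl$label, c(s, a), ek, c(S = s, A = a), pr)
            }
          }
        }
      } else if (tpl %in% c("omulpol", "dipo")) {
        gap <- params$dipole_charge_gap
        dp_probe <- find_dipoles(sys, adj, p_heavy, gap,
                                 sp2_only = FALSE)
        dp_env <- find_dipoles(sys, adj, e_heavy, gap, sp2_only = FALSE)
        for (d1 in dp_probe) for (d2 in dp_env) {
          for (ord in 1:2) {
            a1 <- if (ord == 1) d1 else d2
            a2 <- if (ord == 1) d2 else d1
            pr <- if (tpl == "omulpol")
              evaluate_omulpol(sys, adj, a1, a2, params, radii)
            else evaluate_dipo(sys, adj, a1, a2, params, radii)
            if (is.null(pr)) next
            add(rl$label, c(a1$minus, a2$plus), ek,
                c(Dp1_plus = a1$plus, Dp1_minus = a1$minus,
                  Dp2_plus = a2$plus, Dp2_minus = a2$minus), pr)
            break
          }
        }
      } else if (tpl == "vdw") {
        buf <- rule_param(params, rl$label, "buffer", params$vdw_buffer)
        for (s1 in p_heavy) for (s2 in e_heavy) {
          pr <- evaluate_vdw_contact(sys, s1, s2, params, radii, buffer = buf)
          if (is.null(pr)) next
          add(rl$label, c(s1, s2), ek, c(A1 = s1, A2 = s2), pr)
        }
      } else if (tpl %in% c("metal", "ion")) {
        cutoff <- rule_param(params, rl$label, "cutoff",
                             if (tpl == "metal") params$metal_cutoff
                             else params$ion_cutoff)
        mts <- e_heavy[at$element[match(e_heavy, at$serial)] == rl$metal]
        for (m in mts) for (a in p_heavy) {
          pr <- evaluate_coordination(sys, m, a, cutoff)
          if (is.null(pr)) next
          add(rl$label, c(m, a), ek, c(Metal = m, A = a), pr)
        }
      }
    }
  }
  cand
}

# keep the highest-priority label per unordered atom pair
.resolve_priority <- function(cand, priority) {
  if (!length(cand)) return(cand)
  keys <- vapply(cand, function(h) paste(h$pair, collapse = "-"), "")
  rank <- match(vapply(cand, `[[`, "", "label"), priority)
  if (anyNA(rank)) stop("priority order does not cover all labels")
  keep <- integer(0)
  for (k in unique(keys)) {
    i <- which(keys == k)
    keep <- c(keep, i[which.min(rank[i])])
  }
  cand[sort(keep)]
}

.sort_hits <- function(hits) {
  if (!length(hits)) return(hits)
  ord <- order(vapply(hits, `[[`, "", "target"),
               vapply(hits, `[[`, "", "partner"),
               vapply(hits, `[[`, "", "label"),
               vapply(hits, function(h) h$pair[1], numeric(1)),
               vapply(hits, function(h) h$pair[2], numeric(1)))
  hits[ord]
}

#' Enumerate single-water bridges
#'
#' A bridge requires one leg between an M residue and a water (taken
#' from the direct hits) and one leg between the same water and a
#' non-water partner residue (antibody, antigen or the other M residue).
#' Waters touching only the M residue yield no bridge.  One bridge is
#' emitted per (leg1, leg2) pair; deduplication to descriptor level
#' happens during aggregation.
#'
#' @param sys typed, partner-classed system.
#' @param hits direct hits from the engine.
#' @param adj,params,radii,priority,registry,rings_all,ring_res,cull
#'   engine state (internal use).
#' @return list of bridges, each `list(water, leg1, leg2)`.
#' @export
bridge_water <- function(sys, hits, adj = adjacency(sys),
                         params = default_rule_params(),
                         radii = default_vdw_radii(),
                         priority = default_priority(),
                         registry = default_registry(),
                         rings_all = NULL, ring_res = NULL, cull = 8) {
  if (is.null(rings_all)) {
    rings_all <- find_rings(sys, params = params)
    ring_res <- vapply(rings_all, `[[`, "", "reskey")
  }
  res <- sys$residues
  cls <- stats::setNames(res$class, res$reskey)
  m_water <- Filter(function(h) h$partner_class == "S", hits)
  if (!length(m_water)) return(list())
  bridges <- list()
  for (w in unique(vapply(m_water, `[[`, "", "partner"))) {
    leg1s <- Filter(function(h) h$partner == w, m_water)
    w_ser <- sys$atoms$serial[sys$atoms$reskey == w]
    env_keys <- .culled_residues(sys, w_ser, w, cull)
    env_keys <- env_keys[cls[env_keys] %in% c("Ab", "Ag", "M")]
    cand <- .evaluate_side(sys, adj, params, radii, registry,
                           probe_serials = w_ser, probe_key = w,
                           env_keys = env_keys, rings_all = rings_all,
                           ring_res = ring_res)
    leg2s <- .resolve_priority(cand, priority)
    for (l2 in leg2s) l2$partner_class <- unname(cls[l2$partner])
    for (l1 in leg1s) {
      for (l2 in leg2s) {
        if (l2$partner == l1$target) next   # would re-trace leg1
        l2$partner_class <- unname(cls[l2$partner])
        bridges[[length(bridges) + 1]] <-
          list(water = w, leg1 = l1, leg2 = l2)
      }
    }
  }
  # deterministic order
  if (length(bridges)) {
    ord <- order(vapply(bridges, `[[`, "", "water"),
                 vapply(bridges, function(b) b$leg1$target, ""),
                 vapply(bridges, function(b) b$leg2$partner, ""),
                 vapply(bridges, function(b) b$leg1$label, ""),
                 vapply(bridges, function(b) b$leg2$label, ""),
                 vapply(bridges, function(b) b$leg2$pair[1], numeric(1)))
    bridges <- bridges[ord]
  }
  bridges
}

.fmt_measured <- function(m)
  paste(sprintf("%s=%.3f", names(m), unlist(m)), collapse = ";")

#' Write hits and bridges to a tab-separated file
#'
#' One row per hit or bridge: descriptor name, target residue, partner
#' residue, role atom names and the measured geometry.  Output is
#' byte-identical across reruns on identical input.
#'
#' @param hits,bridges engine output.
#' @param sys the system the hits refer to.
#' @param path output file.
#' @export
write_hits <- function(hits, bridges, sys, path) {
  at <- sys$atoms
  nm <- function(s) at$name[match(s, at$serial)]
  rows <- c(paste("descriptor", "target", "partner", "atoms", "measured",
                  sep = "\t"))
  for (h in hits) {
    rows <- c(rows, paste(
      descriptor_name(h), h$target, h$partner,
      paste(sprintf("%s:%s", names(h$roles), nm(h$roles)), collapse = ","),
      .fmt_measured(h$measured), sep = "\t"))
  }
  for (b in bridges) {
    rows <- c(rows, paste(
      descriptor_name(b), b$leg1$target, b$leg2$partner,
      paste(c(sprintf("%s:%s", names(b$leg1$roles), nm(b$leg1$roles)),
              sprintf("%s:%s", names(b$leg2$roles), nm(b$leg2$roles))),
            collapse = ","),
      paste(.fmt_measured(b$leg1$measured), .fmt_measured(b$leg2$measured),
            sep = "|"), sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

.pml_color <- function(label) {
  if (startsWith(label, "HB_")) return("blue")
  if (startsWith(label, "Ele_")) return("cyan")
  if (label %in% c("CH_PI", "NH_PI", "OH_PI", "SH_PI")) return("orange")
  if (label == "CH_O") return("pink")
  if (label == "OMulPol") return("yellow")
  if (label == "vdW") return(NA_character_)   # suppressed
  "grey70"
}

#' Write a PyMOL visualization script
#'
#' Emits one dashed distance object per hit, named after its label and
#' colored by interaction family: hydrogen bonds blue, electrostatics
#' cyan, X-H...pi orange, CH...O pink, orthogonal multipolar yellow.
#' van der Waals contacts are omitted by default.
#'
#' @param hits,bridges engine output.
#' @param path output `.pml` file.
#' @param show_vdw draw vdW contacts too (off by default).
#' @export
write_pml <- function(hits, bridges, path, show_vdw = FALSE) {
  lines <- c("# nciprofiler interaction visualization", "hide labels")
  n <- 0
  draw <- function(label, pair) {
    col <- .pml_color(label)
    if (is.na(col) && !show_vdw) return(NULL)
    if (is.na(col)) col <- "grey50"
    n <<- n + 1
    obj <- sprintf("nci_%03d_%s", n, label)
    c(sprintf("distance %s, id %d, id %d", obj, pair[1], pair[2]),
      sprintf("color %s, %s", col, obj),
      sprintf("hide labels, %s", obj))
  }
  for (h in hits) lines <- c(lines, draw(h$label, h$pair))
  for (b in bridges) {
    lines <- c(lines, draw(b$leg1$label, b$leg1$pair),
               draw(b$leg2$label, b$leg2$pair))
  }
  writeLines(lines, path)
  invisible(path)
}
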
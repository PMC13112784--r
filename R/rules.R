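#' Rule parameters, vdW radii and the interaction rule registry
#'
#' The registry holds the 36 interaction labels: 28 direct labels
#' (hydrogen bonds, long-range electrostatics, pi systems, weak hydrogen
#' bonds, sulfur contacts, dipole interactions, van der Waals), 5 metal
#' coordination labels and 3 ion labels.  Each rule is declarative:
#' participant constraints (donor/acceptor elements and SYBYL types)
#' plus a predicate template with parameter bindings.  All numeric
#' thresholds live in the parameter set and can be overridden from an
#' interaction criteria config file.
#'
#' @name interaction_rules
NULL

#' Default rule parameters
#'
#' Distances in Angstrom, angles in degrees.  The vdW `buffer` (default
#' 1 A) is added to the sum of vdW radii in every distance-gated rule;
#' the orthogonal multipolar rule uses its own tighter 0.7 A buffer.
#' Hydrogen bonds and electrostatics are split at a heavy-atom distance
#' of 3.2 A (the boundary value itself classifies as hydrogen bond).
#'
#' @return named list of parameters.
#' @export
default_rule_params <- function() {
  list(
    vdw_buffer        = 1.0,
    omulpol_buffer    = 0.7,
    hb_ele_cutoff     = 3.2,
    polar_angle_min   = 90,
    ch_o_ha_max       = 3.22,
    ch_o_angle_min    = 94.58,
    ch_pi_ha_inner    = 3.195,
    ch_pi_ha_outer    = 3.325,
    ch_pi_angle_min   = 124.455,
    ring_radius_factor = 1.4,
    dipole_charge_gap = 0.2,
    omulpol_perp_window  = c(75, 105),
    omulpol_nr_dp2_window = c(0, 35),
    omulpol_nr_dp1_window = c(150, 180),
    dipo_align_window = c(135, 180),
    pi_pi_max_dist    = 5.5,
    pi_pi_max_angle   = 35,
    metal_cutoff      = 3.0,
    ion_cutoff        = 3.5,
    planarity_tol     = 0.35,
    per_rule          = list()   # label -> list(ha_max=, angle_min=, buffer=)
  )
}

#' Default van der Waals radii (Bondi set, Angstrom)
#'
#' @return named numeric vector element -> radius.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
    Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39,
    Ni = 1.63, Fe = 1.94)
}

#' Read a vdW radius definition file
#'
#' Plain text, one `element radius` pair per line; `#` comments allowed.
#' Entries override the Bondi defaults.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_vdw_radii <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  f <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  if (ncol(f) != 2) stop("vdW radius file: expected 'element radius' lines")
  r <- as.numeric(f[, 2]); names(r) <- f[, 1]
  if (any(r <= 0.5 | r >= 3.0)) stop("vdW radius file: radius outside (0.5, 3.0) A")
  out <- default_vdw_radii()
  out[names(r)] <- r
  out
}

#' Read an interaction criteria config (YAML)
#'
#' Top-level keys override global parameters (e.g. `vdw_buffer`,
#' `hb_ele_cutoff`); a `rules:` map of label to `{ha_max, angle_min,
#' buffer}` sets per-rule overrides.
#'
#' @param path YAML file.
#' @param params base parameter set to modify.
#' @return updated parameter list.
#' @export
read_criteria <- function(path, params = default_rule_params()) {
  cfg <- yaml::read_yaml(path)
  for (k in setdiff(names(cfg), "rules")) {
    if (!k %in% names(params)) stop(sprintf("criteria file: unknown parameter '%s'", k))
    params[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$rules)) {
    labels <- names(default_registry())
    bad <- setdiff(names(cfg$rules), labels)
    if (length(bad)) stop(sprintf("criteria file: unknown rule label(s) %s",
                                  paste(bad, collapse = ", ")))
    for (lb in names(cfg$rules))
      params$per_rule[[lb]] <- utils::modifyList(
        params$per_rule[[lb]] %||% list(), cfg$rules[[lb]])
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SYBYL acceptor sets
.acc_O_any  <- c("O.2", "O.3", "O.co2")
.acc_N_lp   <- c("N.2", "N.ar")          # nitrogen with an available lone pair
.acc_S_any  <- c("S.3", "S.2")
.acc_sp2    <- c("O.2", "O.co2", "N.2", "N.ar")  # chalcogen-bond acceptors

#' The interaction rule registry
#'
#' @return named list of 36 rules; each rule carries `label`, `category`
#'   (hbond, electrostatic, weak_hbond, pi, sulfur, dipole, vdw, metal,
#'   ion), `template` (polar, xh_y, xh_pi, s_pi, pi_pi, chalcogen,
#'   omulpol, dipo, vdw, metal, ion) and participant constraints.
#' @export
default_registry <- function() {
  rule <- function(label, category, template, donor = NULL, acceptor = NULL,
                   acceptor_sybyl = NULL, metal = NULL) {
    list(label = label, category = category, template = template,
         donor = donor, acceptor = acceptor,
         acceptor_sybyl = acceptor_sybyl, metal = metal)
  }
  rules <- list(
    # canonical polar contacts, split HB/Ele at the 3.2 A heavy-atom distance
    rule("HB_OH_O",  "hbond", "polar", donor = "O", acceptor = "O", acceptor_sybyl = .acc_O_any),
    rule("HB_NH_O",  "hbond", "polar", donor = "N", acceptor = "O", acceptor_sybyl = .acc_O_any),
    rule("HB_OH_N",  "hbond", "polar", donor = "O", acceptor = "N", acceptor_sybyl = .acc_N_lp),
    rule("HB_NH_N",  "hbond", "polar", donor = "N", acceptor = "N", acceptor_sybyl = .acc_N_lp),
    rule("Ele_OH_O", "electrostatic", "polar", donor = "O", acceptor = "O", acceptor_sybyl = .acc_O_any),
    rule("Ele_NH_O", "electrostatic", "polar", donor = "N", acceptor = "O", acceptor_sybyl = .acc_O_any),
    rule("Ele_OH_N", "electrostatic", "polar", donor = "O", acceptor = "N", acceptor_sybyl = .acc_N_lp),
    rule("Ele_NH_N", "electrostatic", "polar", donor = "N", acceptor = "N", acceptor_sybyl = .acc_N_lp),
    # pi systems
    rule("PI_PI", "pi", "pi_pi"),
    rule("CH_PI", "pi", "xh_pi", donor = "C"),
    rule("NH_PI", "pi", "xh_pi", donor = "N"),
    rule("S_PI",  "sulfur", "s_pi", donor = "S"),
    # weak hydrogen bonds (X-H...Y), CH...O predicate template
    rule("CH_O", "weak_hbond", "xh_y", donor = "C", acceptor = "O", acceptor_sybyl = .acc_O_any),
    rule("CH_N", "weak_hbond", "xh_y", donor = "C", acceptor = "N", acceptor_sybyl = .acc_N_lp),
    rule("CH_S", "weak_hbond", "xh_y", donor = "C", acceptor = "S", acceptor_sybyl = .acc_S_any),
    rule("OH_S", "weak_hbond", "xh_y", donor = "O", acceptor = "S", acceptor_sybyl = .acc_S_any),
    rule("NH_S", "weak_hbond", "xh_y", donor = "N", acceptor = "S", acceptor_sybyl = .acc_S_any),
    rule("SH_O", "weak_hbond", "xh_y", donor = "S", acceptor = "O", acceptor_sybyl = .acc_O_any),
    rule("SH_N", "weak_hbond", "xh_y", donor = "S", acceptor = "N", acceptor_sybyl = .acc_N_lp),
    rule("SH_S", "weak_hbond", "xh_y", donor = "S", acceptor = "S", acceptor_sybyl = .acc_S_any),
    rule("OH_PI", "pi", "xh_pi", donor = "O"),
    rule("SH_PI", "pi", "xh_pi", donor = "S"),
    # chalcogen contacts: sulfur donor, sp2/charged acceptor only
    rule("S_O", "sulfur", "chalcogen", donor = "S", acceptor = "O", acceptor_sybyl = intersect(.acc_sp2, .acc_O_any)),
    rule("S_N", "sulfur", "chalcogen", donor = "S", acceptor = "N", acceptor_sybyl = intersect(.acc_sp2, .acc_N_lp)),
    rule("S_S", "sulfur", "chalcogen", donor = "S", acceptor = "S", acceptor_sybyl = .acc_S_any),
    # dipole interactions
    rule("OMulPol", "dipole", "omulpol"),
    rule("Dipo",    "dipole", "dipo"),
    # residual contacts
    rule("vdW", "vdw", "vdw"),
    # metal coordination
    rule("Fe_A", "metal", "metal", metal = "Fe"),
    rule("Zn_A", "metal", "metal", metal = "Zn"),
    rule("Ca_A", "metal", "metal", metal = "Ca"),
    rule("Mg_A", "metal", "metal", metal = "Mg"),
    rule("Ni_A", "metal", "metal", metal = "Ni"),
    # ion coordination
    rule("Na_A", "ion", "ion", metal = "Na"),
    rule("K_A",  "ion", "ion", metal = "K"),
    rule("Cl_A", "ion", "ion", metal = "Cl")
  )
  names(rules) <- vapply(rules, `[[`, "", "label")
  stopifnot(length(rules) == 36)
  rules
}

#' Direct (non-metal, non-ion) labels of a registry
#'
#' @param registry rule registry.
#' @return character vector of 28 labels.
#' @export
direct_labels <- function(registry = default_registry()) {
  cat <- vapply(registry, `[[`, "", "category")
  names(registry)[!(cat %in% c("metal", "ion"))]
}

#' Default priority order for label assignment
#'
#' When several rules accept the same atom pair, only the
#' highest-priority label is kept.  Metals/ions outrank hydrogen bonds,
#' which outrank electrostatics, dipole interactions, chalcogen
#' contacts, pi interactions and weak hydrogen bonds; van der Waals is
#' last (it is defined as the residual contact).  Fully overridable via
#' a priority file.
#'
#' @return character vector of the 36 labels, highest priority first.
#' @export
default_priority <- function() {
  c("Fe_A", "Zn_A", "Ca_A", "Mg_A", "Ni_A", "Na_A", "K_A", "Cl_A",
    "HB_OH_O", "HB_NH_O", "HB_OH_N", "HB_NH_N",
    "Ele_OH_O", "Ele_NH_O", "Ele_OH_N", "Ele_NH_N",
    "OMulPol", "Dipo",
    "S_O", "S_N", "S_S",
    "CH_PI", "NH_PI", "OH_PI", "SH_PI",
    "PI_PI", "S_PI",
    "CH_O", "CH_N", "CH_S", "OH_S", "NH_S", "SH_O", "SH_N", "SH_S",
    "vdW")
}

#' Read an interaction priority file
#'
#' One label per line, highest priority first; must be a permutation of
#' the registry labels.
#'
#' @param path file path.
#' @param registry rule registry to check against.
#' @return character vector of labels.
#' @export
read_priority <- function(path, registry = default_registry()) {
  p <- trimws(readLines(path))
  p <- p[nzchar(p) & !grepl("^#", p)]
  if (!setequal(p, names(registry)) || length(p) != length(registry))
    stop("priority file must be a permutation of the 36 registry labels")
  p
}

# effective per-rule parameter with fallback chain:
# per-rule override -> rule-family default
rule_param <- function(params, label, key, default) {
  ov <- params$per_rule[[label]]
  if (!is.null(ov[[key]])) ov[[key]] else default
}
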
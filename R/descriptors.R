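#' Interaction descriptors
#'
#' Hits and water bridges are named `M#<label>#<partner class>` and
#' `M#<label1>#S#<label2>#<class>` respectively.  Aggregation produces
#' either the grouped 30-vector (28 direct labels with the partner
#' identity erased, plus the pooled water terms `M##S` and `M##S##`) or
#' the individual vector that keeps water interactions resolved by
#' label.  Metal and ion labels are excluded from descriptor vectors by
#' default.
#'
#' @name descriptors
NULL

#' Descriptor name of a hit or bridge
#'
#' @param x an interaction hit (`M#label#class`; class `S` for direct
#'   water contacts) or a water bridge (`M#l1#S#l2#class`).
#' @return descriptor string.
#' @export
descriptor_name <- function(x) {
  if (!is.null(x$leg1)) {
    cls <- x$leg2$partner_class
    if (!cls %in% c("Ab", "Ag", "M"))
      stop(sprintf("descriptor_name: unknown bridge partner class '%s'", cls))
    return(paste0("M#", x$leg1$label, "#S#", x$leg2$label, "#", cls))
  }
  cls <- x$partner_class
  if (cls == "S") return(paste0("M#", x$label, "#S"))
  if (!cls %in% c("Ab", "Ag", "M"))
    stop(sprintf("descriptor_name: unknown partner class '%s'", cls))
  paste0("M#", x$label, "#", cls)
}

#' Labels whose constraints are satisfiable with a water participant
#'
#' A water molecule offers an sp3 oxygen (SYBYL `O.3`) bearing two
#' hydrogens and nothing else: it can act as an O-H donor, as an sp3
#' oxygen acceptor, and as a heavy atom for vdW contacts, but it has no
#' carbon, nitrogen, sulfur, pi system or heavy-atom bond dipole.  A
#' direct label is water-capable when one side of its participant
#' specification can be drawn from that template.
#'
#' @param registry rule registry.
#' @return character vector of water-capable direct labels, in registry
#'   order.
#' @export
water_capable_labels <- function(registry = default_registry()) {
  water_sybyl <- "O.3"
  ok <- vapply(registry, function(rl) {
    switch(rl$template,
      polar = ,
      xh_y = {
        as_donor <- identical(rl$donor, "O")
        as_acceptor <- rl$acceptor == "O" && water_sybyl %in% rl$acceptor_sybyl
        as_donor || as_acceptor
      },
      xh_pi = identical(rl$donor, "O"),  # water O-H toward a residue ring
      s_pi = FALSE,                       # no sulfur, no ring
      pi_pi = FALSE,
      chalcogen = rl$acceptor == "O" && water_sybyl %in% rl$acceptor_sybyl,
      omulpol = FALSE,                    # no heavy-atom bond dipole
      dipo = FALSE,
      vdw = TRUE,                         # water oxygen is a heavy atom
      metal = FALSE,                      # excluded: not a direct label
      ion = FALSE,
      FALSE)
  }, logical(1))
  intersect(names(registry)[ok], direct_labels(registry))
}

#' Canonical descriptor keys
#'
#' @param mode `"grouped"` (30 keys) or `"individual"` (28 direct +
#'   11 `M#X#S` + 11 `M#X#S#X#` + 55 unordered `M#X#S#Y#` keys).
#' @param registry rule registry.
#' @return character vector of keys in canonical order.
#' @export
descriptor_keys <- function(mode = c("grouped", "individual"),
                            registry = default_registry()) {
  mode <- match.arg(mode)
  direct <- direct_labels(registry)
  if (mode == "grouped")
    return(c(paste0("M#", direct, "#"), "M##S", "M##S##"))
  wc <- water_capable_labels(registry)
  mixed <- character(0)
  if (length(wc) > 1) {
    for (i in seq_len(length(wc) - 1))
      for (j in (i + 1):length(wc))
        mixed <- c(mixed, paste0("M#", wc[i], "#S#", wc[j], "#"))
  }
  c(paste0("M#", direct, "#"),
    paste0("M#", wc, "#S"),
    paste0("M#", wc, "#S#", wc, "#"),
    mixed)
}

#' Aggregate hits and bridges into a descriptor vector
#'
#' Grouped mode erases the partner class of direct hits (`M#CH_O#Ab`
#' and `M#CH_O#Ag` both count into `M#CH_O#`), pools all direct
#' M-water hits into `M##S` and all bridges into `M##S##`.  Individual
#' mode keeps water contacts and bridges resolved by label, with mixed
#' bridges `M#X#S#Y#` treated as unordered pairs.  Bridges that differ
#' only in role atoms but share (water, leg labels, partner) count once
#' per occurrence.  Metal and ion labels are dropped by default.
#'
#' @param hits,bridges engine output.
#' @param mode `"grouped"` or `"individual"`.
#' @param exclusions labels to drop (default metals + ions).
#' @param registry rule registry.
#' @return named integer vector over [descriptor_keys()].
#' @export
aggregate_descriptors <- function(hits, bridges,
                                  mode = c("grouped", "individual"),
                                  exclusions = NULL,
                                  registry = default_registry()) {
  mode <- match.arg(mode)
  if (is.null(exclusions)) {
    cat <- vapply(registry, `[[`, "", "category")
    exclusions <- names(registry)[cat %in% c("metal", "ion")]
  }
  keys <- descriptor_keys(mode, registry)
  counts <- stats::setNames(integer(length(keys)), keys)
  wc <- water_capable_labels(registry)
  bump <- function(k) counts[k] <<- counts[k] + 1L
  for (h in hits) {
    if (h$label %in% exclusions) next
    if (mode == "grouped") {
      if (h$partner_class == "S") bump("M##S") else bump(paste0("M#", h$label, "#"))
    } else {
      if (h$partner_class == "S") bump(paste0("M#", h$label, "#S"))
      else bump(paste0("M#", h$label, "#"))
    }
  }
  for (b in bridges) {
    l1 <- b$leg1$label; l2 <- b$leg2$label
    if (l1 %in% exclusions || l2 %in% exclusions) next
    if (mode == "grouped") bump("M##S##")
    else {
      if (l1 == l2) bump(paste0("M#", l1, "#S#", l1, "#"))
      else {
        pair <- c(l1, l2)[order(match(c(l1, l2), wc))]
        bump(paste0("M#", pair[1], "#S#", pair[2], "#"))
      }
    }
  }
  counts
}

#' Write descriptor vectors to CSV
#'
#' One row per structure/target set; metadata columns first, then the
#' descriptor keys in canonical order.  The file reads back losslessly
#' with [read_descriptor_table()].
#'
#' @param vectors list of named count vectors sharing one mode.
#' @param path output CSV.
#' @param metadata optional data frame (one row per vector), e.g.
#'   structure id, target residues, class label, cluster id,
#'   rotamer energy.
#' @export
write_descriptor_table <- function(vectors, path, metadata = NULL) {
  if (length(vectors)) {
    keysets <- vapply(vectors, function(v) paste(names(v), collapse = "|"), "")
    if (length(unique(keysets)) > 1)
      stop("write_descriptor_table: vectors with mixed descriptor modes")
    m <- do.call(rbind, lapply(vectors, function(v) as.data.frame(as.list(v),
                                                                  check.names = FALSE)))
  } else {
    m <- as.data.frame(as.list(stats::setNames(
      integer(length(descriptor_keys("grouped"))),
      descriptor_keys("grouped"))), check.names = FALSE)[0, ]
  }
  out <- if (!is.null(metadata)) cbind(metadata, m) else m
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor CSV back
#'
#' @param path CSV written by [write_descriptor_table()].
#' @return data frame with metadata and descriptor columns.
#' @export
read_descriptor_table <- function(path)
  utils::read.csv(path, check.names = FALSE)
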
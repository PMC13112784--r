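#' Aromatic ring perception
#'
#' Rings are found per residue, first from the residue ring templates
#' (Phe, Tyr, His and the two Trp rings), then — for residues without a
#' template — from the bond graph: connected components of aromatic
#' (`ar`) bonds that form a single simple cycle of five or more atoms.
#' Each ring is reduced to its centroid, best-fit plane normal and mean
#' radius; rings failing the planarity gate are skipped.
#'
#' @param sys typed `mol_system`.
#' @param reskeys residue keys to search; default all residues.
#' @param params rule parameters (for the planarity tolerance).
#' @return list of ring systems; each has `reskey`, `serials`, `cn`,
#'   `normal`, `radius` and `coords`.
#' @export
find_rings <- function(sys, reskeys = NULL, params = default_rule_params()) {
  a <- sys$atoms
  if (is.null(reskeys)) reskeys <- unique(a$reskey)
  tmpl <- .ring_templates
  rings <- list()
  graph_done <- FALSE
  for (k in reskeys) {
    ra <- a[a$reskey == k, , drop = FALSE]
    rt <- tmpl[[ra$resname[1]]]
    if (!is.null(rt)) {
      for (names_set in rt) {
        idx <- match(names_set, ra$name)
        if (anyNA(idx)) next   # incomplete ring: skip
        rings[[length(rings) + 1]] <- .make_ring(k, ra[idx, ], params)
      }
    }
  }
  # graph-based perception for residues without a template
  rest <- reskeys[!(a$resname[match(reskeys, a$reskey)] %in% names(tmpl))]
  if (length(rest) && nrow(sys$bonds)) {
    b <- sys$bonds[sys$bonds$type == "ar", , drop = FALSE]
    if (nrow(b)) {
      keep <- a$serial[a$reskey %in% rest]
      b <- b[b$a %in% keep & b$b %in% keep, , drop = FALSE]
      if (nrow(b)) {
        g <- igraph::graph_from_data_frame(
          data.frame(from = as.character(b$a), to = as.character(b$b)),
          directed = FALSE)
        comps <- igraph::components(g)
        for (ci in seq_len(comps$no)) {
          vs <- names(comps$membership)[comps$membership == ci]
          if (length(vs) < 5) next
          sub <- igraph::induced_subgraph(g, vs)
          if (!all(igraph::degree(sub) == 2)) next   # not a simple cycle
          serials <- as.integer(vs)
          idx <- match(serials, a$serial)
          rings[[length(rings) + 1]] <- .make_ring(a$reskey[idx[1]],
                                                   a[idx, ], params)
        }
      }
    }
  }
  rings[!vapply(rings, is.null, logical(1))]
}

.make_ring <- function(reskey, ratoms, params) {
  co <- as.matrix(ratoms[, c("x", "y", "z")])
  r <- tryCatch(ring_center_normal(co, params$planarity_tol),
                error = function(e) NULL)
  if (is.null(r)) return(NULL)
  r$reskey <- reskey
  r$serials <- ratoms$serial
  r
}
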
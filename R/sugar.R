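## Detection and removal of linear and circular sugar moieties.
##
## Glycosylation is ubiquitous in natural products but contributes
## repetitive, weakly distinctive fragments, so scoring is done on the
## aglycone as well. The detection rules are this package's operational
## definition (tunable via sugar_options()):
##
##   circular: a non-aromatic 5- or 6-membered ring with exactly one ring
##     oxygen and otherwise carbons, not fused or spiro to another ring,
##     whose ring carbons carry at least (ring size - 2) exocyclic
##     single-bonded oxygen substituents (hydroxyl or glycosidic).
##   linear: a maximal acyclic chain of 3-7 carbons in which every carbon
##     bears exactly one oxygen substituent (hydroxyl, carbonyl or
##     connecting oxygen) and no atom is in a ring.
##
## SMARTS renditions of these patterns are documented in
## inst/extdata/sugar_patterns.smarts for reference and external editing.

#' Sugar detection options
#'
#' @param ring_sizes ring sizes eligible as circular sugars.
#' @param exocyclic_o_deficit a ring of size k needs at least
#'   `k - exocyclic_o_deficit` ring carbons bearing exocyclic
#'   single-bonded oxygens.
#' @param chain_min,chain_max length bounds of linear sugar carbon
#'   chains.
#' @return a named list of thresholds.
#' @export
sugar_options <- function(ring_sizes = c(5L, 6L), exocyclic_o_deficit = 2L,
                          chain_min = 3L, chain_max = 7L) {
  list(ring_sizes = as.integer(ring_sizes),
       exocyclic_o_deficit = as.integer(exocyclic_o_deficit),
       chain_min = as.integer(chain_min), chain_max = as.integer(chain_max))
}

## Bonds that lie on a cycle (non-bridges), and the atoms they touch.
.ring_bonds <- function(mg) {
  g <- mg_igraph(mg)
  if (igraph::ecount(g) == 0) return(logical(0))
  br <- igraph::bridges(g)
  on_ring <- rep(TRUE, nrow(mg$bonds))
  on_ring[as.integer(br)] <- FALSE
  on_ring
}

## Smallest cycle through each ring bond (length-capped), deduplicated.
.small_rings <- function(mg, max_size = 7L) {
  m <- nrow(mg$bonds)
  if (m == 0) return(list())
  on_ring <- .ring_bonds(mg)
  g <- mg_igraph(mg)
  seen <- character(0)
  out <- list()
  for (e in which(on_ring)) {
    a <- mg$bonds[e, 1]; b <- mg$bonds[e, 2]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, a, b)$vpath[[1]])
    if (length(sp) == 0 || length(sp) > max_size) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- ring  # in cycle order (path a..b, edge b-a)
  }
  out
}

#' Detect circular sugar moieties
#'
#' @param mg a curated `molgraph` (heavy atoms, single component).
#' @param opts thresholds from [sugar_options()].
#' @return a list of disjoint integer vectors, each the ring-atom indices
#'   of one detected sugar ring.
#' @export
detect_circular_sugars <- function(mg, opts = sugar_options()) {
  rings <- .small_rings(mg, max_size = max(opts$ring_sizes) + 1L)
  if (!length(rings)) return(list())
  on_ring <- .ring_bonds(mg)
  rb <- mg$bonds[on_ring, , drop = FALSE]
  nb <- .mg_adjacency(mg)$nb
  taken <- integer(0)
  out <- list()
  for (ring in rings) {
    k <- length(ring)
    if (!(k %in% opts$ring_sizes)) next
    el <- mg$elem[ring]
    if (sum(el == "O") != 1 || !all(el %in% c("C", "O"))) next
    if (any(mg$arom[ring])) next
    ## not fused/spiro: every cycle bond touching a ring atom is internal
    touches <- rb[, 1] %in% ring | rb[, 2] %in% ring
    internal <- rb[, 1] %in% ring & rb[, 2] %in% ring
    if (any(touches & !internal)) next
    ## exocyclic single-bonded oxygens on ring carbons
    n_exo_o <- 0L
    for (v in ring[el == "C"]) {
      for (u in nb[[v]]) {
        if (u %in% ring) next
        bi <- which((mg$bonds[, 1] == v & mg$bonds[, 2] == u) |
                    (mg$bonds[, 1] == u & mg$bonds[, 2] == v))
        if (mg$elem[u] == "O" && mg$bonds[bi[1], 3] == 1L) {
          n_exo_o <- n_exo_o + 1L
          break  # count carbons bearing oxygen, one per carbon
        }
      }
    }
    if (n_exo_o < k - opts$exocyclic_o_deficit) next
    if (any(ring %in% taken)) next
    taken <- c(taken, ring)
    out[[length(out) + 1L]] <- ring
  }
  out
}

#' Detect linear sugar moieties
#'
#' @inheritParams detect_circular_sugars
#' @return a list of disjoint integer vectors, each the atom indices of
#'   one detected open-chain sugar (chain carbons plus their oxygen
#'   substituents).
#' @export
detect_linear_sugars <- function(mg, opts = sugar_options()) {
  n <- mg_n_atoms(mg)
  if (n == 0) return(list())
  on_ring <- .ring_bonds(mg)
  ring_atoms <- unique(as.integer(mg$bonds[on_ring, 1:2]))
  nb <- .mg_adjacency(mg)$nb
  ## eligible carbons: acyclic, exactly one oxygen neighbour, that
  ## oxygen acyclic too
  o_nbrs <- lapply(seq_len(n), function(v)
    nb[[v]][mg$elem[nb[[v]]] == "O" & !(nb[[v]] %in% ring_atoms)])
  eligible <- which(mg$elem == "C" & !(seq_len(n) %in% ring_atoms) &
                    vapply(o_nbrs, length, 1L) == 1L)
  if (!length(eligible)) return(list())
  ## carbon-carbon single-bond subgraph over eligible carbons
  keepb <- mg$bonds[, 1] %in% eligible & mg$bonds[, 2] %in% eligible &
           mg$bonds[, 3] == 1L
  sub_edges <- mg$bonds[keepb, 1:2, drop = FALSE]
  comp_g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub_edges[, 1]),
               to = as.character(sub_edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(eligible)))
  memb <- igraph::components(comp_g)$membership
  out <- list()
  for (cc in unique(memb)) {
    atoms <- as.integer(names(memb)[memb == cc])
    path <- .longest_simple_path(atoms, nb)
    if (length(path) < opts$chain_min || length(path) > opts$chain_max) next
    set <- sort(unique(c(path, unlist(o_nbrs[path]))))
    out[[length(out) + 1L]] <- set
  }
  out
}

## Longest simple path within an atom set (sets are tiny).
.longest_simple_path <- function(atoms, nb) {
  best <- integer(0)
  walk <- function(v, seen) {
    if (length(seen) > length(best)) best <<- seen
    for (u in nb[[v]]) {
      if (u %in% atoms && !(u %in% seen)) walk(u, c(seen, u))
    }
  }
  for (a in atoms) walk(a, a)
  best
}

#' Remove sugar moieties
#'
#' Detected circular sugars are removed first (with their exocyclic and
#' glycosidic oxygens), then linear sugars are detected on the remainder
#' and removed; finally the largest remaining component is kept. An
#' oxygen bridging a sugar and the rest of the molecule leaves with the
#' sugar unless it bonds to two non-sugar atoms. Sugar-free molecules
#' are returned unchanged (the identical graph object).
#'
#' @inheritParams detect_circular_sugars
#' @param min_atoms if the remainder has fewer heavy atoms than this,
#'   the aglycone is reported as `NULL`.
#' @return a list with elements `aglycone` (a `molgraph`, or `NULL` when
#'   nothing non-sugar of sufficient size remains), `had_circular_sugar`,
#'   `had_linear_sugar`, `removed_atom_count` (heavy atoms removed as
#'   sugar moieties).
#' @examples
#' salicin <- parse_smiles("OCC1=CC=CC=C1OC1OC(CO)C(O)C(O)C1O")[[1]]
#' res <- remove_sugars(salicin)
#' res$had_circular_sugar
#' mg_n_heavy(res$aglycone)
#' @export
remove_sugars <- function(mg, opts = sugar_options(), min_atoms = 6L) {
  stopifnot(inherits(mg, "molgraph"))
  nb <- .mg_adjacency(mg)$nb
  circ <- detect_circular_sugars(mg, opts)
  sugar_atoms <- unlist(circ) %||% integer(0)
  ## exocyclic oxygens of ring carbons; bridging oxygens stay only when
  ## bonded to >= 2 non-sugar heavy atoms
  core <- sugar_atoms
  for (v in core) {
    for (u in nb[[v]]) {
      if (u %in% sugar_atoms || mg$elem[u] != "O") next
      if (length(setdiff(nb[[u]], core)) >= 2) next
      sugar_atoms <- c(sugar_atoms, u)
    }
  }
  had_circ <- length(circ) > 0
  remainder_idx <- setdiff(seq_len(mg_n_atoms(mg)), sugar_atoms)
  removed <- length(unique(sugar_atoms))
  had_lin <- FALSE
  if (length(remainder_idx)) {
    rem <- if (removed) mg_induced(mg, remainder_idx) else mg
    lin <- detect_linear_sugars(rem, opts)
    had_lin <- length(lin) > 0
    if (had_lin) {
      lin_atoms <- unique(unlist(lin))
      removed <- removed + length(lin_atoms)
      keep <- setdiff(seq_len(mg_n_atoms(rem)), lin_atoms)
      rem <- if (length(keep)) mg_induced(rem, keep) else NULL
    }
  } else rem <- NULL
  if (!had_circ && !had_lin)
    return(list(aglycone = mg, had_circular_sugar = FALSE,
                had_linear_sugar = FALSE, removed_atom_count = 0L))
  aglycone <- NULL
  if (!is.null(rem) && mg_n_atoms(rem) > 0) {
    rem <- largest_component(rem)
    if (mg_n_heavy(rem) >= min_atoms) aglycone <- mg_canonicalize(rem)
  }
  list(aglycone = aglycone, had_circular_sugar = had_circ,
       had_linear_sugar = had_lin, removed_atom_count = as.integer(removed))
}
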
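## Canonical atom signatures.
##
## The height-h signature of an atom is a canonical string encoding of the
## subgraph induced by all atoms within graph distance h of that atom (its
## "ball"), rooted at the atom. Within the ball, atoms are layered by
## shortest-path distance from the root; every bond of the molecule whose
## two endpoints lie in the ball connects atoms of the same or adjacent
## layers and is part of the encoded structure, so rings are preserved.
##
## Canonicalisation uses colour refinement (Weisfeiler-Lehman style) over
## (layer, element, aromaticity, charge) atom colours and bond tokens,
## followed by individualisation of tied atoms; the canonical string is
## the lexicographic minimum over all serialisations the search produces.
## Serialisation is SMILES-like: depth-first spanning tree from the root
## with bracketed atom tokens, bond tokens (nothing, "=", "#", ":") and
## numbered ring closures.

.BOND_TOKENS <- c("-", "=", "#")

.bond_token <- function(order, arom) ifelse(arom, ":", .BOND_TOKENS[order])

.atom_token <- function(elem, arom, charge) {
  sym <- ifelse(arom, tolower(elem), elem)
  chg <- ifelse(charge == 0, "",
         ifelse(charge > 0, paste0("+", ifelse(charge > 1, charge, "")),
                paste0("-", ifelse(charge < -1, -charge, ""))))
  paste0("[", sym, chg, "]")
}

#' Atom signature of one atom
#'
#' Computes the canonical height-`height` signature of atom `atom_index`
#' in an explicit-hydrogen molecular graph. Two atoms receive the same
#' canonical string exactly when their rooted height-`height`
#' neighbourhood subgraphs are isomorphic (matching elements, aromaticity
#' flags, formal charges and bond orders).
#'
#' @param mg a `molgraph` with explicit hydrogens (see
#'   [mg_add_hydrogens()]); hydrogens are legitimate signature centres.
#' @param atom_index integer atom index.
#' @param height integer neighbourhood radius (graph distance), >= 0.
#' @return an object of class `atom_signature`: a list with elements
#'   `canonical_string`, `height` and `center_element`.
#' @examples
#' mg <- mg_add_hydrogens(parse_smiles("CCC")[[1]])
#' atom_signature(mg, 1, 2)$canonical_string
#' @export
atom_signature <- function(mg, atom_index, height = 2L) {
  stopifnot(inherits(mg, "molgraph"))
  n <- mg_n_atoms(mg)
  if (!(is.numeric(atom_index) && length(atom_index) == 1 &&
        atom_index >= 1 && atom_index <= n))
    .stopf("invalid atom index %s", paste(atom_index, collapse = ","))
  if (height < 0) .stopf("height must be >= 0")
  D <- .mg_dist_from(mg, as.integer(atom_index), as.integer(height))
  s <- .ball_canonical_string(mg, as.integer(atom_index), D, as.integer(height))
  structure(list(canonical_string = s, height = as.integer(height),
                 center_element = mg$elem[atom_index]),
            class = "atom_signature")
}

#' @export
print.atom_signature <- function(x, ...) {
  cat(sprintf("<atom signature h=%d center=%s> %s\n",
              x$height, x$center_element, x$canonical_string))
  invisible(x)
}

#' Molecular signature
#'
#' The multiset of canonical atom signatures of every atom (hydrogens
#' included) of a molecule, with multiplicities.
#'
#' @param mg a `molgraph`; implicit hydrogens are made explicit first.
#' @param height signature height (default 2).
#' @return an object of class `molecular_signature`: a named integer
#'   vector of multiplicities (names are canonical signature strings,
#'   sorted), with attributes `height` and `center_element` (named
#'   character vector mapping signature string to its centre element).
#' @examples
#' sig <- molecular_signature(parse_smiles("c1ccccc1")[[1]], 2)
#' length(sig)  # benzene has two distinct height-2 signatures
#' @export
molecular_signature <- function(mg, height = 2L) {
  stopifnot(inherits(mg, "molgraph"))
  if (mg_n_atoms(mg) == 0) .stopf("empty molecule")
  if (!mg$explicit_h) mg <- mg_add_hydrogens(mg)
  height <- as.integer(height)
  n <- mg_n_atoms(mg)
  adj <- .mg_adjacency(mg)
  sigs <- character(n)
  for (a in seq_len(n)) {
    D <- .bfs_dist(adj$nb, a, height)
    sigs[a] <- .ball_canonical_string(mg, a, D, height, adj)
  }
  tab <- table(sigs)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  centers <- vapply(split(mg$elem, sigs), `[`, "", 1)
  structure(counts, height = height,
            center_element = centers[names(counts)],
            class = "molecular_signature")
}

#' @export
print.molecular_signature <- function(x, ...) {
  cat(sprintf("<molecular signature h=%d: %d distinct, %d atoms>\n",
              attr(x, "height"), length(x), sum(x)))
  for (i in seq_along(x)) cat(sprintf("  %3dx %s\n", x[i], names(x)[i]))
  invisible(x)
}

#' Centre element of a signature string
#'
#' Recovers the element symbol of the root atom from a canonical
#' signature string.
#'
#' @param s character vector of canonical signature strings.
#' @return character vector of element symbols.
#' @export
sig_center_element <- function(s) {
  root <- sub("^\\[([A-Za-z]+).*$", "\\1", s)
  paste0(toupper(substr(root, 1, 1)),
         substr(root, 2, nchar(root)))
}

## ---- internals --------------------------------------------------------

## Adjacency lists with aligned bond tokens.
.mg_adjacency <- function(mg) {
  n <- mg_n_atoms(mg)
  nb <- vector("list", n)
  bt <- vector("list", n)
  for (i in seq_len(n)) { nb[[i]] <- integer(0); bt[[i]] <- character(0) }
  if (nrow(mg$bonds)) {
    tok <- .bond_token(mg$bonds[, 3], mg$barom)
    for (e in seq_len(nrow(mg$bonds))) {
      a <- mg$bonds[e, 1]; b <- mg$bonds[e, 2]
      nb[[a]] <- c(nb[[a]], b); bt[[a]] <- c(bt[[a]], tok[e])
      nb[[b]] <- c(nb[[b]], a); bt[[b]] <- c(bt[[b]], tok[e])
    }
  }
  list(nb = nb, bt = bt)
}

## BFS distances from `root`, capped at `height` (NA beyond).
.bfs_dist <- function(nb, root, height) {
  n <- length(nb)
  d <- rep(NA_integer_, n)
  d[root] <- 0L
  frontier <- root
  depth <- 0L
  while (length(frontier) && depth < height) {
    depth <- depth + 1L
    nxt <- unique(unlist(nb[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- depth
    frontier <- nxt
  }
  d
}

.mg_dist_from <- function(mg, root, height) {
  .bfs_dist(.mg_adjacency(mg)$nb, root, height)
}

## Canonical string of the ball of radius `height` around `root`.
## D: distance vector from root (NA outside the ball).
.ball_canonical_string <- function(mg, root, D, height, adj = NULL) {
  ball <- which(!is.na(D) & D <= height)
  k <- length(ball)
  local <- integer(mg_n_atoms(mg))
  local[ball] <- seq_len(k)
  atok <- .atom_token(mg$elem[ball], mg$arom[ball], mg$charge[ball])
  layer <- D[ball]
  ## induced bonds
  keep <- mg$bonds[, 1] %in% ball & mg$bonds[, 2] %in% ball
  e1 <- local[mg$bonds[keep, 1]]
  e2 <- local[mg$bonds[keep, 2]]
  btok <- .bond_token(mg$bonds[keep, 3], mg$barom[keep])
  ## local adjacency
  nb <- vector("list", k); bt <- vector("list", k)
  for (i in seq_len(k)) { nb[[i]] <- integer(0); bt[[i]] <- character(0) }
  for (e in seq_along(e1)) {
    a <- e1[e]; b <- e2[e]
    nb[[a]] <- c(nb[[a]], b); bt[[a]] <- c(bt[[a]], btok[e])
    nb[[b]] <- c(nb[[b]], a); bt[[b]] <- c(bt[[b]], btok[e])
  }
  rloc <- local[root]
  init <- paste(layer, atok, sep = "\r")
  col <- match(init, sort(unique(init), method = "radix"))
  .canon_search(col, nb, bt, atok, rloc)
}

## Colour refinement: repeatedly augment colours with the sorted multiset
## of (bond token, neighbour colour) pairs until the partition stabilises.
.wl_refine <- function(col, nb, bt) {
  k <- length(col)
  repeat {
    key <- character(k)
    for (v in seq_len(k)) {
      nbc <- paste0(bt[[v]], col[nb[[v]]])
      key[v] <- paste(col[v], paste(sort(nbc, method = "radix"),
                                    collapse = ","), sep = "|")
    }
    newcol <- match(key, sort(unique(key), method = "radix"))
    if (length(unique(newcol)) == length(unique(col))) return(newcol)
    col <- newcol
  }
}

## Individualisation-refinement search; returns the lexicographically
## smallest serialisation over all discrete colourings explored. The
## target cell (first non-singleton colour class) is chosen canonically,
## and every member is individualised in turn, so the result does not
## depend on input atom order.
.canon_search <- function(col, nb, bt, atok, root) {
  col <- .wl_refine(col, nb, bt)
  sizes <- table(col)
  nonsing <- as.integer(names(sizes)[sizes > 1])
  if (!length(nonsing))
    return(.serialize_ordered(col, nb, bt, atok, root))
  cell <- which(col == nonsing[1])
  best <- NULL
  for (a in cell) {
    col2 <- col * 2L
    col2[a] <- col2[a] - 1L
    s <- .canon_search(match(col2, sort(unique(col2))), nb, bt, atok, root)
    ## byte-wise (locale-independent) lexicographic minimum
    if (is.null(best) || sort(c(s, best), method = "radix")[1] == s) best <- s
  }
  best
}

## SMILES-like serialisation under a discrete colouring (rank order).
.serialize_ordered <- function(rank, nb, bt, atok, root) {
  k <- length(rank)
  visited <- logical(k)
  tree_children <- vector("list", k)
  tree_bt <- vector("list", k)
  closure_at <- vector("list", k)  # list of c(number, token) per atom
  edge_seen <- new.env(hash = TRUE, parent = emptyenv())
  n_closure <- 0L
  ## pass 1: DFS in rank order, assign tree edges and closure numbers
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    ord <- order(rank[nb[[v]]])
    for (j in ord) {
      u <- nb[[v]][j]
      tokn <- bt[[v]][j]
      ekey <- paste(min(u, v), max(u, v), sep = ".")
      if (!is.null(edge_seen[[ekey]])) next
      if (visited[u]) {
        assign(ekey, TRUE, envir = edge_seen)
        n_closure <<- n_closure + 1L
        closure_at[[v]] <<- c(closure_at[[v]], list(c(n_closure, tokn)))
        closure_at[[u]] <<- c(closure_at[[u]], list(c(n_closure, tokn)))
      } else {
        assign(ekey, TRUE, envir = edge_seen)
        tree_children[[v]] <<- c(tree_children[[v]], u)
        tree_bt[[v]] <<- c(tree_bt[[v]], tokn)
        dfs1(u)
      }
    }
  }
  dfs1(root)
  ## pass 2: emit
  emit <- function(v) {
    s <- atok[v]
    cl <- closure_at[[v]]
    if (length(cl)) {
      cl <- cl[order(vapply(cl, function(x) as.integer(x[1]), 1L))]
      s <- paste0(s, paste(vapply(cl, function(x) paste0(x[2], x[1]), ""),
                           collapse = ""))
    }
    ch <- tree_children[[v]]
    for (j in seq_along(ch))
      s <- paste0(s, "(", tree_bt[[v]][j], emit(ch[j]), ")")
    s
  }
  emit(root)
}
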
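## Internal molecular graph representation.
##
## A `molgraph` is a plain list describing a connectivity-only molecular
## graph: no coordinates and, by construction, no stereochemistry.
## Aromaticity is an annotation (atom and bond flags) perceived from ring
## analysis; bond orders are kept in their Kekulé form so the graph can
## always be serialised back to a V2000 molblock that OpenBabel reads.

#' Construct a molecular graph
#'
#' Low-level constructor for the package's internal molecular graph.
#' Most users will obtain graphs from [parse_smiles()] or
#' [read_molecules()] rather than calling this directly.
#'
#' @param elem character vector of element symbols, one per atom.
#' @param charge integer vector of formal charges.
#' @param bonds integer matrix with columns `a1`, `a2`, `order`
#'   (1, 2 or 3); zero rows allowed.
#' @param arom logical vector, is the atom part of an aromatic ring.
#' @param barom logical vector, is the bond part of an aromatic ring.
#' @param explicit_h logical, do hydrogen atoms appear as graph nodes.
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(elem, charge = integer(length(elem)),
                     bonds = matrix(integer(0), 0, 3),
                     arom = logical(length(elem)),
                     barom = logical(nrow(bonds)),
                     explicit_h = FALSE) {
  stopifnot(is.character(elem), length(elem) >= 1)
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("a1", "a2", "order")))
  structure(list(elem = elem, charge = as.integer(charge), bonds = bonds,
                 arom = as.logical(arom), barom = as.logical(barom),
                 explicit_h = isTRUE(explicit_h)),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms (%d heavy), %d bonds%s>\n",
              mg_n_atoms(x), mg_n_heavy(x), nrow(x$bonds),
              if (x$explicit_h) ", explicit H" else ""))
  invisible(x)
}

#' Atom counts of a molecular graph
#'
#' `mg_n_atoms()` counts graph nodes (hydrogens only when explicit),
#' `mg_n_heavy()` counts non-hydrogen atoms, `mg_total_atoms()` counts
#' all atoms including implicit hydrogens.
#'
#' @param mg a `molgraph`.
#' @return an integer count.
#' @export
mg_n_atoms <- function(mg) length(mg$elem)

#' @rdname mg_n_atoms
#' @export
mg_n_heavy <- function(mg) sum(mg$elem != "H")

## ---- OpenBabel plumbing ----------------------------------------------

.ob_convert <- function(from, to, source, opts = NULL) {
  if (is.null(opts)) ChemmineOB::convertFormat(from, to, source)
  else ChemmineOB::convertFormat(from, to, source, options = opts)
}

## MDL old-style charge codes <-> formal charge
.chg_to_code <- function(chg) {
  code <- integer(length(chg))
  code[chg == 1L] <- 3L; code[chg == 2L] <- 2L; code[chg == 3L] <- 1L
  code[chg == -1L] <- 5L; code[chg == -2L] <- 6L; code[chg == -3L] <- 7L
  code
}

## Parse "M  CHG" lines of one molblock record into a charge vector.
.parse_mchg <- function(lines, n_atoms) {
  chg <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) chg[f[2 * i]] <- f[2 * i + 1]
  }
  chg
}

## Parse multi-record SDF text (as produced by OpenBabel) into a list of
## molgraphs named by record title. Records OpenBabel failed to parse are
## simply absent from the text, so callers map records back via titles.
.mg_from_sdf_text <- function(sdftxt, perceive_aromaticity = TRUE,
                              explicit_h = FALSE) {
  if (!nzchar(trimws(sdftxt))) return(list())
  con <- textConnection(sdftxt)
  on.exit(close(con))
  sdfstr <- ChemmineR::read.SDFstr(con)
  recs <- ChemmineR::sdfstr2list(sdfstr)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(sdfstr))
  out <- vector("list", length(recs))
  nms <- character(length(recs))
  for (i in seq_along(recs)) {
    lns <- recs[[i]]
    ## V2000 counts line: atoms in cols 1-3, bonds in cols 4-6
    n <- as.integer(substr(lns[4], 1, 3))
    m <- as.integer(substr(lns[4], 4, 6))
    if (is.na(n) || n < 1) next
    elem <- trimws(substr(lns[4 + seq_len(n)], 32, 34))
    if (m > 0) {
      bl <- lns[4 + n + seq_len(m)]
      bonds <- cbind(a1 = as.integer(substr(bl, 1, 3)),
                     a2 = as.integer(substr(bl, 4, 6)),
                     order = as.integer(substr(bl, 7, 9)))
    } else {
      bonds <- matrix(integer(0), 0, 3,
                      dimnames = list(NULL, c("a1", "a2", "order")))
    }
    chg <- .parse_mchg(lns, n)
    mg <- molgraph(elem, chg, bonds, explicit_h = explicit_h)
    if (perceive_aromaticity && m > 0)
      mg <- .mg_perceive_aromaticity(mg, sdfset[[i]])
    out[[i]] <- mg
    nms[i] <- trimws(lns[1])
  }
  keep <- !vapply(out, is.null, TRUE)
  out <- out[keep]
  names(out) <- nms[keep]
  out
}

## Aromaticity: an atom/bond is aromatic when it lies on an aromatic ring
## as judged by ChemmineR's ring perception of the Kekulé structure.
.mg_perceive_aromaticity <- function(mg, sdf) {
  n <- mg_n_atoms(mg)
  m <- nrow(mg$bonds)
  mg$arom <- logical(n)
  mg$barom <- logical(m)
  if (m == 0) return(mg)
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 7, type = "all",
                                      arom = TRUE)),
    error = function(e) NULL)
  if (is.null(r) || is.null(r$RINGS)) return(mg)
  bkey <- paste(pmin(mg$bonds[, 1], mg$bonds[, 2]),
                pmax(mg$bonds[, 1], mg$bonds[, 2]))
  for (k in seq_along(r$RINGS)) {
    if (!isTRUE(r$AROMATIC[[k]])) next
    ring <- as.integer(sub("^.*_", "", r$RINGS[[k]]))
    mg$arom[ring] <- TRUE
    nxt <- c(ring[-1], ring[1])
    rkey <- paste(pmin(ring, nxt), pmax(ring, nxt))
    mg$barom[bkey %in% rkey] <- TRUE
  }
  mg
}

## Serialise a molgraph to a V2000 molblock (zero coordinates, Kekulé
## bond orders, formal charges as both old-style codes and M CHG lines).
mg_to_molblock <- function(mg, title = "mol") {
  n <- mg_n_atoms(mg)
  m <- nrow(mg$bonds)
  header <- c(title, " npscore", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, mg$elem, .chg_to_code(mg$charge))
  bonds <- if (m) sprintf("%3d%3d%3d  0  0  0  0",
                          mg$bonds[, 1], mg$bonds[, 2], mg$bonds[, 3])
           else character(0)
  chg_idx <- which(mg$charge != 0L)
  mlines <- character(0)
  while (length(chg_idx)) {
    grp <- chg_idx[seq_len(min(8, length(chg_idx)))]
    chg_idx <- chg_idx[-seq_len(min(8, length(chg_idx)))]
    mlines <- c(mlines, paste0(sprintf("M  CHG%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp, mg$charge[grp]),
                                     collapse = "")))
  }
  paste(c(header, atoms, bonds, mlines, "M  END", "$$$$", ""), collapse = "\n")
}

## ---- derived representations -----------------------------------------

#' Canonical SMILES of a molecular graph
#'
#' The SMILES is canonical and stereochemistry-free (the internal graph
#' carries no stereo descriptors).
#'
#' @param mg a `molgraph`.
#' @return a single SMILES string.
#' @export
mg_canonical_smiles <- function(mg) {
  out <- .ob_convert("SDF", "CAN", mg_to_molblock(mg))
  smi <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  sub("[ \t].*$", "", smi)
}

## Standard InChI of the (stereo-free) graph; NA_character_ on failure.
mg_inchi <- function(mg) {
  out <- tryCatch(.ob_convert("SDF", "INCHI", mg_to_molblock(mg)),
                  error = function(e) "")
  ln <- grep("^InChI=", strsplit(out, "\n", fixed = TRUE)[[1]], value = TRUE)
  if (length(ln)) trimws(ln[1]) else NA_character_
}

mg_inchikey <- function(mg) {
  out <- tryCatch(.ob_convert("SDF", "INCHIKEY", mg_to_molblock(mg)),
                  error = function(e) "")
  key <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  key <- sub("[ \t].*$", "", key)
  if (nzchar(key)) key else NA_character_
}

#' Canonicalise a molecular graph
#'
#' Re-derives the graph from its own canonical SMILES so that identical
#' molecules (however they were entered) have byte-identical graphs.
#'
#' @param mg a `molgraph`.
#' @return a `molgraph` in canonical atom order.
#' @export
mg_canonicalize <- function(mg) {
  smi <- mg_canonical_smiles(mg)
  out <- parse_smiles(smi)
  if (is.null(out[[1]])) .stopf("canonicalisation round trip failed for %s", smi)
  out[[1]]
}

#' Make hydrogens explicit
#'
#' Returns the same molecule with every hydrogen as a graph node
#' (aromaticity re-perceived). Signature computation requires explicit
#' hydrogens; [molecular_signature()] applies this automatically.
#'
#' @param mg a `molgraph`.
#' @return a `molgraph` with `explicit_h = TRUE`.
#' @export
mg_add_hydrogens <- function(mg) {
  if (mg$explicit_h) return(mg)
  sdftxt <- .ob_convert("SDF", "SDF", mg_to_molblock(mg),
                        opts = data.frame(names = "h", args = ""))
  lst <- .mg_from_sdf_text(sdftxt, explicit_h = TRUE)
  if (!length(lst)) .stopf("hydrogen addition failed")
  lst[[1]]
}

#' Parse SMILES strings into molecular graphs
#'
#' Each SMILES is parsed with OpenBabel; stereochemistry descriptors are
#' discarded (the internal representation has none) and aromaticity is
#' perceived from ring analysis.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list of `molgraph` objects, `NULL` for unparseable entries.
#' @examples
#' mg <- parse_smiles("c1ccccc1")[[1]]
#' mg_n_atoms(mg)
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  inp <- paste0(smiles, " r", seq_along(smiles), collapse = "\n")
  sdftxt <- tryCatch(
    .ob_convert("SMI", "SDF", paste0(inp, "\n"),
                opts = data.frame(names = "e", args = "")),
    error = function(e) "")
  out <- vector("list", length(smiles))
  if (!nzchar(sdftxt)) return(out)
  lst <- .mg_from_sdf_text(sdftxt)
  idx <- suppressWarnings(as.integer(sub("^r", "", names(lst))))
  keep <- !is.na(idx) & vapply(lst, function(g) mg_n_atoms(g) > 0, TRUE)
  out[idx[keep]] <- lst[keep]
  out
}

## ---- graph utilities ---------------------------------------------------

mg_igraph <- function(mg) {
  g <- igraph::make_empty_graph(n = mg_n_atoms(mg), directed = FALSE)
  if (nrow(mg$bonds)) g <- igraph::add_edges(g, t(mg$bonds[, 1:2]))
  g
}

mg_components <- function(mg) igraph::components(mg_igraph(mg))$membership

## Induced subgraph on atom indices `idx` (bond flags preserved).
mg_induced <- function(mg, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(mg_n_atoms(mg))
  map[idx] <- seq_along(idx)
  keep <- mg$bonds[, 1] %in% idx & mg$bonds[, 2] %in% idx
  bonds <- mg$bonds[keep, , drop = FALSE]
  bonds[, 1] <- map[bonds[, 1]]
  bonds[, 2] <- map[bonds[, 2]]
  molgraph(mg$elem[idx], mg$charge[idx], bonds,
           arom = mg$arom[idx], barom = mg$barom[keep],
           explicit_h = mg$explicit_h)
}

#' Relabel atoms of a molecular graph
#'
#' Returns the same molecule with atom indices permuted: atom `i` of the
#' result is atom `perm[i]` of the input. Signature computations must be
#' invariant under this operation.
#'
#' @param mg a `molgraph`.
#' @param perm a permutation of `seq_len(mg_n_atoms(mg))`.
#' @return a `molgraph`.
#' @export
mg_permute <- function(mg, perm) {
  n <- mg_n_atoms(mg)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)
  bonds <- mg$bonds
  if (nrow(bonds)) {
    bonds[, 1] <- inv[bonds[, 1]]
    bonds[, 2] <- inv[bonds[, 2]]
  }
  molgraph(mg$elem[perm], mg$charge[perm], bonds,
           arom = mg$arom[perm], barom = mg$barom,
           explicit_h = mg$explicit_h)
}

#' Ring count (cyclomatic number) of the heavy-atom graph
#' @param mg a `molgraph`.
#' @return integer number of independent rings.
#' @export
mg_ring_count <- function(mg) {
  heavy <- which(mg$elem != "H")
  sub <- if (length(heavy) < mg_n_atoms(mg)) mg_induced(mg, heavy) else mg
  comps <- igraph::components(mg_igraph(sub))$no
  nrow(sub$bonds) - mg_n_atoms(sub) + comps
}

mg_element_counts <- function(mg) {
  c(c = sum(mg$elem == "C"), o = sum(mg$elem == "O"), n = sum(mg$elem == "N"))
}

#' @rdname mg_n_atoms
#' @export
mg_total_atoms <- function(mg) {
  if (mg$explicit_h) mg_n_atoms(mg) else mg_n_atoms(mg_add_hydrogens(mg))
}
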
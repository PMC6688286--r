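## Molecule curation: standardisation, filtering, deduplication.

#' Allowed element symbols
#'
#' The 17 element symbols a curated molecule may contain. Molecules with
#' any other element are discarded during curation.
#' @export
ALLOWED_ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Cl", "F", "As", "Se",
                      "Br", "I", "B", "Na", "Si", "K", "Fe")

#' Remove stereochemistry descriptors
#'
#' The package's molecular graphs never carry stereo descriptors: wedge,
#' parity and double-bond geometry information is discarded when a
#' molecule is parsed. This operation makes the step explicit in the
#' curation pipeline: given a SMILES string it returns the parsed,
#' stereo-free graph; given a `molgraph` it returns it unchanged.
#'
#' @param x a SMILES string or a `molgraph`.
#' @return a `molgraph` with no stereochemistry.
#' @examples
#' mg <- strip_stereochemistry("C[C@@H](N)C(=O)O")
#' mg_canonical_smiles(mg)  # same structure as CC(N)C(=O)O
#' @export
strip_stereochemistry <- function(x) {
  if (is.character(x)) {
    g <- parse_smiles(x[1])[[1]]
    if (is.null(g)) .stopf("unparseable SMILES: %s", x[1])
    return(g)
  }
  stopifnot(inherits(x, "molgraph"))
  x
}

#' Keep the largest connected component
#'
#' Selects the connected component with the most heavy atoms; ties are
#' broken by total atom count (hydrogens included), then by the
#' lexicographically smallest canonical SMILES.
#'
#' @param mg a `molgraph`.
#' @return a `molgraph` containing one connected component.
#' @export
largest_component <- function(mg) {
  memb <- mg_components(mg)
  if (max(memb) == 1) return(mg)
  comps <- split(seq_along(memb), memb)
  heavy <- vapply(comps, function(ix) sum(mg$elem[ix] != "H"), 1L)
  best <- which(heavy == max(heavy))
  if (length(best) > 1) {
    cand <- lapply(comps[best], function(ix) mg_induced(mg, ix))
    tot <- vapply(cand, mg_total_atoms, 1L)
    best2 <- which(tot == max(tot))
    if (length(best2) > 1) {
      smi <- vapply(cand[best2], mg_canonical_smiles, "")
      best2 <- best2[order(smi, method = "radix")[1]]
    }
    return(cand[[best2]])
  }
  mg_induced(mg, comps[[best]])
}

#' Element and size filter
#'
#' A molecule passes when it has at least `min_atoms` heavy atoms (or
#' total atoms when `count_hydrogens = TRUE`) and every element belongs
#' to [ALLOWED_ELEMENTS].
#'
#' @param mg a single-component `molgraph`.
#' @param min_atoms minimum atom count (default 6; the boundary passes).
#' @param count_hydrogens count hydrogens towards the size threshold?
#'   Defaults to `FALSE`: heavy-atom counting is stable across input
#'   representations.
#' @return `TRUE` or `FALSE`.
#' @export
filter_elements_and_size <- function(mg, min_atoms = 6L,
                                     count_hydrogens = FALSE) {
  if (!all(mg$elem %in% ALLOWED_ELEMENTS)) return(FALSE)
  n <- if (count_hydrogens) mg_total_atoms(mg) else mg_n_heavy(mg)
  n >= min_atoms
}

#' Structural identity key
#'
#' Standard InChI of the stereochemistry-free graph; equal for any two
#' inputs that are identical graphs ignoring stereochemistry and atom
#' order. Used to deduplicate molecules across source databases.
#'
#' @param mg a `molgraph`.
#' @return the InChI string, or `NA_character_` when generation fails.
#' @export
structural_key <- function(mg) mg_inchi(mg)

#' Curate a set of molecule records
#'
#' Applies the curation pipeline to each record in order: parse, strip
#' stereochemistry, keep the largest connected component, apply the
#' element/size filter, compute the structural key. Records sharing a
#' structural key are merged into one curated molecule whose sources are
#' the union; the merged molecule is a natural product when any source
#' record is labelled NP (label conflicts are logged). BIOGENIC records
#' are curated and kept but join neither training class. Finally linear
#' and circular sugar moieties are detected and removed to produce the
#' aglycone variant of each molecule.
#'
#' @param records a `molecule_records` data.frame from [read_molecules()]
#'   (or any data.frame with columns `record_id`, `source_db`,
#'   `source_id`, `smiles`, `status`).
#' @param min_atoms,count_hydrogens size filter, see
#'   [filter_elements_and_size()].
#' @param sugar_opts detection thresholds, see [sugar_options()].
#' @return an object of class `curated_set`: a list with elements
#'   `molecules` (data.frame, one row per unique structure), `graphs`
#'   (per-molecule list of graphs and sugar flags), `sources`
#'   (data.frame mapping molecules to source records), `rejections`
#'   (data.frame with reasons) and `report` (named counters: `parsed`,
#'   `rejected_parse`, `rejected_size`, `rejected_element`, `unique`,
#'   plus `label_conflicts`).
#' @export
curate <- function(records, min_atoms = 6L, count_hydrogens = FALSE,
                   sugar_opts = sugar_options()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  graphs <- attr(records, "graphs")
  if (is.null(graphs))
    graphs <- if (n) parse_smiles(records$smiles) else list()
  report <- c(parsed = n, rejected_parse = 0L, rejected_size = 0L,
              rejected_element = 0L, unique = 0L)
  rej <- list()
  by_key <- new.env(hash = TRUE, parent = emptyenv())
  key_order <- character(0)
  for (i in seq_len(n)) {
    mg <- graphs[[i]]
    rid <- records$record_id[i]
    if (is.null(mg)) {
      report["rejected_parse"] <- report["rejected_parse"] + 1L
      rej[[length(rej) + 1L]] <- c(rid, "unparseable")
      next
    }
    mg <- largest_component(mg)
    if (!all(mg$elem %in% ALLOWED_ELEMENTS)) {
      report["rejected_element"] <- report["rejected_element"] + 1L
      rej[[length(rej) + 1L]] <- c(rid, "disallowed element")
      next
    }
    if (!filter_elements_and_size(mg, min_atoms, count_hydrogens)) {
      report["rejected_size"] <- report["rejected_size"] + 1L
      rej[[length(rej) + 1L]] <- c(rid, "too small")
      next
    }
    mg <- mg_canonicalize(mg)
    key <- structural_key(mg)
    if (is.na(key)) {
      report["rejected_parse"] <- report["rejected_parse"] + 1L
      rej[[length(rej) + 1L]] <- c(rid, "InChI generation failed")
      next
    }
    ek <- paste0("k", match(key, key_order))
    if (is.na(match(key, key_order))) {
      key_order <- c(key_order, key)
      ek <- paste0("k", length(key_order))
      assign(ek, list(mg = mg, key = key, idx = integer(0)), envir = by_key)
    }
    entry <- get(ek, envir = by_key)
    entry$idx <- c(entry$idx, i)
    assign(ek, entry, envir = by_key)
  }
  nu <- length(key_order)
  report["unique"] <- nu
  conflicts <- character(0)
  mols <- vector("list", nu)
  gout <- vector("list", nu)
  src <- vector("list", nu)
  for (j in seq_len(nu)) {
    entry <- get(paste0("k", j), envir = by_key)
    mg <- entry$mg
    idx <- entry$idx
    st <- records$status[idx]
    is_np <- any(st == "NP")
    if (is_np && any(st == "SM")) {
      conflicts <- c(conflicts, entry$key)
      .warnf("NP/SM label conflict for %s; resolved to NP", entry$key)
    }
    train_class <- if (is_np) "NP" else if (any(st == "SM")) "SM" else "NONE"
    sg <- remove_sugars(mg, sugar_opts, min_atoms = min_atoms)
    mg_h <- mg_add_hydrogens(mg)
    mg_h_ns <- if (!is.null(sg$aglycone)) mg_add_hydrogens(sg$aglycone)
    contains_sugar <- sg$had_circular_sugar || sg$had_linear_sugar
    ec <- mg_element_counts(mg)
    heavy <- mg_n_heavy(mg)
    total <- mg_n_atoms(mg_h)
    mols[[j]] <- data.frame(
      molecule_id = j, structural_key = entry$key,
      smiles = mg_canonical_smiles(mg), is_np = is_np,
      train_class = train_class, contains_sugar = contains_sugar,
      heavy_atom_count = heavy, total_atom_count = total,
      heavy_atom_count_no_sugar =
        if (!contains_sugar) heavy
        else if (is.null(sg$aglycone)) NA_integer_
        else mg_n_heavy(sg$aglycone),
      total_atom_count_no_sugar =
        if (!contains_sugar) total
        else if (is.null(sg$aglycone)) NA_integer_
        else mg_n_atoms(mg_h_ns),
      ring_count = mg_ring_count(mg),
      c_count = ec[["c"]], o_count = ec[["o"]], n_count = ec[["n"]],
      n_sources = length(idx), stringsAsFactors = FALSE)
    gout[[j]] <- list(mg = mg, mg_h = mg_h,
                      aglycone = sg$aglycone, aglycone_h = mg_h_ns,
                      had_circular_sugar = sg$had_circular_sugar,
                      had_linear_sugar = sg$had_linear_sugar,
                      removed_atom_count = sg$removed_atom_count)
    src[[j]] <- data.frame(molecule_id = j,
                           record_id = records$record_id[idx],
                           source_db = records$source_db[idx],
                           source_id = records$source_id[idx],
                           status = st, stringsAsFactors = FALSE)
  }
  rejections <- if (length(rej)) {
    m <- do.call(rbind, rej)
    data.frame(record_id = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(record_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  structure(list(
    molecules = if (nu) do.call(rbind, mols) else NULL,
    graphs = gout,
    sources = if (nu) do.call(rbind, src) else
      data.frame(molecule_id = integer(0), record_id = character(0),
                 source_db = character(0), source_id = character(0),
                 status = character(0), stringsAsFactors = FALSE),
    rejections = rejections,
    report = c(as.list(report), list(label_conflicts = conflicts))),
    class = "curated_set")
}

#' @export
print.curated_set <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<curated_set: %d unique molecules from %d records ",
                     "(%d parse, %d size, %d element rejections)>\n"),
              r$unique, r$parsed, r$rejected_parse, r$rejected_size,
              r$rejected_element))
  invisible(x)
}
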
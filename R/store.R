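## File-backed relational store.
##
## Five tables, each one TSV file in the store directory, plus meta.json
## with the run configuration and corpus totals:
##
##   ori_molecule          raw records as submitted (may be redundant)
##   molecule              unique curated structures + descriptors/scores
##   fragment_with_sugar   trained fragments, sugars retained
##   fragment_without_sugar trained fragments, aglycones
##   molecule_fragment_cpd molecule/fragment occurrence relations
##
## The equivalent SQL DDL ships in inst/extdata/schema.sql. Score columns
## are serialised with 17 significant digits so dump/load round trips are
## lossless.

.STORE_TABLES <- c("ori_molecule", "molecule", "fragment_with_sugar",
                   "fragment_without_sugar", "molecule_fragment_cpd")

.STORE_COLS <- list(
  ori_molecule = c(ori_id = "integer", source_id = "character",
                   smiles = "character", inchikey = "character",
                   submission_date = "character", source_db = "character",
                   status = "character"),
  molecule = c(molecule_id = "integer", smiles = "character",
               inchi = "character", is_np = "logical",
               train_class = "character", contains_sugar = "logical",
               score_with_sugar = "numeric", score_without_sugar = "numeric",
               heavy_atom_count = "integer", total_atom_count = "integer",
               heavy_atom_count_no_sugar = "integer",
               total_atom_count_no_sugar = "integer",
               ring_count = "integer", n_repeated_fragments = "integer",
               c_count = "integer", o_count = "integer", n_count = "integer"),
  fragment_with_sugar = c(fragment_id = "integer",
                          canonical_string = "character",
                          height = "integer", np_count = "integer",
                          sm_count = "integer", score = "numeric"),
  fragment_without_sugar = c(fragment_id = "integer",
                             canonical_string = "character",
                             height = "integer", np_count = "integer",
                             sm_count = "integer", score = "numeric"),
  molecule_fragment_cpd = c(molecule_id = "integer", fragment_id = "integer",
                            sugar_mode = "character", occurrence = "integer"))

.empty_table <- function(name) {
  cols <- .STORE_COLS[[name]]
  df <- as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                      stringsAsFactors = FALSE)
  names(df) <- names(cols)
  df
}

#' Create an empty NP-likeness store
#'
#' @param path directory to create.
#' @param height signature height used throughout the store.
#' @param pseudocount,log_base fragment score parameters.
#' @param min_atoms curation size threshold.
#' @param sugar_opts sugar detection thresholds, see [sugar_options()].
#' @param overwrite replace an existing store?
#' @return an `np_store` handle.
#' @export
store_create <- function(path, height = 2L, pseudocount = 1,
                         log_base = "natural", min_atoms = 6L,
                         sugar_opts = sugar_options(), overwrite = FALSE) {
  if (dir.exists(path)) {
    if (!overwrite) .stopf("store already exists: %s", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  meta <- list(schema_version = 1L, height = as.integer(height),
               pseudocount = pseudocount, log_base = log_base,
               min_atoms = as.integer(min_atoms), sugar_opts = sugar_opts,
               trained = FALSE,
               totals = list(WITH_SUGAR = list(np_total = 0L, sm_total = 0L),
                             WITHOUT_SUGAR = list(np_total = 0L,
                                                  sm_total = 0L)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  st <- structure(list(path = normalizePath(path)), class = "np_store")
  for (tb in .STORE_TABLES) store_write_table(st, tb, .empty_table(tb))
  st
}

#' Open an existing store
#' @param path store directory.
#' @return an `np_store` handle.
#' @export
store_open <- function(path) {
  if (!dir.exists(path) || !file.exists(file.path(path, "meta.json")))
    .stopf("not a store directory: %s", path)
  structure(list(path = normalizePath(path)), class = "np_store")
}

#' @export
print.np_store <- function(x, ...) {
  meta <- store_meta(x)
  mol <- store_table(x, "molecule")
  cat(sprintf("<np_store %s: %d molecules, trained=%s, height=%d>\n",
              x$path, nrow(mol), meta$trained, meta$height))
  invisible(x)
}

#' Store metadata
#' @param store an `np_store`.
#' @return named list of configuration and totals.
#' @export
store_meta <- function(store) {
  jsonlite::read_json(file.path(store$path, "meta.json"),
                      simplifyVector = TRUE)
}

.store_write_meta <- function(store, meta) {
  jsonlite::write_json(meta, file.path(store$path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a store table
#' @param store an `np_store`.
#' @param name one of the five table names.
#' @return the table as a data.frame.
#' @export
store_table <- function(store, name) {
  name <- match.arg(name, .STORE_TABLES)
  read_tsv(file.path(store$path, paste0(name, ".tsv")),
           colClasses = unname(.STORE_COLS[[name]]))
}

#' Write a store table (internal plumbing, exported for tooling)
#' @param store an `np_store`.
#' @param name table name.
#' @param df table content with the schema columns.
#' @return the store, invisibly.
#' @export
store_write_table <- function(store, name, df) {
  name <- match.arg(name, .STORE_TABLES)
  cols <- .STORE_COLS[[name]]
  df <- df[, names(cols), drop = FALSE]
  for (cn in names(cols)[cols == "numeric"]) {
    v <- df[[cn]]
    df[[cn]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  write_tsv(df, file.path(store$path, paste0(name, ".tsv")))
  invisible(store)
}

#' Ingest curated molecules into the store
#'
#' Raw records are appended to `ori_molecule` (which may be redundant);
#' curated molecules are upserted into `molecule` keyed on structural
#' identity (InChI); the atom signatures of every new molecule are
#' inserted into the two fragment tables (scores pending) and their
#' occurrences into `molecule_fragment_cpd`. Call [retrain_scores()]
#' afterwards to (re)compute fragment and molecule scores.
#'
#' @param store an `np_store`.
#' @param curated a `curated_set` from [curate()].
#' @param raw optional `molecule_records` the set was curated from.
#' @return the store, invisibly.
#' @export
ingest <- function(store, curated, raw = NULL) {
  stopifnot(inherits(store, "np_store"))
  meta <- store_meta(store)
  height <- meta$height
  if (!is.null(raw)) {
    ori <- store_table(store, "ori_molecule")
    graphs <- attr(raw, "graphs")
    keys <- vapply(seq_len(nrow(raw)), function(i) {
      if (!is.null(graphs) && !is.null(graphs[[i]]))
        mg_inchikey(graphs[[i]]) else NA_character_
    }, "")
    add <- data.frame(ori_id = nrow(ori) + seq_len(nrow(raw)),
                      source_id = raw$source_id, smiles = raw$smiles,
                      inchikey = keys,
                      submission_date = raw$submission_date,
                      source_db = raw$source_db, status = raw$status,
                      stringsAsFactors = FALSE)
    store_write_table(store, "ori_molecule", rbind(ori, add))
  }
  if (is.null(curated) || is.null(curated$molecules))
    return(invisible(store))
  mol <- store_table(store, "molecule")
  cpd <- store_table(store, "molecule_fragment_cpd")
  frags <- list(WITH_SUGAR = store_table(store, "fragment_with_sugar"),
                WITHOUT_SUGAR = store_table(store, "fragment_without_sugar"))
  new <- which(!(curated$molecules$structural_key %in% mol$inchi))
  next_id <- if (nrow(mol)) max(mol$molecule_id) + 1L else 1L
  mol_rows <- list()
  cpd_rows <- list()
  sig_new <- list(WITH_SUGAR = character(0), WITHOUT_SUGAR = character(0))
  sig_cache <- list()
  for (j in new) {
    cm <- curated$molecules[j, ]
    g <- curated$graphs[[j]]
    mid <- next_id
    next_id <- next_id + 1L
    sigs <- list(WITH_SUGAR = molecular_signature(g$mg_h, height),
                 WITHOUT_SUGAR = if (!is.null(g$aglycone_h))
                   molecular_signature(g$aglycone_h, height))
    n_rep <- {
      s <- sigs$WITH_SUGAR
      sum(s >= 2L & attr(s, "center_element") != "H")
    }
    mol_rows[[length(mol_rows) + 1L]] <- data.frame(
      molecule_id = mid, smiles = cm$smiles, inchi = cm$structural_key,
      is_np = cm$is_np, train_class = cm$train_class,
      contains_sugar = cm$contains_sugar,
      score_with_sugar = NA_real_, score_without_sugar = NA_real_,
      heavy_atom_count = cm$heavy_atom_count,
      total_atom_count = cm$total_atom_count,
      heavy_atom_count_no_sugar = cm$heavy_atom_count_no_sugar,
      total_atom_count_no_sugar = cm$total_atom_count_no_sugar,
      ring_count = cm$ring_count, n_repeated_fragments = n_rep,
      c_count = cm$c_count, o_count = cm$o_count, n_count = cm$n_count,
      stringsAsFactors = FALSE)
    for (mode in names(sigs)) {
      s <- sigs[[mode]]
      if (is.null(s)) next
      sig_new[[mode]] <- c(sig_new[[mode]], names(s))
      sig_cache[[paste(mid, mode)]] <- s
    }
  }
  ## assign fragment ids: existing kept, new strings appended in
  ## byte-sorted order
  for (mode in names(frags)) {
    tb <- frags[[mode]]
    newsig <- sort(unique(sig_new[[mode]]), method = "radix")
    newsig <- setdiff(newsig, tb$canonical_string)
    if (length(newsig)) {
      base <- if (nrow(tb)) max(tb$fragment_id) else 0L
      frags[[mode]] <- rbind(tb, data.frame(
        fragment_id = base + seq_along(newsig), canonical_string = newsig,
        height = height, np_count = 0L, sm_count = 0L, score = NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  for (key in names(sig_cache)) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    mid <- as.integer(parts[1]); mode <- parts[2]
    s <- sig_cache[[key]]
    fid <- frags[[mode]]$fragment_id[match(names(s),
                                           frags[[mode]]$canonical_string)]
    cpd_rows[[length(cpd_rows) + 1L]] <- data.frame(
      molecule_id = mid, fragment_id = fid, sugar_mode = mode,
      occurrence = as.integer(s), stringsAsFactors = FALSE)
  }
  if (length(mol_rows)) mol <- rbind(mol, do.call(rbind, mol_rows))
  if (length(cpd_rows)) cpd <- rbind(cpd, do.call(rbind, cpd_rows))
  store_write_table(store, "molecule", mol)
  store_write_table(store, "molecule_fragment_cpd", cpd)
  store_write_table(store, "fragment_with_sugar", frags$WITH_SUGAR)
  store_write_table(store, "fragment_without_sugar", frags$WITHOUT_SUGAR)
  invisible(store)
}

#' Recompute all fragment and molecule scores from stored counts
#'
#' Recounts every fragment's NP/SM occurrences from the
#' molecule/fragment relations and the molecules' training classes,
#' recomputes every Frag score, and rescores every stored molecule in
#' both sugar modes. Idempotent: retraining an unchanged store leaves
#' every table byte-identical.
#'
#' @param store an `np_store`.
#' @return invisibly, a list with the two updated `fragment_table`s.
#' @export
retrain_scores <- function(store) {
  stopifnot(inherits(store, "np_store"))
  meta <- store_meta(store)
  mol <- store_table(store, "molecule")
  if (nrow(mol) == 0) .stopf("store is empty; ingest molecules first")
  cpd <- store_table(store, "molecule_fragment_cpd")
  out <- list()
  for (mode in .SUGAR_MODES) {
    tbname <- if (mode == "WITH_SUGAR") "fragment_with_sugar"
              else "fragment_without_sugar"
    tb <- store_table(store, tbname)
    sub <- cpd[cpd$sugar_mode == mode, , drop = FALSE]
    cls <- mol$train_class[match(sub$molecule_id, mol$molecule_id)]
    np_total <- length(unique(sub$molecule_id[cls == "NP"]))
    sm_total <- length(unique(sub$molecule_id[cls == "SM"]))
    if (np_total == 0 || sm_total == 0)
      .stopf("cannot train: a class is empty in mode %s", mode)
    npc <- tapply(sub$occurrence[cls == "NP"], sub$fragment_id[cls == "NP"],
                  sum)
    smc <- tapply(sub$occurrence[cls == "SM"], sub$fragment_id[cls == "SM"],
                  sum)
    tb$np_count <- as.integer(npc[as.character(tb$fragment_id)])
    tb$np_count[is.na(tb$np_count)] <- 0L
    tb$sm_count <- as.integer(smc[as.character(tb$fragment_id)])
    tb$sm_count[is.na(tb$sm_count)] <- 0L
    seen <- tb$np_count + tb$sm_count >= 1L
    tb$score <- NA_real_
    tb$score[seen] <- fragment_score(tb$np_count[seen], tb$sm_count[seen],
                                     np_total, sm_total, meta$pseudocount,
                                     meta$log_base)
    store_write_table(store, tbname, tb)
    ## rescore every molecule: mean of known fragment scores, weighted
    ## by occurrence
    sc <- tb$score[match(sub$fragment_id, tb$fragment_id)]
    ok <- !is.na(sc)
    num <- tapply(sub$occurrence[ok] * sc[ok], sub$molecule_id[ok], sum)
    den <- tapply(sub$occurrence[ok], sub$molecule_id[ok], sum)
    val <- num / den
    col <- if (mode == "WITH_SUGAR") "score_with_sugar"
           else "score_without_sugar"
    mol[[col]] <- as.numeric(val[as.character(mol$molecule_id)])
    meta$totals[[mode]] <- list(np_total = np_total, sm_total = sm_total)
    attr_tb <- structure(tb[seen, , drop = FALSE], np_total = np_total,
                         sm_total = sm_total, sugar_mode = mode,
                         log_base = meta$log_base,
                         pseudocount = meta$pseudocount,
                         class = c("fragment_table", "data.frame"))
    out[[mode]] <- attr_tb
  }
  store_write_table(store, "molecule", mol)
  meta$trained <- TRUE
  .store_write_meta(store, meta)
  invisible(out)
}

#' Extract a trained fragment table from the store
#'
#' @param store an `np_store`.
#' @param sugar_mode `"WITH_SUGAR"` or `"WITHOUT_SUGAR"`.
#' @return a `fragment_table` (rows with no occurrences in either
#'   training class are omitted).
#' @export
store_fragment_table <- function(store,
                                 sugar_mode = c("WITHOUT_SUGAR",
                                                "WITH_SUGAR")) {
  sugar_mode <- match.arg(sugar_mode)
  meta <- store_meta(store)
  if (!isTRUE(meta$trained)) .stopf("store is not trained")
  tbname <- if (sugar_mode == "WITH_SUGAR") "fragment_with_sugar"
            else "fragment_without_sugar"
  tb <- store_table(store, tbname)
  tb <- tb[!is.na(tb$score), , drop = FALSE]
  rownames(tb) <- NULL
  structure(tb,
            np_total = as.integer(meta$totals[[sugar_mode]]$np_total),
            sm_total = as.integer(meta$totals[[sugar_mode]]$sm_total),
            sugar_mode = sugar_mode, log_base = meta$log_base,
            pseudocount = as.numeric(meta$pseudocount),
            class = c("fragment_table", "data.frame"))
}

#' Look up fragment scores by signature string
#'
#' @param store an `np_store`.
#' @param signatures character vector of canonical signature strings.
#' @param sugar_mode which fragment table to query.
#' @return a named numeric vector containing only the signatures present
#'   in the table; callers detect unknown fragments by absence.
#' @export
query_fragment_scores <- function(store, signatures,
                                  sugar_mode = c("WITHOUT_SUGAR",
                                                 "WITH_SUGAR")) {
  sugar_mode <- match.arg(sugar_mode)
  tb <- store_fragment_table(store, sugar_mode)
  idx <- match(signatures, tb$canonical_string)
  found <- !is.na(idx)
  stats::setNames(tb$score[idx[found]], signatures[found])
}

#' Dump a store to a directory of TSV files
#' @param store an `np_store`.
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
store_dump <- function(store, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in .STORE_TABLES)
    file.copy(file.path(store$path, paste0(tb, ".tsv")),
              file.path(dir, paste0(tb, ".tsv")), overwrite = TRUE)
  file.copy(file.path(store$path, "meta.json"),
            file.path(dir, "meta.json"), overwrite = TRUE)
  invisible(dir)
}

#' Load a dumped store into a fresh store directory
#' @param dump directory produced by [store_dump()].
#' @param path new store directory.
#' @return an `np_store` handle on the loaded copy.
#' @export
store_load <- function(dump, path) {
  if (!file.exists(file.path(dump, "meta.json")))
    .stopf("not a store dump: %s", dump)
  if (dir.exists(path)) .stopf("target exists: %s", path)
  dir.create(path, recursive = TRUE)
  for (tb in .STORE_TABLES) {
    src <- file.path(dump, paste0(tb, ".tsv"))
    if (!file.exists(src)) .stopf("dump is missing table %s", tb)
    file.copy(src, file.path(path, paste0(tb, ".tsv")))
  }
  file.copy(file.path(dump, "meta.json"), file.path(path, "meta.json"))
  st <- store_open(path)
  validate_store(st)
  st
}

#' Check store referential integrity
#'
#' Verifies that every molecule/fragment relation references existing
#' rows, occurrences are positive, structural keys are unique, and the
#' per-molecule sum of WITH_SUGAR occurrences equals the molecule's
#' total atom count.
#'
#' @param store an `np_store`.
#' @return `TRUE` (invisibly); stops with a message on violation.
#' @export
validate_store <- function(store) {
  mol <- store_table(store, "molecule")
  cpd <- store_table(store, "molecule_fragment_cpd")
  fws <- store_table(store, "fragment_with_sugar")
  fns <- store_table(store, "fragment_without_sugar")
  if (anyDuplicated(mol$inchi))
    .stopf("duplicate structural keys in molecule table")
  if (any(!(cpd$molecule_id %in% mol$molecule_id)))
    .stopf("cpd references missing molecules")
  ws <- cpd$sugar_mode == "WITH_SUGAR"
  if (any(!(cpd$fragment_id[ws] %in% fws$fragment_id)) ||
      any(!(cpd$fragment_id[!ws] %in% fns$fragment_id)))
    .stopf("cpd references missing fragments")
  if (any(cpd$occurrence < 1L)) .stopf("non-positive occurrence count")
  tot <- tapply(cpd$occurrence[ws], cpd$molecule_id[ws], sum)
  mtot <- mol$total_atom_count[match(as.integer(names(tot)),
                                     mol$molecule_id)]
  if (any(as.integer(tot) != mtot))
    .stopf("occurrence sums disagree with total atom counts")
  invisible(TRUE)
}
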
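## Fragment frequency training and NP-likeness scoring.
##
## A fragment i with NPi occurrences among natural products and SMi among
## synthetic molecules (occurrences counted with multiplicity), in corpora
## of NPt natural products and SMt synthetic molecules, gets the score
##
##   Frag_i = log[ (NPi + p) / (SMi + p) * SMt / NPt ]
##
## with additive pseudocount p (default 1) applied to the per-fragment
## counts only: the raw ratio is undefined whenever a fragment is absent
## from one class, which is common, and with equal corpus sizes the
## pseudocount preserves the zero score of balanced fragments. The
## NP-likeness of a molecule is the mean fragment score over all its atom
## signatures that are present in the table; unknown fragments raise an
## alert and are excluded from both the numerator and the denominator.

.SUGAR_MODES <- c("WITH_SUGAR", "WITHOUT_SUGAR")
.LOG_BASES <- c("natural", "10")

#' Fragment frequency score
#'
#' @param np_count,sm_count occurrences of the fragment among natural
#'   products / synthetic molecules (multiplicities included).
#' @param np_total,sm_total number of molecules in each training class.
#' @param pseudocount additive smoothing on the per-fragment counts
#'   (default 1; 0 reproduces the unsmoothed log ratio).
#' @param log_base `"natural"` or `"10"`.
#' @return numeric score(s); vectorised over the count arguments.
#' @examples
#' fragment_score(10, 10, 100, 100)              # balanced: 0
#' fragment_score(20, 5, 100, 100, pseudocount = 0)  # log 4
#' @export
fragment_score <- function(np_count, sm_count, np_total, sm_total,
                           pseudocount = 1, log_base = c("natural", "10")) {
  log_base <- match.arg(log_base)
  if (np_total < 1 || sm_total < 1)
    .stopf("class totals must be >= 1")
  if (any(np_count + sm_count < 1))
    .stopf("a fragment must occur in at least one class")
  r <- log((np_count + pseudocount) / (sm_count + pseudocount) *
           sm_total / np_total)
  if (log_base == "10") r <- r / log(10)
  r
}

## Resolve a corpus argument into a list of explicit-H graphs for a mode.
.corpus_graphs <- function(x, sugar_mode, class = NULL) {
  if (inherits(x, "curated_set")) {
    sel <- if (is.null(class)) seq_along(x$graphs)
           else which(x$molecules$train_class == class)
    gs <- lapply(x$graphs[sel], function(g)
      if (sugar_mode == "WITH_SUGAR") g$mg_h else g$aglycone_h)
  } else if (is.list(x)) {
    gs <- lapply(x, function(g) {
      if (is.null(g)) return(NULL)
      stopifnot(inherits(g, "molgraph"))
      if (sugar_mode == "WITH_SUGAR") mg_add_hydrogens(g)
      else {
        sr <- remove_sugars(g)
        if (is.null(sr$aglycone)) NULL else mg_add_hydrogens(sr$aglycone)
      }
    })
  } else .stopf("expected a curated_set or a list of molgraphs")
  gs
}

#' Count fragment occurrences in two labelled corpora
#'
#' @param np_mols,sm_mols the natural-product and synthetic corpora:
#'   either `curated_set` objects (their NP / SM training members are
#'   used) or lists of `molgraph` objects.
#' @param height signature height.
#' @param sugar_mode `"WITH_SUGAR"` (molecules as curated) or
#'   `"WITHOUT_SUGAR"` (aglycones; molecules that are entirely sugar are
#'   skipped and reported via a message).
#' @return a list with `counts` (data.frame: `canonical_string`,
#'   `np_count`, `sm_count`), `np_total`, `sm_total` (molecule counts,
#'   not occurrence sums), `height`, `sugar_mode`.
#' @export
count_fragments <- function(np_mols, sm_mols, height = 2L,
                            sugar_mode = c("WITHOUT_SUGAR", "WITH_SUGAR")) {
  sugar_mode <- match.arg(sugar_mode)
  gs_np <- .corpus_graphs(np_mols, sugar_mode, "NP")
  gs_sm <- .corpus_graphs(sm_mols, sugar_mode, "SM")
  skip_np <- sum(vapply(gs_np, is.null, TRUE))
  skip_sm <- sum(vapply(gs_sm, is.null, TRUE))
  gs_np <- gs_np[!vapply(gs_np, is.null, TRUE)]
  gs_sm <- gs_sm[!vapply(gs_sm, is.null, TRUE)]
  if (skip_np + skip_sm > 0)
    .msgf("count_fragments: skipped %d NP and %d SM molecules with no non-sugar remainder",
          skip_np, skip_sm)
  if (!length(gs_np) || !length(gs_sm))
    .stopf("both training classes must be non-empty")
  acc <- function(gs) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (g in gs) {
      sig <- molecular_signature(g, height)
      for (i in seq_along(sig)) {
        s <- names(sig)[i]
        env[[s]] <- (env[[s]] %||% 0L) + sig[[i]]
      }
    }
    env
  }
  e_np <- acc(gs_np)
  e_sm <- acc(gs_sm)
  keys <- sort(unique(c(ls(e_np), ls(e_sm))), method = "radix")
  counts <- data.frame(
    canonical_string = keys,
    np_count = vapply(keys, function(k) e_np[[k]] %||% 0L, 1L),
    sm_count = vapply(keys, function(k) e_sm[[k]] %||% 0L, 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, np_total = length(gs_np), sm_total = length(gs_sm),
       height = as.integer(height), sugar_mode = sugar_mode)
}

#' Train a fragment score table
#'
#' Counts fragments in both corpora and attaches Frag scores. Warns when
#' class sizes are imbalanced by more than a factor of 10 (the SMt/NPt
#' term corrects for imbalance, but extreme imbalance starves one class
#' of fragment coverage).
#'
#' @inheritParams count_fragments
#' @inheritParams fragment_score
#' @param include_h_centers keep hydrogen-centred fragments? Default
#'   `TRUE`; they are part of the trained table and of the score
#'   denominator.
#' @return a `fragment_table`: a data.frame with columns `fragment_id`,
#'   `canonical_string`, `height`, `np_count`, `sm_count`, `score` and
#'   attributes `np_total`, `sm_total`, `sugar_mode`, `log_base`,
#'   `pseudocount`.
#' @export
train_fragment_table <- function(np_mols, sm_mols, height = 2L,
                                 sugar_mode = c("WITHOUT_SUGAR", "WITH_SUGAR"),
                                 pseudocount = 1,
                                 log_base = c("natural", "10"),
                                 include_h_centers = TRUE) {
  sugar_mode <- match.arg(sugar_mode)
  log_base <- match.arg(log_base)
  cf <- count_fragments(np_mols, sm_mols, height, sugar_mode)
  if (max(cf$np_total, cf$sm_total) > 10 * min(cf$np_total, cf$sm_total))
    .warnf("class imbalance exceeds 10x (%d NP vs %d SM)",
           cf$np_total, cf$sm_total)
  df <- cf$counts
  if (!include_h_centers)
    df <- df[sig_center_element(df$canonical_string) != "H", , drop = FALSE]
  df$score <- fragment_score(df$np_count, df$sm_count, cf$np_total,
                             cf$sm_total, pseudocount, log_base)
  df <- data.frame(fragment_id = seq_len(nrow(df)),
                   canonical_string = df$canonical_string,
                   height = cf$height, np_count = df$np_count,
                   sm_count = df$sm_count, score = df$score,
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(df, np_total = cf$np_total, sm_total = cf$sm_total,
            sugar_mode = sugar_mode, log_base = log_base,
            pseudocount = pseudocount,
            class = c("fragment_table", "data.frame"))
}

#' @export
print.fragment_table <- function(x, ...) {
  cat(sprintf("<fragment_table: %d fragments h=%d %s; NPt=%d SMt=%d log=%s p=%g>\n",
              nrow(x), x$height[1] %||% NA, attr(x, "sugar_mode"),
              attr(x, "np_total"), attr(x, "sm_total"),
              attr(x, "log_base"), attr(x, "pseudocount")))
  invisible(x)
}

#' Score one molecule against a fragment table
#'
#' Computes the molecular signature (on the aglycone when the table was
#' trained without sugars), sums the table scores of the matched
#' fragments with multiplicity and normalises by the number of fragment
#' occurrences used. Fragments absent from the table are excluded from
#' numerator and denominator, counted, and flagged with an alert.
#'
#' @param mol a `molgraph` (heavy-atom form; explicit hydrogens are
#'   handled internally).
#' @param table a `fragment_table`.
#' @param record_id identifier copied into the result.
#' @return a list of class `score_result`: `record_id`, `np_likeness`
#'   (NA when no fragment of the molecule is known), `n_fragments_used`,
#'   `n_unknown_fragments`, `alerts` (character vector).
#' @export
score_molecule <- function(mol, table, record_id = "mol") {
  stopifnot(inherits(mol, "molgraph"), inherits(table, "fragment_table"))
  height <- if (nrow(table)) table$height[1] else 2L
  alerts <- character(0)
  g <- mol
  if (g$explicit_h) {
    heavy <- which(g$elem != "H")
    g <- if (length(heavy) < mg_n_atoms(g)) mg_induced(g, heavy) else g
    g$explicit_h <- FALSE
  }
  if (attr(table, "sugar_mode") == "WITHOUT_SUGAR") {
    sr <- remove_sugars(g)
    if (is.null(sr$aglycone)) {
      if (sr$had_circular_sugar || sr$had_linear_sugar)
        alerts <- c(alerts, "molecule is entirely sugar; no aglycone to score")
      else alerts <- c(alerts, "no scorable remainder")
      return(structure(list(record_id = record_id, np_likeness = NA_real_,
                            n_fragments_used = 0L, n_unknown_fragments = 0L,
                            alerts = alerts), class = "score_result"))
    }
    g <- sr$aglycone
  }
  sig <- molecular_signature(g, height)
  idx <- match(names(sig), table$canonical_string)
  known <- !is.na(idx)
  n_used <- sum(sig[known])
  n_unknown <- sum(sig[!known])
  if (n_unknown > 0)
    alerts <- c(alerts, sprintf(
      "%d fragment occurrence%s (%d distinct) not in the table; excluded from the score",
      n_unknown, if (n_unknown == 1) "" else "s", sum(!known)))
  score <- if (n_used > 0)
    sum(as.numeric(sig[known]) * table$score[idx[known]]) / n_used
  else {
    alerts <- c(alerts, "no known fragments; score undefined")
    NA_real_
  }
  structure(list(record_id = record_id, np_likeness = score,
                 n_fragments_used = as.integer(n_used),
                 n_unknown_fragments = as.integer(n_unknown),
                 alerts = alerts), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result %s: NP-likeness %s (%d used, %d unknown)%s>\n",
              x$record_id,
              if (is.na(x$np_likeness)) "NA" else sprintf("%.4f", x$np_likeness),
              x$n_fragments_used, x$n_unknown_fragments,
              if (length(x$alerts)) paste0("; ", paste(x$alerts, collapse = "; "))
              else ""))
  invisible(x)
}

#' Score molecules with and without sugar moieties
#'
#' Convenience batch scorer mirroring the result table of the scoring
#' service: each molecule is scored against the aglycone-trained table
#' (`np_likeness`) and, when available, the table trained with sugars
#' retained (`np_likeness_with_sugar`).
#'
#' @param x a `molecule_records` data.frame (from [read_molecules()]), a
#'   list of `molgraph` objects, or a character vector of SMILES.
#' @param table_without_sugar a `fragment_table` trained WITHOUT_SUGAR.
#' @param table_with_sugar optional `fragment_table` trained WITH_SUGAR.
#' @return a `score_results` data.frame with columns `record_id`,
#'   `smiles`, `np_likeness`, `np_likeness_with_sugar`,
#'   `heavy_atom_count`, `total_atom_count`, `ring_count`,
#'   `n_fragments_used`, `n_unknown_fragments`, `alerts`
#'   (semicolon-joined).
#' @export
score_molecules <- function(x, table_without_sugar, table_with_sugar = NULL) {
  if (is.character(x)) {
    graphs <- parse_smiles(x)
    ids <- paste0("m", seq_along(x))
  } else if (is.data.frame(x)) {
    graphs <- attr(x, "graphs") %||% parse_smiles(x$smiles)
    ids <- x$record_id
  } else {
    graphs <- x
    ids <- names(x) %||% paste0("m", seq_along(x))
  }
  rows <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    mg <- graphs[[i]]
    if (is.null(mg)) {
      rows[[i]] <- data.frame(record_id = ids[i], smiles = NA_character_,
                              np_likeness = NA_real_,
                              np_likeness_with_sugar = NA_real_,
                              heavy_atom_count = NA_integer_,
                              total_atom_count = NA_integer_,
                              ring_count = NA_integer_,
                              n_fragments_used = 0L,
                              n_unknown_fragments = 0L,
                              alerts = "unparseable",
                              stringsAsFactors = FALSE)
      next
    }
    mg <- mg_canonicalize(largest_component(mg))
    res <- score_molecule(mg, table_without_sugar, ids[i])
    with_s <- NA_real_
    alerts <- res$alerts
    if (!is.null(table_with_sugar)) {
      rs <- score_molecule(mg, table_with_sugar, ids[i])
      with_s <- rs$np_likeness
      alerts <- unique(c(alerts, rs$alerts))
    }
    rows[[i]] <- data.frame(
      record_id = ids[i], smiles = mg_canonical_smiles(mg),
      np_likeness = res$np_likeness, np_likeness_with_sugar = with_s,
      heavy_atom_count = mg_n_heavy(mg),
      total_atom_count = mg_total_atoms(mg),
      ring_count = mg_ring_count(mg),
      n_fragments_used = res$n_fragments_used,
      n_unknown_fragments = res$n_unknown_fragments,
      alerts = paste(alerts, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("score_results", "data.frame"))
}

## ---- fragment table persistence --------------------------------------

#' Export a fragment table as TSV (+ JSON sidecar)
#'
#' The TSV holds `canonical_string`, `height`, `np_count`, `sm_count`,
#' `score` (17 significant digits, so the round trip is lossless); the
#' sidecar `<path>.json` holds the corpus totals, sugar mode, log base
#' and pseudocount.
#'
#' @param table a `fragment_table`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(table, path) {
  stopifnot(inherits(table, "fragment_table"))
  out <- data.frame(canonical_string = table$canonical_string,
                    height = table$height,
                    np_count = table$np_count, sm_count = table$sm_count,
                    score = sprintf("%.17g", table$score),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  meta <- list(np_total = attr(table, "np_total"),
               sm_total = attr(table, "sm_total"),
               sugar_mode = attr(table, "sugar_mode"),
               log_base = attr(table, "log_base"),
               pseudocount = attr(table, "pseudocount"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Import a fragment table written by [write_fragment_table()]
#'
#' @param path TSV path (the `<path>.json` sidecar must exist).
#' @return a `fragment_table`.
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) .stopf("no such fragment table: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) .stopf("missing table sidecar: %s", sidecar)
  df <- read_tsv(path, colClasses = c(canonical_string = "character",
                                      height = "integer",
                                      np_count = "integer",
                                      sm_count = "integer",
                                      score = "numeric"))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(data.frame(fragment_id = seq_len(nrow(df)),
                       canonical_string = df$canonical_string,
                       height = df$height, np_count = df$np_count,
                       sm_count = df$sm_count, score = df$score,
                       row.names = NULL, stringsAsFactors = FALSE),
            np_total = as.integer(meta$np_total),
            sm_total = as.integer(meta$sm_total),
            sugar_mode = meta$sugar_mode, log_base = meta$log_base,
            pseudocount = as.numeric(meta$pseudocount),
            class = c("fragment_table", "data.frame"))
}
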
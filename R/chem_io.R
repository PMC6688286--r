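## Reading molecule files and writing score tables.

.STATUS_LEVELS <- c("NP", "SM", "BIOGENIC")

#' Read molecules from an SDF, MOL or SMILES file
#'
#' Every parseable entry becomes one record, in input order. Unparseable
#' entries are skipped and logged (see the `skipped` attribute of the
#' result); parsing is delegated to OpenBabel.
#'
#' The `.smi` dialect is one molecule per line, whitespace-separated
#' `SMILES [identifier]`; lines starting with `#` and blank lines are
#' ignored. Records without an identifier get a generated id `m<i>`
#' (1-based position among the file's molecule records). A MOL file is
#' treated as a single-record SDF.
#'
#' @param path path to the input file.
#' @param format one of `"smi"`, `"sdf"`, `"mol"` (case-insensitive).
#' @param status class label applied to every record in the file: `"NP"`
#'   (natural product), `"SM"` (synthetic molecule) or `"BIOGENIC"`.
#' @param source_db free-text tag naming the source database.
#' @return a data.frame of class `molecule_records` with columns
#'   `record_id`, `source_db`, `source_id`, `smiles`, `status`,
#'   `submission_date`. Attributes: `graphs` (list of parsed `molgraph`
#'   objects, aligned with rows), `skipped` (data.frame of skipped
#'   entries with reasons), `n_skipped`.
#' @export
read_molecules <- function(path, format = c("smi", "sdf", "mol"),
                           status = c("NP", "SM", "BIOGENIC"),
                           source_db = "") {
  format <- match.arg(tolower(format[1]), c("smi", "sdf", "mol"))
  status <- match.arg(toupper(status[1]), .STATUS_LEVELS)
  if (!file.exists(path)) .stopf("input file does not exist: %s", path)
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    toks <- strsplit(trimws(lines[keep]), "\\s+")
    smiles <- vapply(toks, `[`, "", 1)
    ids <- vapply(toks, function(x) if (length(x) >= 2) x[2] else "", "")
    graphs <- parse_smiles(smiles)
    bad <- vapply(graphs, is.null, TRUE)
    skipped <- data.frame(index = keep[bad], entry = smiles[bad],
                          reason = rep("unparseable SMILES", sum(bad)),
                          stringsAsFactors = FALSE)
    ids <- ifelse(nzchar(ids), ids, paste0("m", seq_along(smiles)))
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], "_", which(dup))
    n_ok <- sum(!bad)
    rec <- data.frame(record_id = ids[!bad],
                      source_db = rep(source_db, n_ok),
                      source_id = ids[!bad], smiles = smiles[!bad],
                      status = rep(status, n_ok),
                      submission_date = rep(as.character(Sys.Date()), n_ok),
                      stringsAsFactors = FALSE)
    graphs <- graphs[!bad]
  } else {
    lines <- readLines(path, warn = FALSE)
    con <- textConnection(paste(lines, collapse = "\n"))
    recs <- tryCatch({
      s <- ChemmineR::read.SDFstr(con)
      ChemmineR::sdfstr2list(s)
    }, error = function(e) list(), finally = close(con))
    if (!length(recs)) .stopf("no molecule records in %s", path)
    graphs <- vector("list", length(recs))
    ids <- character(length(recs))
    ok <- logical(length(recs))
    reasons <- character(length(recs))
    for (i in seq_along(recs)) {
      txt <- paste(c(recs[[i]], ""), collapse = "\n")
      mg <- tryCatch({
        norm <- .ob_convert("SDF", "SDF", txt)
        g <- .mg_from_sdf_text(norm)
        if (length(g) && mg_n_atoms(g[[1]]) > 0) g[[1]] else NULL
      }, error = function(e) NULL)
      title <- trimws(recs[[i]][1])
      ids[i] <- if (nzchar(title)) title else paste0("m", i)
      if (is.null(mg)) {
        reasons[i] <- "unparseable molblock"
      } else {
        graphs[[i]] <- mg
        ok[i] <- TRUE
      }
    }
    skipped <- data.frame(index = which(!ok), entry = ids[!ok],
                          reason = reasons[!ok], stringsAsFactors = FALSE)
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], "_", which(dup))
    smiles <- vapply(graphs[ok], mg_canonical_smiles, "")
    rec <- data.frame(record_id = ids[ok],
                      source_db = rep(source_db, sum(ok)),
                      source_id = ids[ok], smiles = smiles,
                      status = rep(status, sum(ok)),
                      submission_date = rep(as.character(Sys.Date()),
                                            sum(ok)),
                      stringsAsFactors = FALSE)
    graphs <- graphs[ok]
  }
  if (nrow(rec) == 0) .stopf("no parseable molecules in %s", path)
  if (nrow(skipped))
    .msgf("read_molecules: skipped %d unparseable entr%s in %s",
          nrow(skipped), if (nrow(skipped) == 1) "y" else "ies", path)
  structure(rec, graphs = graphs, skipped = skipped,
            n_skipped = nrow(skipped),
            class = c("molecule_records", "data.frame"))
}

#' Write molecule scores as CSV
#'
#' @param results a `score_results` data.frame as returned by
#'   [score_molecules()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    .stopf("no results to write")
  cols <- c("record_id", "smiles", "np_likeness", "np_likeness_with_sugar",
            "heavy_atom_count", "total_atom_count", "ring_count",
            "n_unknown_fragments", "alerts")
  missing <- setdiff(cols, names(results))
  if (length(missing))
    .stopf("results lack columns: %s", paste(missing, collapse = ", "))
  out <- results[, cols]
  tryCatch(utils::write.csv(out, path, row.names = FALSE, na = ""),
           error = function(e) .stopf("cannot write %s: %s", path,
                                      conditionMessage(e)))
  invisible(path)
}
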
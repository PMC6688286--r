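## Corpus-level statistics: score distributions, repeated fragments,
## centre-atom analyses.

#' Repeated-fragment profile of one molecule
#'
#' A fragment is "repeated" when its signature occurs with multiplicity
#' >= 2 within the molecule. Hydrogen-centred fragments are not counted
#' (nearly every molecule repeats them); the oxygen and nitrogen flags
#' report whether any repeated fragment is centred on that element.
#'
#' @param mol a `molgraph`, or `NULL` when `sig` is given.
#' @param sig optional precomputed [molecular_signature()].
#' @param height signature height when `sig` must be computed.
#' @return a list: `n_repeated_non_h` (distinct repeated signatures not
#'   centred on hydrogen), `has_repeated_o`, `has_repeated_n`.
#' @export
repeated_fragment_profile <- function(mol, sig = NULL, height = 2L) {
  if (is.null(sig)) sig <- molecular_signature(mol, height)
  ce <- attr(sig, "center_element")
  rep_idx <- sig >= 2L
  list(n_repeated_non_h = sum(rep_idx & ce != "H"),
       has_repeated_o = any(rep_idx & ce == "O"),
       has_repeated_n = any(rep_idx & ce == "N"))
}

## per-molecule repeated-centre flags from the stored relations
.store_repeat_flags <- function(store, center, mode = "WITH_SUGAR") {
  cpd <- store_table(store, "molecule_fragment_cpd")
  tbname <- if (mode == "WITH_SUGAR") "fragment_with_sugar"
            else "fragment_without_sugar"
  fr <- store_table(store, tbname)
  sub <- cpd[cpd$sugar_mode == mode & cpd$occurrence >= 2L, , drop = FALSE]
  ce <- sig_center_element(
    fr$canonical_string[match(sub$fragment_id, fr$fragment_id)])
  unique(sub$molecule_id[ce == center])
}

#' Corpus statistics of a trained store
#'
#' Aggregates per-class (NP, SM training classes) score summaries and
#' repeated-fragment fractions. Scores are the primary (sugar-removed)
#' NP-likeness scores. Element-conditioned fractions use only molecules
#' containing that element; they are `NA` when no such molecule exists
#' in the class.
#'
#' @param store a trained `np_store`.
#' @param top_k how many extreme-score fragments to report per class.
#' @return a list of class `corpus_stats`: `per_class` (min/max/mean/n
#'   of scores), `frac_repeated_non_h`, `frac_o_repeated`,
#'   `frac_n_repeated` (each per class), `top_fragments` (highest-score
#'   fragments for NP, lowest for SM).
#' @export
corpus_stats <- function(store, top_k = 10L) {
  mol <- store_table(store, "molecule")
  if (nrow(mol) == 0) .stopf("store is empty")
  o_rep <- .store_repeat_flags(store, "O")
  n_rep <- .store_repeat_flags(store, "N")
  per_class <- list()
  frac_nonh <- list()
  frac_o <- list()
  frac_n <- list()
  for (cl in c("NP", "SM")) {
    mm <- mol[mol$train_class == cl, , drop = FALSE]
    if (nrow(mm) == 0) {
      per_class[[cl]] <- list(min = NA_real_, max = NA_real_,
                              mean = NA_real_, n = 0L)
      frac_nonh[[cl]] <- frac_o[[cl]] <- frac_n[[cl]] <- NA_real_
      next
    }
    sc <- mm$score_without_sugar
    sc <- sc[!is.na(sc)]
    per_class[[cl]] <- list(min = if (length(sc)) min(sc) else NA_real_,
                            max = if (length(sc)) max(sc) else NA_real_,
                            mean = if (length(sc)) mean(sc) else NA_real_,
                            n = nrow(mm))
    frac_nonh[[cl]] <- mean(mm$n_repeated_fragments >= 1L)
    with_o <- mm[mm$o_count >= 1L, , drop = FALSE]
    frac_o[[cl]] <- if (nrow(with_o))
      mean(with_o$molecule_id %in% o_rep) else NA_real_
    with_n <- mm[mm$n_count >= 1L, , drop = FALSE]
    frac_n[[cl]] <- if (nrow(with_n))
      mean(with_n$molecule_id %in% n_rep) else NA_real_
  }
  fr <- tryCatch(store_fragment_table(store, "WITHOUT_SUGAR"),
                 error = function(e) NULL)
  top <- list(NP = NULL, SM = NULL)
  if (!is.null(fr) && nrow(fr)) {
    ord <- order(fr$score, method = "radix")
    cols <- c("canonical_string", "np_count", "sm_count", "score")
    top$NP <- utils::tail(fr[ord, cols], top_k)
    top$SM <- utils::head(fr[ord, cols], top_k)
    rownames(top$NP) <- rownames(top$SM) <- NULL
  }
  structure(list(per_class = per_class,
                 frac_repeated_non_h = frac_nonh,
                 frac_o_repeated = frac_o,
                 frac_n_repeated = frac_n,
                 top_fragments = top),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  for (cl in names(x$per_class)) {
    p <- x$per_class[[cl]]
    cat(sprintf("%s: n=%d score [%.3f, %.3f] mean %.3f\n", cl, p$n,
                p$min, p$max, p$mean))
    cat(sprintf("  repeated non-H: %.1f%%; O-centred (O-containing): %.1f%%; N-centred (N-containing): %.1f%%\n",
                100 * x$frac_repeated_non_h[[cl]],
                100 * x$frac_o_repeated[[cl]],
                100 * x$frac_n_repeated[[cl]]))
  }
  invisible(x)
}

#' Per-class score histogram
#'
#' @param store a trained `np_store`.
#' @param binwidth histogram bin width in score units.
#' @param path optional CSV output path.
#' @return a data.frame with columns `class`, `bin_lower`, `bin_upper`,
#'   `count`.
#' @export
score_histogram <- function(store, binwidth = 0.25, path = NULL) {
  mol <- store_table(store, "molecule")
  rows <- list()
  for (cl in c("NP", "SM")) {
    sc <- mol$score_without_sugar[mol$train_class == cl]
    sc <- sc[!is.na(sc)]
    if (!length(sc)) next
    lo <- floor(min(sc) / binwidth) * binwidth
    hi <- ceiling(max(sc) / binwidth) * binwidth
    breaks <- seq(lo, hi + binwidth / 2, by = binwidth)
    h <- hist(sc, breaks = breaks, plot = FALSE)
    rows[[cl]] <- data.frame(class = cl, bin_lower = utils::head(h$breaks, -1),
                             bin_upper = h$breaks[-1], count = h$counts,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
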
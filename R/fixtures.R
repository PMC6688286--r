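## Deterministic synthetic corpora.
##
## The generator assembles chemically valid molecules from a template
## grammar: NP-like molecules from oxygen-rich scaffolds (polyphenols,
## oxygenated rings, polyol side chains) plus alkaloid-like indole and
## pyrrolidine scaffolds, optionally decorated with a pyranose or
## furanose sugar; SM-like molecules from halogenated
## aromatic / sulfonamide / urea scaffolds. The two grammars overlap in
## their benzene-core fragments (aromatic CH environments away from the
## substituents serialise identically) so mixed-score and
## unknown-fragment code paths are exercised. Every NP template carries
## a class-typical marker in its core: the answer key's expected score
## sign refers to the primary, sugar-removed score, so a sugar must
## never be the only thing distinguishing an NP-like molecule from the
## shared aromatic background. Validity is guaranteed by construction
## (templates, not random graphs), and every product passes the
## curation element/size filters.

.NP_CORES <- c(
  "Oc1ccc(%s)cc1O",
  "Oc1cc(O)cc(%s)c1",
  "Oc1ccc(%s)cc1C(=O)O",
  "O=C1CC(%s)Oc2ccccc21",
  "Oc1ccc2CC(%s)OC(=O)c2c1",
  "Oc1ccc(%s)cc1",
  "Oc1cc(%s)ccc1CC(O)C",
  "CC1(C)CCC(%s)C(O)C1O",
  "Oc1ccc2[nH]cc(CC(N)%s)c2c1",
  "OC(C1CCN(C)C1)c1ccc(%s)cc1O")

.NP_SUBS <- c("O", "C", "CO", "OC", "CCO", "C(C)O", "CC(C)O", "C(=O)O",
              "CC(O)C", "OCC(C)O")

.NP_SUGARS <- c("OC9OC(CO)C(O)C(O)C9O",   # pyranose, O-glycosidic
                "OC9OC(C)C(O)C(O)C9O",    # 6-deoxy pyranose
                "OC9OC(CO)C(O)C9O")       # furanose

.SM_CORES <- c(
  "Clc1ccc(%s)cc1",
  "Clc1ccc(%s)cc1Cl",
  "Fc1ccc(%s)cc1",
  "c1ccc(%s)cc1",
  "c1ccnc(%s)c1",
  "Cc1ccc(%s)cc1S(N)(=O)=O",
  "FC(F)(F)c1ccc(%s)cc1",
  "Clc1cccc(-c2ccc(%s)cc2)c1")

.SM_SUBS <- c("Cl", "F", "Br", "C", "C(F)(F)F", "S(N)(=O)=O", "NC(=O)NC",
              "C#N", "N(C)C", "C(=O)OC", "CCl", "C(=O)NC")

#' Generate deterministic NP-like and SM-like corpora
#'
#' Writes `np.smi`, `sm.smi` and `answer_key.tsv` into `dir`. The same
#' specification produces byte-identical files. The answer key records,
#' per molecule: class, the generated SMILES, whether a circular sugar
#' was attached, and the expected sign of a trained NP-likeness score.
#'
#' @param n_np,n_sm corpus sizes (>= 10 each).
#' @param seed integer seed driving all sampling.
#' @param sugar_fraction fraction of NP-like molecules that receive a
#'   sugar decoration (default 0.4).
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `np_file`, `sm_file`, `key_file` and
#'   the answer key data.frame (`key`).
#' @export
generate_corpora <- function(n_np, n_sm, seed, sugar_fraction = 0.4,
                             dir = ".") {
  if (n_np < 10 || n_sm < 10) .stopf("corpus sizes must be >= 10")
  if (sugar_fraction < 0 || sugar_fraction > 1)
    .stopf("sugar_fraction must be in [0, 1]")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  build <- function(n, prefix, cores, subs, sugars = NULL, frac = 0) {
    smiles <- character(n)
    sugar <- logical(n)
    for (i in seq_len(n)) {
      core <- sample(cores, 1)
      if (!is.null(sugars) && stats::runif(1) < frac) {
        sub <- sample(sugars, 1)
        sugar[i] <- TRUE
      } else sub <- sample(subs, 1)
      smiles[i] <- sprintf(core, sub)
    }
    list(smiles = smiles, id = paste0(prefix, seq_len(n)), sugar = sugar)
  }
  res <- with_seed(seed, {
    np <- build(n_np, "np", .NP_CORES, .NP_SUBS, .NP_SUGARS, sugar_fraction)
    sm <- build(n_sm, "sm", .SM_CORES, .SM_SUBS)
    list(np = np, sm = sm)
  })
  np_file <- file.path(dir, "np.smi")
  sm_file <- file.path(dir, "sm.smi")
  key_file <- file.path(dir, "answer_key.tsv")
  writeLines(paste(res$np$smiles, res$np$id), np_file)
  writeLines(paste(res$sm$smiles, res$sm$id), sm_file)
  key <- data.frame(
    record_id = c(res$np$id, res$sm$id),
    class = rep(c("NP", "SM"), c(n_np, n_sm)),
    smiles = c(res$np$smiles, res$sm$smiles),
    has_sugar = c(res$np$sugar, res$sm$sugar),
    expected_sign = rep(c(1L, -1L), c(n_np, n_sm)),
    stringsAsFactors = FALSE)
  write_tsv(key, key_file)
  invisible(list(np_file = np_file, sm_file = sm_file, key_file = key_file,
                 key = key))
}
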
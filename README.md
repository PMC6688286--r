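# npscore

Fragment-based natural product likeness scoring for small molecules.

Natural products (NPs) — secondary metabolites of living organisms —
are a privileged source of bioactive scaffolds, and ranking compound
libraries by how "NP-like" they are is a standard prioritisation step
in drug discovery. `npscore` trains and applies a fragment-frequency
NP-likeness score: molecules are decomposed into canonical **atom
signatures** (circular substructure descriptors of height *h*, default
2), each fragment *i* is scored from a labelled training corpus of
*NPt* natural products and *SMt* synthetic molecules (SMs) as

    Frag_i = log[ (NP_i + p)/(SM_i + p) * SMt/NPt ]

(occurrences `NP_i`, `SM_i` counted with multiplicity; pseudocount
`p = 1` by default), and a query molecule scores the size-normalised
sum over its fragments,

    NPls = (1/N) * sum_i m_i * Frag_i .

Positive means NP-like, negative means SM-like. Fragments unseen in
training are excluded from both numerator and denominator and raise an
alert. Because sugar moieties are ubiquitous but uninformative in NPs,
every molecule is scored twice: as submitted and on its **aglycone**
after rule-based removal of circular (pyranose/furanose) and linear
(polyol chain) sugars.

The package provides, behind one R API and a small CLI:

* readers for SDF / MOL / SMILES with per-record provenance and class
  labels, and a CSV results writer;
* the curation pipeline: stereochemistry removal, largest-component
  selection, element/size filters, InChI-based deduplication;
* tunable sugar detection and removal;
* canonical atom/molecular signatures (colour refinement +
  individualisation; property-tested against a VF2 isomorphism oracle);
* fragment training, scoring, and lossless TSV import/export;
* a five-table relational store (TSV-backed; DDL in
  `inst/extdata/schema.sql`) with ingest / retrain / query / dump/load;
* corpus statistics (score distributions, repeated-fragment and
  centre-atom analyses);
* a deterministic synthetic corpus generator for testing and
  benchmarking without any external download.

## Worked example

Train on the built-in synthetic corpora (60 molecules per class, 40% of
the NP-like ones glycosylated) and score three probes:

```r
library(npscore)

fx <- generate_corpora(60, 60, seed = 42, sugar_fraction = 0.4,
                       dir = "demo")
store <- cmd_train(fx$np_file, fx$sm_file, "demo/store")
#> trained store demo/store: 90 unique molecules

res <- score_molecules(
  c("OCC1=CC=CC=C1OC1OC(CO)C(O)C(O)C1O",   # salicin (a glycoside)
    "Oc1ccc(cc1O)C(O)CO",                  # a catechol polyol
    "Clc1ccc(cc1Cl)S(N)(=O)=O"),           # a halogenated sulfonamide
  store_fragment_table(store, "WITHOUT_SUGAR"),
  store_fragment_table(store, "WITH_SUGAR"))
res[, c("record_id", "np_likeness", "np_likeness_with_sugar",
        "n_unknown_fragments")]
#>   record_id np_likeness np_likeness_with_sugar n_unknown_fragments
#> 1        m1       0.494                   2.38                   0
#> 2        m2       2.252                   2.41                   2
#> 3        m3      -2.405                  -2.41                   0
```

The glycoside (m1) is strongly NP-like as submitted (+2.38) but much of
that signal is its sugar: on the aglycone alone the score drops to
+0.49. The polyol (m2) stays NP-like either way — two of its fragments
were never seen in training and are excluded with an alert — and the
halogenated sulfonamide (m3) is firmly synthetic-like. `np_likeness`
(the primary, sugar-removed score) is what the corpus statistics and
the separation tests use.

Signatures themselves are ordinary R objects:

```r
molecular_signature(parse_smiles("c1ccccc1")[[1]], height = 2)
#> <molecular signature h=2: 2 distinct, 12 atoms>
#>     6x [c](-[H])(:[c](-[H])(:[c]))(:[c](-[H])(:[c]))
#>     6x [H](-[c](:[c])(:[c]))
```

The same operations are available from a shell via the bundled script
(`inst/cli/npscore.R`): `train`, `score`, `rescore` (recompute all
stored scores), `stats`, and `fixtures`.

## Vignette

`vignettes/np-likeness-methods.Rmd` documents the model and its
assumptions, the curation and sugar rules, the signature
canonicalisation algorithm, the store schema, what the synthetic
generator does and does not emulate, and known limitations.
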
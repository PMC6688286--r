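---
title: "Fragment-based natural product likeness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based natural product likeness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscore)
```

## The model

Natural products (NPs) — secondary metabolites made by living organisms —
occupy regions of chemical space that differ systematically from those of
man-made synthetic molecules (SMs): NPs are oxygen-rich, stereogenic and
scaffold-diverse, while synthetic screening compounds are comparatively
halogen- and nitrogen-rich and flatter. A *natural product likeness
score* quantifies how close a query molecule sits to NP chemical space,
using only the statistics of its substructures.

`npscore` implements the fragment-frequency formulation of this idea.
Molecules are decomposed into **atom signatures**: for every atom
(hydrogens included) the subgraph of all atoms within graph distance
$h$ — the *height*, default $h = 2$ — is encoded as a canonical string.
Two atoms whose chemical neighbourhoods are isomorphic receive the same
string, whatever the input atom ordering or SMILES form. A molecule's
**molecular signature** is the multiset of its atom signatures.

Given a training corpus of $NP_t$ natural products and $SM_t$ synthetic
molecules, each fragment $i$ receives the log-ratio score

$$
\mathrm{Frag}_i \;=\; \log\!\left[
  \frac{NP_i + p}{SM_i + p} \cdot \frac{SM_t}{NP_t}
\right],
$$

where $NP_i$ and $SM_i$ count the fragment's occurrences in each class
*with multiplicity* (a fragment found three times in one molecule
contributes three), and $p$ is an additive pseudocount. The
$SM_t/NP_t$ factor corrects for class imbalance. The NP-likeness of a
molecule is the size-normalised sum

$$
\mathrm{NPls} \;=\; \frac{1}{N} \sum_{i} m_i\,\mathrm{Frag}_i ,
$$

over the fragments of that molecule with multiplicities $m_i$, with
$N = \sum_i m_i$. Positive scores mean NP-like, negative SM-like.

Three conventions in these formulas were genuinely open and are fixed
as follows (all recorded in every trained table so results are
reproducible):

* **Log base.** The natural logarithm, configurable to base 10. The
  base only rescales scores; recording it keeps tables comparable.
* **Smoothing.** $p = 1$ by default, applied to the per-fragment counts
  only, never to the totals. The raw ratio is undefined whenever a
  fragment is missing from one class — the common case for
  discriminative fragments — and with equal class sizes the pseudocount
  leaves balanced fragments at exactly zero. $p = 0$ recovers the
  unsmoothed ratio (then one-class fragments score $\pm\infty$, which
  the ratio-scale invariance tests exploit deliberately).
* **Unknown fragments.** A query fragment absent from the trained table
  is excluded from the numerator *and* from $N$, and the user is
  alerted. Keeping unknowns out of the denominator preserves the
  interpretation of NPls as a weighted average, hence the invariant
  $\min_i \mathrm{Frag}_i \le \mathrm{NPls} \le \max_i \mathrm{Frag}_i$
  over the fragments actually used. A molecule with no known fragment
  gets `NA`, never a fabricated zero.
* **Hydrogen-centred fragments** are first-class: they are trained,
  stored, and counted in $N$ (a configuration flag can exclude them).
  They carry real signal — the hydrogen's height-2 ball sees two bonds
  into the heavy skeleton.

## Curation

Training corpora from heterogeneous databases are standardised before
counting, in this order per record:

1. **Parse** (SDF, MOL, or whitespace-separated `.smi`); unparseable
   records are logged and skipped, never fatal.
2. **Stereochemistry removal.** Databases vary wildly in whether and
   how they depict stereo; keeping it would split identical
   environments into artificial fragment classes. The internal
   graph representation simply has no stereo descriptors, so this step
   is structural, not cosmetic.
3. **Largest connected component** (counter-ions and solvents are
   dropped). Ties break by heavy-atom count, then total atoms, then
   lexicographic canonical SMILES.
4. **Element/size filter.** At least 6 heavy atoms, and only
   C, H, N, O, P, S, Cl, F, As, Se, Br, I, B, Na, Si, K, Fe.
   "6 atoms" is interpreted as *heavy* atoms because hydrogen counts
   depend on the input representation; `--min-atoms` and
   `--count-hydrogens` expose both knobs. The boundary passes: benzene
   (6 heavy atoms) is kept.
5. **Deduplication** on the standard InChI of the stereo-free
   structure. Records sharing a key merge; their sources accumulate;
   a molecule tagged NP anywhere is treated as NP (conflicts are
   logged — public databases demonstrably mislabel), and
   BIOGENIC-tagged records are stored but join neither training class.

## Sugar removal

Glycosylation is everywhere in natural products, and sugar rings
contribute repetitive fragments that say "glycoside" rather than
anything about the aglycone's scaffold. Scoring therefore runs twice:
on the molecule as curated, and on its **aglycone**.

There is no universally agreed graph definition of "a sugar", so the
package states its own, with every threshold tunable via
`sugar_options()`:

* **Circular sugar:** a non-aromatic 5- or 6-membered ring with exactly
  one ring oxygen and otherwise carbon, neither fused nor spiro to any
  other ring, whose ring carbons carry at least (ring size − 2)
  exocyclic single-bonded oxygens. This captures pyranoses and
  furanoses (including deoxy sugars) while sparing tetrahydropyran
  ethers, morpholines and fused chromanones.
* **Linear sugar:** a maximal acyclic chain of 3–7 carbons, each
  bearing exactly one oxygen (hydroxyl, carbonyl or bridging), with no
  chain atom in a ring — the open-chain polyol/aldose motif.

Removal deletes the detected atoms together with their exocyclic
oxygens. A bridging (glycosidic) oxygen leaves with the sugar unless it
bonds to two non-sugar atoms, which avoids both dangling lone oxygens
and spurious phantom hydroxyls on the aglycone. Circular sugars are
removed before linear detection so a ring is never half-eaten by the
chain rule; the largest remaining component is the aglycone, and a
remainder under 6 heavy atoms means the molecule is "entirely sugar"
(scored `NA` without sugars, with an alert). Sugar-free molecules pass
through bit-identical, and removal is idempotent. SMARTS renditions of
the patterns live in `inst/extdata/sugar_patterns.smarts`.

## Canonical atom signatures

The height-$h$ neighbourhood of an atom is the subgraph induced by all
atoms at graph distance $\le h$, layered by distance from the root;
every bond between ball atoms (necessarily within or between adjacent
layers) is kept, so rings inside the ball survive. Canonicalisation
must guarantee: equal strings **iff** isomorphic rooted balls.

The implementation uses colour refinement with individualisation:

1. Initial atom colours combine layer, element, aromaticity flag and
   formal charge.
2. Weisfeiler–Lehman refinement repeatedly extends each colour with the
   sorted multiset of (bond token, neighbour colour) pairs until the
   partition stabilises.
3. If colour classes remain ambiguous, each member of the first
   non-singleton class is individualised in turn and the search
   recurses; the canonical string is the byte-wise minimum over all
   serialisations produced. Class choice and colour ranks are derived
   from sorted keys only, so the search tree — and hence the minimum —
   is independent of input atom numbering.

Serialisation is SMILES-like and versioned with the stored tables:
bracketed atom tokens (`[c]`, `[O]`, `[N+]`, lower case for aromatic),
bond tokens `-`, `=`, `#`, `:`; children of each atom ordered by
canonical rank in nested parentheses; ring closures as numbered
back-references. The root element is recoverable from the first token
(`sig_center_element()`), which the centre-atom statistics rely on.

Aromaticity deserves a note: fragments are computed on
aromaticity-perceived graphs, with a single aromatic bond token. Using
Kekulé structures instead would split chemically equivalent atoms (the
two ortho carbons of toluene, say) into different fragment classes and
double-count ring environments. Perception is ring-based (via
ChemmineR's ring analysis), applied identically everywhere, and both
SMILES forms of benzene produce identical graphs after
canonicalisation.

Correctness is tested two independent ways: random atom-order
permutations must leave every molecular signature exactly unchanged,
and on small molecules string equality is compared pair-by-pair against
a VF2 isomorphism check (igraph) of the rooted, coloured balls — an
oracle that shares no code with the serialiser.

## The store

Training results persist in a five-table relational layout —
`ori_molecule` (raw submissions, redundancy allowed), `molecule`
(unique curated structures with descriptors and both scores),
`fragment_with_sugar` / `fragment_without_sugar` (trained fragments),
and `molecule_fragment_cpd` (occurrence relations) — written as one TSV
per table plus JSON metadata in a store directory;
`inst/extdata/schema.sql` documents the equivalent DDL. A file-backed
store keeps the artifact self-contained and dependency-free while
preserving the relational semantics: referential integrity is checked
(`validate_store()`), the WITH_SUGAR occurrence sums must equal each
molecule's total atom count, and dump/load round trips are
byte-lossless (scores serialise at 17 significant digits).

Retraining (`retrain_scores()` / `rescore`) recomputes every fragment
count from the stored relations and every molecule score from the
fragment tables; it is idempotent to the byte, which makes the
train → rescore pipeline auditable. Fragments contributed only by
non-training (biogenic) molecules stay unscored (`NA`) and are treated
as unknown at query time.

## The synthetic corpus generator

Real NP/SM corpora require multi-gigabyte downloads from ~19 databases;
the package instead ships a deterministic generator
(`generate_corpora()`) whose defaults define the study conditions used
throughout the tests: template-grammar molecules, NP-like from
oxygen-rich polyphenol/chromanone/polyol scaffolds plus alkaloid-like
indole and pyrrolidine scaffolds, 40% of them glycosylated with a
pyranose or furanose; SM-like from halogenated aromatic, sulfonamide,
urea and nitrile scaffolds. The grammars overlap on purpose in their
benzene-core fragments (aromatic CH environments away from the
substituents serialise identically across classes), so fragment
overlap, mixed scores and unknown-fragment alerts all occur. Every
NP template keeps a class-typical marker in its core, because the
answer key's expected score sign refers to the primary
(sugar-removed) score: a sugar must never be the only feature
separating an NP-like molecule from the shared aromatic background.
Template assembly guarantees chemical validity and filter compliance
by construction; an answer key records class, sugar decoration and
expected score sign per molecule.

What the generator does *not* emulate: stereochemistry (stripped
anyway), charge diversity beyond simple salts, tautomerism, the long
tail of rare scaffolds, and realistic nitrogen repetition in NPs (each
NP-like template carries at most one nitrogen environment, so the
"repeated N-centred fragment" fraction is near zero here, far below
what real alkaloid-rich corpora show). Passing the separation test on
these corpora demonstrates that the machinery — curation, signatures,
training, scoring — is sound, not that the two grammars approximate
real chemical space.

Problem sizes: training uses 200 molecules per class and evaluation 100
held-out per class (the corpora deduplicate to fewer unique
structures, which is itself part of the pipeline under test); the
signature-canonicality property runs over 200 generated molecules plus
exhaustive atom-pair checks on 50 small molecules. At these sizes the
complete flow — generate, curate, fragment, train both sugar modes,
score, aggregate — runs in a few minutes on one core.

## Numerical and degenerate-input choices

* Score persistence uses `%.17g`, so TSV round trips reproduce doubles
  exactly; byte-stability of `rescore` is tested with file hashes.
* All string sorts in canonicalisation use byte (`radix`) order —
  locale-independent.
* Ties in largest-component selection resolve by canonical SMILES as
  the last resort, making curation deterministic.
* Empty inputs: a molecule file with zero parseable records is a fatal
  error naming the file; `curate()` on zero records returns empty
  tables with zero counters; an empty training class is fatal (the
  score is undefined without both classes).
* Molecules scoring with no known fragments return `NA` plus an alert;
  downstream aggregation uses `NA`-aware summaries.
* InChI generation failures (exotic valences) reject the record with a
  logged reason rather than aborting the run.

## Known limitations

* Sugar definitions are heuristic; unusual sugars (anhydro, amino
  sugars with N in the ring, sugar acids whose ring carries fewer
  exocyclic oxygens) escape the rules, and glycoside-rich corpora
  will differ from runs made with other toolkits' sugar removal.
* Aromaticity follows one perception model; compounds at the edge of
  aromaticity conventions (mesoionics, extended tautomers) may fragment
  differently than in other software.
* No tautomer or protonation-state canonicalisation: databases that
  depict the same compound differently at those levels produce
  distinct structural keys.
* The individualisation search in canonicalisation is exponential in
  the worst case; for height-2 balls of drug-sized molecules this is
  irrelevant, but very large heights on highly symmetric graphs would
  be slow.
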
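# SMARTS-style documentation of the sugar moiety definitions used by
# detect_circular_sugars() / detect_linear_sugars(). The implementation
# evaluates the equivalent graph rules directly (thresholds are tunable
# via sugar_options()); these patterns are kept here as the editable,
# human-readable reference of what counts as a sugar.

# --- circular sugars -------------------------------------------------
# A non-aromatic pyranose- or furanose-like ring: 5 or 6 ring atoms,
# exactly one ring oxygen, remaining ring atoms carbon, ring not fused
# or spiro to any other ring, and at least (ring size - 2) ring carbons
# carrying a single-bonded exocyclic oxygen (hydroxyl or glycosidic).

# pyranose skeleton (exocyclic oxygens shown on 4 of 5 ring carbons):
circular.pyranose  [C;R1]1(-[O;!R])[C;R1](-[O;!R])[C;R1](-[O;!R])[C;R1][C;R1](-[O;!R])[O;R1]1
# furanose skeleton (exocyclic oxygens on 3 of 4 ring carbons):
circular.furanose  [C;R1]1(-[O;!R])[C;R1](-[O;!R])[C;R1][C;R1](-[O;!R])[O;R1]1

# --- linear sugars ---------------------------------------------------
# A maximal acyclic chain of 3-7 carbons, each bearing exactly one
# oxygen substituent (hydroxyl, carbonyl, or connecting oxygen), no
# chain atom in a ring. Minimal 3-carbon motif:
linear.triose      [C;!R](~[O;!R])[C;!R](~[O;!R])[C;!R](~[O;!R])

# Removal semantics: detected ring/chain atoms are deleted together
# with their exocyclic oxygens; a bridging (glycosidic) oxygen stays
# with the aglycone only if it bonds to two non-sugar atoms. Circular
# sugars are removed before linear ones; the largest remaining
# component is kept and must have at least 6 heavy atoms.
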
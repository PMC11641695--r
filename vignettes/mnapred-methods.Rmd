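---
title: "mnapred: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mnapred: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnapred)
```

# The problem and the modelling idea

Most secondary-structure predictors operate on residue strings, often with
evolutionary profiles. `mnapred` takes a chemoinformatics view: a peptide is
a molecule, its secondary-structure propensity a molecular *property*, and
the predictor a structure–property relationship model over substructural
descriptors. The pipeline is

1. one-letter sequence → explicit-hydrogen molecular graph
   (`build_peptide_graph()`),
2. graph → canonical MNA descriptor strings at a chosen level
   (`descriptor_set()`),
3. descriptor set → per-class evidence score B, calibrated to Pa/Pi
   (`sspr_train()`, `sspr_pa_pi()`),
4. for whole proteins, sliding-window aggregation of Pa−Pi per residue
   (`annotate_protein()`), scored by Q8/Q3 (`q_score()`).

Eight DSSP states are modelled: H, G, I, P, E, C, T, S. The β-bridge state
B is excluded from modelling (isolated bridges are rare and at most a couple
of residues long, below the minimum peptide length the model accepts); it is
still understood on input and maps to strand in the 3-state view.

# Peptide structural formulae

Residues are instantiated from hand-audited templates (PDB atom naming,
Kekulé aromatic rings) and condensed N-to-C with one water removed per
peptide bond. Conventions, chosen once:

* **Neutral protonation everywhere**: NH2/COOH termini, COOH side chains for
  Asp/Glu, neutral Lys amine and Arg guanidine, Nε-H histidine tautomer,
  free cysteine thiol. The physiological charge states would add no
  information under MNA labels (which ignore charge) but would change
  hydrogen counts; the neutral form is the common default of
  sequence-to-molecule converters and keeps descriptor sets deterministic.
* **Explicit hydrogens**: MNA descriptors treat hydrogens as full graph
  atoms, both as centres and as neighbours.
* **Deterministic atom order** (backbone before side chain, each heavy atom
  followed by its hydrogens) so SDF output is reproducible; descriptor
  canonicalisation makes all results independent of that order anyway.
* **Ring perception** is "lies on any cycle", computed from bridge edges;
  it feeds the acyclic `-` prefix of atom labels.

Every generated graph is validated: connected, hydrogens of degree 1,
element valences (C4 N3 O2 S2 H1) consistent with the stored bond orders.

# MNA descriptors and canonicalisation

The level-k descriptor of an atom wraps its label around the *sorted*
level-(k−1) descriptors of its neighbours; a molecule's descriptor set is
the deduplicated set over atoms. Two numerical choices matter:

* **Byte-order sorting.** Sub-descriptors are sorted by raw byte order
  (radix semantics), never locale collation, so canonical strings are
  platform-independent.
* **Rank-based ordering.** Level-9 strings reach tens of kilobytes, and
  sorting them repeatedly would dominate runtime. Because MNA strings of a
  given level are mutually prefix-free, the byte order of
  `LABEL(D1…Dm)` equals the lexicographic order of (label, ranks of the
  sorted sub-descriptors, shorter-first). The implementation therefore
  carries an integer rank per atom across levels and sorts only short
  fixed-width rank codes; the acceptance suite verifies string-for-string
  (including order) agreement with a naive recursive oracle.

A model "at level L" uses exactly the level-L set — one descriptor per atom,
deduplicated — because single levels are what the descriptor-level sweep
(`evaluate_levels()`) compares; `union_levels = TRUE` is available for
experimentation. Counts (multiset semantics) and bond-order-aware labels are
deliberately out of scope.

# The classifier

No published equations exist for the reference implementation of this
Bayesian scheme, so the package states its own, testable reconstruction:

$$B = \frac{1}{|D|}\sum_{d \in D}\bigl(2\hat p(a\mid d)-1\bigr),\qquad
\hat p(a\mid d)=\frac{n_{ad}+c\,p_0}{n_d+c},\qquad p_0=\frac{n_a}{n}.$$

Descriptors unseen in training have $n_d=n_{ad}=0$ and fall back to the
class prior, contributing $2p_0-1$. B is bounded in $[-1,1]$. The smoothing
constant `c_smooth` (default 1) shrinks rare-descriptor estimates toward the
prior; larger values damp noise from singleton descriptors, smaller values
sharpen them.

**Pa/Pi** are read off the empirical distribution functions of the
*leave-one-out* training scores of positives and negatives (ties counted ½).
Both are monotone in B, so the decision rule "Pa > Pi" is a per-class
threshold on B located where the two empirical curves cross. Parity with any
proprietary implementation's exact numbers is not claimed — only the
documented semantics (Pa/Pi in [0,1], monotonicity, threshold decision,
LOO-AUC validation) are guaranteed and tested.

**Leave-one-out is exact.** Scoring record *i* removes its contributions
from $n$, $n_a$, $n_d$, $n_{ad}$; the acceptance suite checks equality with
literal retraining to 1e−12. Exactness has a consequence worth knowing:
under *zero* signal the LOO estimate is conservative, not centred at 0.5.
Removing a positive record lowers the positive counts behind its own score,
so information-free classes score positives systematically below negatives —
in the extreme case of all-identical descriptor sets the LOO AUC is exactly
0, and at low descriptor levels (heavily shared, near-uninformative
descriptors) a label-shuffled null sits visibly below 0.5. At the working
level of the model (level 9, where most descriptors are record-specific and
fall back to the prior under LOO) the shuffled-label null is ≈ 0.50, which
is what the null-control acceptance test pins down. This is a property of
exact LOO itself, not a defect of the counting.

Classes with no positive or no negative record are dropped with a warning
and reported as absent rather than crashing — small synthetic sets routinely
lack the rare states (I, P).

**Multi-label training**: a peptide observed as, say, 3₁₀-helix, α-helix and
turn is a positive example for all three classes and a negative for the
other five. Training operates on unique (sequence, label-set) records; if a
sequence recurs across PDB entries it contributes once.

# Dataset assembly

`parse_dssp()` reads the classic fixed-column DSSP text (amino acid at
column 14, summary code at column 17), maps blank codes to coil and
lowercase disulfide-cysteine letters back to `C`, and splits chains at `!`
break rows. The mmCIF-style DSSP-4 output is out of scope (convertible
externally), as is re-running DSSP or fetching PDB entries; resolution comes
from a user-supplied sidecar TSV.

Segments are maximal runs of one code, kept when 4 ≤ length ≤ 130 and the
code is not B, and when resolution ≤ 2 Å (inclusive; records without a
resolution are dropped unless `keep_missing`). The co-occurrence table
counts single-label sequences on its diagonal and pairwise co-occurrences
off it — the diagonal is "sequences belonging to only one type", matching
how such tables are usually annotated — and its percentage form normalises
each column to 100.

# Whole-protein annotation

All windows of 4–30 residues are predicted; each residue inherits, per
class, the maximum Pa−Pi over covering windows, and its call is the argmax.
Choices:

* Ties at the argmax break by the fixed priority H>E>C>T>S>G>P>I (decreasing
  prevalence of the states in real data), making output deterministic.
* The 0.7 display threshold used by interactive front-ends is a
  *presentation* default: `annotate_protein()` reports raw deltas and only
  masks calls when `min_delta` is given; the CLI default is 0.7.
* The optional `smooth_short_runs()` pass suppresses predicted runs shorter
  than four residues — the method cannot firmly predict segments below the
  minimum window length — but is off by default because no exact rule for it
  is fixed.
* The 8→3 mapping defaults to the common DSSP convention H,G,I→H; E,B→E;
  C,T,S,P→C and is configurable, since published Q3 figures are sensitive to
  where polyproline II is sent and the reference choice is not documented.
  Q3 ≥ Q8 always holds under any many-to-one mapping applied to both
  strings.

# The synthetic generator: what a green test establishes

`generate_synthetic_set()` draws sequences i.i.d. from per-class residue
frequency vectors (helix-biased A/L/E/K/M, strand-biased V/I/Y/T/F/W, and so
on), lengths uniform in 4–20 by default — the typical length range of real
helix and strand segments; real segments run up to 130 and the generator
accepts any range inside 4–130. An optional contamination fraction assigns a
second label to emulate multi-type sequences. Everything is seeded and the
caller's RNG state is restored.

This stated world captures exactly one regularity of real data —
class-dependent residue composition — and none of the positional,
cooperative or physical structure of actual secondary-structure segments
(no helical periodicity, no pairing constraints, no length–class
dependence). A green signal-recovery test therefore establishes that the
pipeline recovers compositional signal through the graph→descriptor→Bayes
chain, not that the package attains any published accuracy on PDB-derived
corpora; the published headline numbers require the full experimental
training corpus and are out of scope by design.

# Numerical and format notes

* AUC uses the Mann–Whitney rank form with average ranks, ties ½ — exactly
  the pairwise-comparison definition, verified by enumeration.
* Model files are versioned JSON carrying level, smoothing, vocabulary,
  global and per-class counts and the sorted LOO score arrays; reading a
  model reproduces predictions bit-for-bit.
* SDF output is MOL V3000 only (no atom-count limit; a 60-residue peptide
  already exceeds 1000 atoms); V2000 is never written. Coordinates are
  zeros — the format carries topology and data fields (`SSP_TYPE`,
  optionally `PDB_ID`, `CHAIN`, `RESOLUTION`) only.
* Degenerate inputs fail loudly: empty sequences, non-standard residue
  letters (B, J, O, U, X, Z) with the offending position, length mismatches,
  malformed SDF blocks with line numbers, AUC on single-class score sets.

# Known limitations

* Sequence-only conversion cannot represent disulfides, post-translational
  modifications, non-standard residues or cyclic peptides.
* The classifier is a reconstruction of a PASS-style scheme; it matches the
  documented behaviour, not any proprietary implementation's exact output.
* Exact-LOO conservatism (above) makes low-level or tiny-sample AUC
  estimates pessimistic; compare levels on equal footing only.
* Whole-protein annotation costs one descriptor-set computation per unique
  window; for long proteins at level 9 this is minutes, not seconds, in
  pure R.
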
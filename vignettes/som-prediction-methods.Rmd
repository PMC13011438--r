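---
title: "Atom-level site-of-metabolism prediction: models, descriptors and design choices"
author: "somkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-level site-of-metabolism prediction: models, descriptors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Xenobiotic metabolism transforms small molecules at specific atoms — the
*sites of metabolism* (SOMs). Predicting which atoms of a candidate compound
are susceptible to phase 1 (oxidation, reduction, hydrolysis) or phase 2
(conjugation) biotransformations helps medicinal chemists anticipate
metabolic soft spots early. somkit frames this as binary classification at
the atom level: every heavy atom of every molecule is an instance, annotated
SOMs are the positive class, and all remaining heavy atoms of an annotated
molecule are negatives. The package is a complete, trainable toolkit: it
does not ship a pre-trained model but builds one from any SDF input that
carries per-atom SOM annotations.

## Molecule perception

All downstream computation operates on a perceived heavy-atom graph.
Perception applies one fixed model to every molecule — train and test alike
— because atom typing must be stable for the fingerprint encoding to be
meaningful:

* **Hydrogens** are removed from the explicit graph and folded into
  per-atom implicit counts; missing hydrogens are completed from standard
  element valences (adjusted for formal charge). The fingerprints and
  distance computations see heavy atoms only.
* **Fragments.** Multi-fragment inputs (salts, counter-ions) keep the
  largest connected component; removals are logged.
* **Aromaticity** is perceived on Kekulé input by a Hückel-style rule: a
  ring of size 3–7 is aromatic when every ring atom can carry a p orbital
  (≤ 3 connections, element C/N/O/S) and the ring's π-electron count —
  1 per atom with an endocyclic double bond, 2 for a heteroatom lone pair,
  0 for an exocyclic double bond — satisfies 4n+2. Inputs that use the
  V2000 "aromatic" bond order 4 are rejected rather than silently
  re-kekulized, so exactly one aromaticity model is ever in play.
* **Hybridization** follows bond orders: triple bond or two double bonds →
  sp; one double bond or aromatic → sp2; otherwise sp3.

Every atom then receives one of 26 SYBYL atom types (sp3/sp2/sp/aromatic
carbon and nitrogen variants, amide and planar nitrogen, ether/carbonyl/
carboxylate oxygen, sulfur oxidation states, phosphorus, halogens, silicon,
and a catch-all). The published 26-type list is not reproduced in full
anywhere we can cite at implementation level, so the shipped table is a
documented reconstruction; `sybylTypeTable()` accepts any replacement list
and the fingerprint layout adapts automatically. Elements outside the table
reject the molecule by default (never a silent fallback); a catch-all
`"Any"` mapping is opt-in.

## Rooted circular fingerprints

The central encoding assigns a 32-bit block to every combination of SYBYL
type and bond distance from a root atom. If the root has *n* neighbours of
type *t* at topological distance *d* (0 ≤ *d* ≤ radius, distance 0 being the
root itself), the first min(*n*, 32) bits of block (*d*, *t*) are set — so
set bits always form a prefix and the block's popcount is the clamped
neighbour count. The equivalent count fingerprint stores the exact counts in
the same distance-major, type-minor layout; it is lossless and far denser,
and either representation can back the classifier.

The default radius is 5 bonds. The encoding is radius-bounded by
construction and 5 covers the full diameter of typical drug-like molecules
(the synthetic fixtures span 5–25 heavy atoms); the real contract is that
the radius is a configuration field serialized with the model, so train and
prediction layouts can never diverge.

## Atom descriptors

Ten physicochemical slots complement the fingerprint, each behind a named
provider so a slot can be disabled (shrinking the schema) or re-backed by an
external toolkit without touching the rest of the pipeline:

| slot | reference provider |
|---|---|
| atom_degree | heavy-neighbour count |
| formal_valence | bond-order sum incl. implicit H (Kekulé) |
| hybrid_polarizability | per-(element, hybridization) lookup, Å³ |
| vsepr_geometry | steric-number rule, stable integer code 0–7 |
| effective_polarizability | neighbour contributions damped 0.5^distance |
| inductive_effect | Σ electronegativity differences / distance² |
| peoe_sigma_charge | Gasteiger–Marsili iteration (below) |
| peoe_sigma_electronegativity | orbital electronegativity at convergence |
| pi_electronegativity | valence-state lookup for π-capable atoms |
| mmff94_charge | bond-charge increments (default) or Open Babel MMFF94 |

The PEOE charges use the classical scheme: per cycle, charge flows across
every bond from the less to the more electronegative atom, proportional to
the electronegativity difference and attenuated by 0.5 per cycle, for 6
cycles — fixed and documented so convergence behaviour is reproducible.
Implicit hydrogens participate as pseudo-atoms and their charges are folded
into the carrier, so the reported heavy-atom charges of a neutral molecule
sum to zero. The inductive-effect and π-electronegativity forms are
documented electronegativity-based substitutes (their original functional
forms are not published at implementation level); the `mmff94_charge`
default is a self-contained bond-charge-increment scheme, with a true
MMFF94 backend through the `obabel` executable selectable via
`descriptorProviderMap()`. Numeric parity with any specific external
toolkit is explicitly not a contract of this package.

Four topological descriptors complete the vector: the molecule's maximum
bond distance, the atom's maximum bond distance, their difference and their
ratio. A single-atom molecule takes (0, 0, 0, 1) — its only atom trivially
attains the molecular maximum, which fixes the 0/0 ratio.

## Classifier

A probability random forest (`ranger`, 250 trees, √p feature sampling,
single-threaded, seeded) maps the per-atom feature vector to a SOM
probability. Calls use `p ≥ 0.3`; the sub-0.5 threshold compensates for the
minority positive class, and the ≥ convention at the boundary is fixed for
reproducibility. Class weighting is unweighted by default: weighting the
minority class up recalibrates forest probabilities toward 0.5, which
saturates every call at a 0.3 threshold and degenerates precision to the
prevalence — with unweighted training the threshold behaves as intended.
`"balanced"` weighting remains available in `somTrainingConfig()`.

Atoms are ranked within each molecule by descending probability, ties
broken by ascending atom index, so ranks are a deterministic permutation of
1..n and the molecule-level top-2 metric needs no tie expansion. Training is
deterministic end to end: identical data, configuration and seed reproduce
identical predictions, and the CLI pipeline reproduces output files to the
byte.

A trained model serializes as a single-file bundle carrying the forest, the
ordered feature schema, the resolved configuration, a format-version string
— loading any other version is refused, never reinterpreted — and the binary
fingerprints of all training atoms, so reliability scoring never needs the
raw (possibly license-encumbered) training structures.

## Prediction reliability

Two complementary per-atom signals:

* **FAME score** — the mean Tanimoto similarity between the query atom's
  binary fingerprint and its k = 3 nearest training-atom fingerprints, an
  applicability-domain proximity measure in [0, 1]. It is always computed
  on binary fingerprints (the Tanimoto definition is a bit-vector
  operation), even for models trained on count fingerprints. The neighbour
  set is all training atoms, not per-class subsets. Ties at the k-th rank
  cannot change the score (values are averaged); neighbour identity is made
  deterministic by index tie-break.
* **Shannon entropy** — the binary entropy of the predicted probability,
  maximal at p = 0.5, a model-confidence measure independent of descriptor
  space.

`reliabilityCorrelation()` reports their rank correlation and per-quantile
bin accuracy/MCC, the package's machinery for comparing the two signals
against realized performance.

## Synthetic fixtures

The generator assembles molecules from a small weighted grammar — alkyl
chains with occasional methyl branches, ether oxygens, amine nitrogens,
benzene rings entered and exited at ortho/meta/para positions, terminal
halides — sized 5–25 heavy atoms, then labels atoms by two deterministic
environment rules: sp3 carbons alpha to an ether oxygen or amine nitrogen,
and aromatic CH carbons ortho to a substituted ring position. Both
environments are expressible within a radius-2 fingerprint, so the learning
task is well-posed by construction; an optional i.i.d. label flip (< 0.5)
injects controlled noise. Everything is deterministic under (spec, seed),
and fixtures are written as ordinary labeled SDF so they exercise the public
interfaces rather than a test backdoor.

What the fixtures emulate is the *shape* of SOM data — per-atom labels
driven by local atom environments, class imbalance around 25% positives,
molecule-level structure. What they deliberately do not emulate is real
metabolic chemistry: no enzyme specificity, no reaction-subset structure
(CYP vs phase 1 vs phase 2), no stereochemistry. Recovery results on
fixtures (held-out ROC-AUC ≥ 0.95 at 400 molecules, noise 0) validate the
pipeline's correctness, not its accuracy on experimental metabolism data.

The train/test split operates at the molecule level and forces records with
identical stereo-agnostic canonical skeletons (joint Weisfeiler–Lehman
refinement, 3 rounds) into the same partition, so duplicates and
stereoisomer records cannot leak across the split.

## Evaluation protocol

Atom-level: ROC-AUC by the rank (Mann–Whitney) formulation with half-credit
for score ties; PR-AUC as step-wise average precision (threshold groups, no
linear interpolation, which is known to overestimate in PR space); F1, MCC,
precision and recall from the thresholded confusion matrix, with MCC
defined as 0 when its denominator vanishes. Single-class inputs flag the
ranking metrics as undefined while threshold metrics are still reported.
Molecule-level: the top-2 correctness rate — the fraction of molecules with
at least one annotated SOM among the two top-ranked atoms; molecules
without any annotated SOM are excluded from it (and counted) but still
enter the atom-level metrics as all-negative.

## Numerical and degenerate-input conventions

* Tanimoto of two all-zero fingerprints is 0; an all-zero query scores
  FAME = 0 (out of domain, logged).
* Binary entropy uses 0·log₂0 = 0, so H(0) = H(1) = 0 exactly.
* Thresholded calls use ≥; rank ties break by ascending atom index.
* Indices are 1-based everywhere a user sees them (SDF atom blocks,
  `SOM_LABELS`, CSV output), matching the SDF convention; `M  CHG` lines
  supersede atom-line charge codes.
* Unfeaturizable molecules (e.g. elements without PEOE parameters) are
  skipped with a logged reason; the run continues.
* Configuration files are YAML with sections
  `featurization / model / evaluate / reliability`; command-line flags
  override file values, and every output artifact embeds the resolved
  configuration and seed.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the complete pipeline at 400
fixture molecules (≈ 4,800 atoms, 80/20 split), which recovers the label
rules to held-out ROC-AUC ≈ 0.98 and top-2 ≈ 1.0 within seconds, and
verifies the no-signal floor by globally permuting labels (held-out ROC-AUC
≈ 0.5). Metric implementations are checked against independent brute-force
oracles (pairwise concordance for ROC-AUC, per-positive precision steps for
average precision, exhaustive per-molecule top-2, brute-force top-k
neighbour search for the FAME score) on hundreds of random instances each.

## Known limitations

* The SYBYL table and several descriptor functional forms are documented
  reconstructions/substitutes, not numeric ports of any external toolkit.
* Aromaticity requires Kekulé input; order-4 bonds are rejected.
* No 3D, conformer or stereochemistry-aware features.
* The CLI is deliberately single-core; per-molecule operations are
  side-effect-free so callers can parallelize by sharding inputs over the
  R API.
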
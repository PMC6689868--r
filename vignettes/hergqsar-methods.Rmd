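---
title: "Predicting hERG liability by combining hypothesis networks, random forests and structural alerts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hERG liability by combining hypothesis networks, random forests and structural alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Blockade of the hERG potassium channel prolongs the cardiac QT interval and
can precipitate torsades de pointes; screening candidate compounds *in
silico* for hERG liability is therefore a routine gate in early drug
discovery. `hergqsar` implements a binary hERG classifier stack built from
three complementary predictors — a self-organising hypothesis network
(SOHN) over typed atom-pair features, a random forest (RF) over
physicochemical descriptors and circular fingerprints, and a
structural-alert expert surrogate — together with the machinery such a
study needs: curation of heterogeneous bioactivity records into binary
calls, temporal train/test splitting, per-prediction confidence scores,
model/data combination strategies, confusion-matrix metrics, and a
synthetic two-source benchmark generator so every component is testable
without any external data.

## Data model and curation

A compound enters the package as a SMILES string with an optional source
tag (`public`/`private`), date, and raw activity measurements (IC50, EC50,
Ki in uM; percent inhibition at 10 uM; or a 0/1 author call). Structures
are canonicalised through OpenBabel on load; unparseable rows are reported
and skipped, never silently dropped. Single-heavy-atom structures (e.g.
water) are outside the supported input space — the SDF toolkit layer
cannot represent a molecule without bonds — and are skipped with the same
reporting path.

Curation turns raw measurements into one call per compound:

* **Thresholds.** Potency kinds are active strictly below 10 uM (an
  IC50-equivalent cutoff; per-kind overrides are configuration);
  percent inhibition is active strictly above 50%. A value exactly at a
  threshold is inactive — the boundary is not defined by convention
  elsewhere, so the package fixes strict inequality and documents it.
* **Replicates.** Replicate numeric values of one kind are averaged
  *first* and then binarised. This is deliberately not the same operation
  as binarising each replicate and merging: `(20, 20, 60)%` inhibition is
  inactive by mean (33%) but active under a conservative merge of
  individual calls. A regression test pins this difference.
* **Merging.** Across kinds (and author calls) the per-kind calls are
  merged conservatively: a single active suffices for an overall active.
  This merge is a join over the two-element lattice — commutative,
  associative, idempotent — which the tests exercise as a property.
* **Temporal split.** Train = dated on or before the cutoff, test =
  strictly later; undated records are excluded with a warning, and a
  canonical structure present on both sides is removed from the test side
  so compounds stay unique to each set.

## Features

**Atom typing.** Each heavy atom receives a code combining element,
aromaticity flag, hybridisation (derived from kekulised bond orders:
triple or two doubles → sp, any double or aromatic → sp2, else sp3) and
the sorted multiset of directly bonded heavy-element symbols, e.g.
`C.ar.sp2[C,C,N]`. This is an intentionally reproducible approximation of
refined Ghose–Crippen-style typing; formal charge is ignored (a
documented simplification), and typing is invariant to atom-index
permutation.

**Atom pairs.** A feature is an unordered pair of atom types plus their
shortest bond-path distance, kept for distances 2–20. Enumeration is
validated against a hand-written all-pairs BFS oracle on random small
molecules.

**Circular fingerprints.** Both fingerprint blocks are radius-4,
4096-bit folded circular fingerprints computed by an in-package
neighbourhood-hashing engine: the plain variant seeds the iteration with
connectivity invariants (element, degree, hybridisation, aromaticity),
the feature variant with pharmacophoric role flags (aromatic, H-bond
donor/acceptor proxies, basic nitrogen, halogen). OpenBabel's ECFP8
implements the same construction with a different hash; the test suite
uses it as an independent cross-check, requiring strong rank agreement
between the two similarity matrices. Tanimoto similarity is the package's
single similarity convention (the choice of similarity metric behind the
confidence scores is configuration, not doctrine).

**Physicochemical descriptors.** 26 descriptors: OpenBabel molecular
properties (MW, logP, TPSA, molar refractivity, H-bond donors/acceptors,
fluorine count) plus graph-derived counts (atoms, bonds, rings, aromatic
fraction, element counts, sp3-carbon fraction, rotatable bonds, basic
nitrogens, amides, degree). The list is exposed as
`PHYSCHEM_DESCRIPTORS` and selectable per model; non-finite values are
imputed to zero with a logged warning.

## The SOHN classifier

Every atom-pair feature present in the training set is a candidate
toxicophoric hypothesis. Training proceeds in three steps:

1. **Selection by recursive partitioning.** At each node the feature with
   the highest Shannon information gain over the node's (weighted) records
   is chosen; records split by presence/absence and recursion continues
   until purity, the support floor (`min_support`, default 5 — small
   enough to find rare toxicophores at desk scale, large enough that a
   local kNN over the support is meaningful), or the depth cap
   (`max_depth`, default 10). Gain ties break deterministically by larger
   support, then lexicographic feature code. The root split is verified
   against an exhaustive information-gain scan in the tests.
2. **Network construction.** Selected hypotheses are ordered by strict
   support-set inclusion into a Hasse diagram (equal supports merge into
   one node holding all their features; transitive shortcut edges are
   removed). Child-in-parent strict containment is asserted by tests
   after every build.
3. **Local kNN models.** Each hypothesis carries its supporting
   compounds. For a query, the most specific applicable hypotheses (those
   matching the query with no applicable descendant) each produce a local
   k-nearest-neighbour prediction (`k = 5` by default) over their support,
   using Tanimoto similarity on the plain fingerprint.

**Confidence.** A local prediction's confidence is exactly 1 under two
anchor conditions — an exact training-set match, or full label agreement
among the neighbours. Between the anchors the package interpolates as
*mean neighbour similarity × fraction of neighbours agreeing with the
call*, which is monotone in both ingredients and bounded in [0, 1]. The
anchors are the defined part of the contract; the interpolation is this
package's documented choice.

**Combination.** The final call is the most confident local prediction
(confidence ties resolve conservatively to active). A weighted-vote mode
is available behind `combine = "vote"` since the original combination
rule admits either reading; most-confident is the default because it is
the same arbitration the ensemble layer uses between whole models. A
query matching no hypothesis falls back to a global kNN over the whole
training set and is flagged out-of-domain in its provenance rather than
abstaining, so the ensemble layer can still arbitrate it.

## The random forest and its confidence score

The RF (via `ranger`; 500 trees, sqrt-features per split, unlimited
depth — all configurable) consumes the concatenation
`[physchem | Morgan | Feature-Morgan]`. Per prediction the confidence
score is

> CS = (max similarity to the training set + predicted-class probability) / 2,

the arithmetic mean of an applicability-domain term and the forest's vote
fraction. The similarity term uses the plain Morgan block, matching the
package-wide similarity convention; since the predicted-class probability
is at least 0.5 in a binary forest, CS usually lies between 0.5 and 1 and
reaches 1 only for an exact training match predicted unanimously. Training
sorts records by id internally, making the model invariant to input row
order at a fixed seed.

## The expert surrogate

The expert component matches a TSV-loaded set of SMARTS alerts; any match
makes the call active, the provenance names the matched alerts, and the
confidence is categorical (`matched`/`no_match`) — deliberately never a
number, so the ensemble uses the expert only as a fallback, not as a
confidence competitor. The five packaged alerts encode the classic hERG
pharmacophore shape (basic amine at a short path distance from an
aromatic; piperidine/piperazine variants; a lipophilicity-guarded
halogenated variant). They are a synthetic testing surrogate for an
expert knowledge base, not a reproduction of any proprietary alert set,
and their absolute performance is not comparable to published expert
systems. Alert matching is training-free, deterministic, and monotone:
adding an alert can only turn calls active.

## Combination strategies

* **Source-weighted training (`a:b`).** Each source's records share the
  source's total effective weight equally, and the totals stand in the
  ratio `a:b`. Weighting (not resampling) is the default because it is
  deterministic and exact; a seeded bootstrap resampling mode exists for
  comparison since either mechanism is a defensible reading of "sampling
  ratio". A zero-weight source is dropped entirely, so `5:0`/`0:5`
  reproduce the single-source models bit-for-bit at a fixed seed — an
  identity the acceptance tests check literally.
* **Confidence-threshold fallback.** Keep the statistical call when its
  confidence is at least the threshold τ, otherwise use the expert's call
  (provenance records the switch). τ = 0 is the statistical model;
  τ > 1 is the expert. The default τ = 0.7 is where the
  statistical-plus-expert combinations perform best in this setting.
* **Most-confident consensus.** Across models, the final call is the most
  confident prediction; SOHN and RF confidences are treated as comparable
  (an assumption, not a calibration — both live in [0, 1] and correlate
  with accuracy). Conflicting-call confidence ties resolve conservatively
  to active, consistent with the curation module's philosophy.
* **Full stack.** Most-confident consensus of the two statistical models,
  then expert fallback below τ = 0.7.

## The synthetic benchmark

The generator emulates the *structure* of an industrial two-source hERG
study at desk scale; it does not attempt to mimic real chemistry
distributions.

* **Chemistry.** Molecules are spliced from 30 scaffold templates with
  one or two substitution sites and a decoration library, so planted
  atom-pair toxicophores occur at controllable topological distances.
  The last six scaffolds form the "corporate" space: the private source
  draws exclusively from them and decorates from a narrow sub-library
  (an analog series with high internal similarity); the public source
  spans the wider pool, including only part of the corporate cores
  (`scaffold_overlap`, default 0.5).
* **Mechanism.** Activity is Bernoulli with logit = base (−1.5) + planted
  motif effects (basic amine chain +3.0, N-methylpiperidine +2.6,
  sulfonamide −2.0) + a per-scaffold context offset. Inside the three
  private-exclusive cores the motif effects shift (−1.4 / 0 / +3.6): the
  classic basic-amine pharmacophore is muted and the normally protective
  sulfonamide becomes an unexpected trigger. The mechanism is one global
  function — a source differs only in *where* it samples it, which is
  exactly what makes domain proximity matter.
* **Noise.** Observed labels flip with rate 0.15 (public) vs 0.05
  (private), encoding the heterogeneity of literature data versus a
  single corporate protocol; public potency values additionally scatter
  around the 10 uM cutoff, so binarisation itself contributes a little
  extra noise. Private records are percent-inhibition measurements,
  ~20% in duplicate, exercising the replicate-averaging rule.
* **History.** The private training series under-samples the two
  basic-amine motifs (prevalence multipliers 0.4/0.3) — a
  lead-optimisation campaign steers away from known liabilities — while
  the late-period test chemistry drifts back to the full decoration pool
  and carries 75% inactives by construction, emulating a negatively
  biased prospective test set whose actives are partly "black swans".
* **Reproducibility.** Everything derives from one master seed via
  per-stage streams; generation is byte-identical under a fixed seed, all
  emitted SMILES are valid, and canonical structures are unique within
  the private series and across its train/test split.

**What passing tests do and do not show.** The generator's planted
ground truth makes parameter-recovery and ordering claims *testable*:
SOHN finds the planted pair among its top hypotheses; private-trained
models beat public-trained models on the private test set; pooled
training does at least as well as private alone; the most-confident
consensus matches its best member. These are statements about the
package's machinery under a controlled mechanism — they do not certify
performance on real hERG data, where feature noise, assay artefacts and
activity cliffs are richer than anything simulated here.

## Numerical choices and problem sizes

* Default study conditions: 250 public / 200 private training compounds,
  150 test compounds, averaged over 10 seeds where a claim is statistical.
  These sizes keep the full benchmark suite runnable on a laptop core in
  minutes while leaving the qualitative contrasts well outside seed noise.
* Confidence ties are broken at 1e-12 resolution; gain ties by support
  then code; kNN similarity ties by training id — every arbitration is
  deterministic and documented at its definition site.
* Degenerate metric denominators (empty margin of the confusion matrix)
  report 0 with a `degenerate` flag rather than NaN, so downstream tables
  stay honest.
* Metric tables round half-to-even to two decimals only at display time;
  computations keep full precision.

## Known limitations

* Atom typing ignores formal charge and stereochemistry; hybridisation is
  inferred from kekulised bond orders, which misreads exotic valence
  states.
* The hydrogen-bond donor proxy in the feature fingerprint infers spare
  valence from heavy-atom degree; explicit-hydrogen inputs are not given
  special treatment.
* Single-heavy-atom molecules are not supported (skipped with a warning).
* The expert surrogate's alert set is intentionally toy-sized; its value
  is in exercising the combination strategies, not in coverage.
* SOHN and RF confidences are assumed comparable by the consensus layer;
  no calibration (Platt/isotonic) is attempted, matching the design this
  package implements.
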
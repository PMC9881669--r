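---
title: "The metaboMatch annotation engine: model, parameters and design"
author: "metaboMatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metaboMatch annotation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboMatch)
```

# The annotation problem

A tandem-MS experiment gives, per detected metabolite, a precursor m/z
(MS1) and one or more fragment spectra (MS2). Annotation means naming the
compound behind the precursor. metaboMatch treats this as a retrieval and
ranking problem over a pre-compiled compound store: the precursor mass
selects a candidate set, and fragment-level evidence orders it. The
engine deliberately relies only on *pre-computable* per-compound
properties (exact mass, formula, fingerprint, fragmentation pattern), so
the per-query cost is independent of how expensive the cheminformatics
was at store build time.

The engine assumes peak-picked, centroided input (an upstream
responsibility), one compound per query spectrum, and high mass accuracy
by default (20 ppm / 0.005 Da); all thresholds below are configurable.

# The compound store

`buildStore()` parses SMILES or SDF input with OpenBabel, deduplicates by
full standard InChI (first occurrence wins; dropped duplicates are
logged), and writes a column-oriented HDF5 file sorted by exact mass with
a JSON manifest sidecar. Retrieval (`queryByMass()`) is a binary search
on the in-memory mass index plus a contiguous slice read; result order is
|Δmass| ascending with InChI-key tie-break, so reports are reproducible.

Molecules are handled neutral unless inherently charged (quaternary
ammoniums such as choline): those store the mass of the charged species
(atom sum minus charge × electron mass) with `charge != 0`, and the mass
window uses that stored mass as-is. Formal charge is read from the InChI
`/q` and `/p` layers; the molecular formula is taken from the
explicit-hydrogen atom block, so a species drawn deprotonated keeps its
drawn composition. Every record satisfies the invariant that
recomputing the monoisotopic mass from the stored formula (with the
electron correction) reproduces the stored mass to 1e-4 Da.

All structures are converted with explicit hydrogens before graph
extraction. This has two benefits: single-heavy-atom molecules (water,
methane) have a well-defined bond block, and fragment masses can be
summed directly over atoms.

# In-silico fragmentation

`enumerateFragments()` deletes every subset of at most `maxBonds` bonds
(default 2) of the molecular graph and records the neutral monoisotopic
mass of each resulting connected component, plus the intact parent mass.
Key modelling choices:

* **Simultaneous subset deletion, not recursive cleavage.** For a mass
  *set* with a bounded total number of cuts the two formulations are
  equivalent, and subset deletion needs no recursion-depth parameter.
* **Heavy-atom bonds only, by default.** Hydrogens remain attached to
  their heavy atom; `cleaveH = TRUE` switches to the explicit-hydrogen
  graph. The match-time ±1 H correction (below) absorbs hydrogen
  mobility, so cutting X–H bonds mostly inflates the pattern.
* **No valence repair.** A fragment's mass is the plain atomic-mass sum
  of the severed subgraph (homolytic bookkeeping). At the ±1 H match
  slack, electron and radical bookkeeping is immaterial.
* **No bond-breakage rates.** The pattern is a mass set; all fragments
  are equal a priori. Intensities enter only on the query side.

Masses are deduplicated within `dedupTol` (default 1e-4 Da, well below
instrument accuracy but above float noise), keeping the smallest of each
cluster; the parent is always retained. Ring bonds only produce fragments
when enough cuts disconnect the graph — benzene with one cut yields only
the parent, with two cuts the C<sub>k</sub>H<sub>k</sub> arc series.

The test suite checks this implementation against an independent
brute-force oracle (union-find over explicit bond subsets) on 50 fixture
metabolites with up to 12 heavy atoms, and checks mass conservation
(two-fragment cuts sum to the parent within 1e-6 Da).

# Query spectra

`readSpectra()` reads MGF blocks or two-column TSV peak lists.
`mergeSpectra()` pools multi-collision-energy spectra of one precursor —
the merged result is roughly a ramp-mode acquisition — combining peaks
closer than `mzMergeTol` (default 0.002 Da, comfortably inside a
0.005 Da accuracy bound) into intensity-weighted mean positions, then
normalizing intensities to sum to 1. Merging is permutation-invariant
and normalization idempotent; both are asserted as properties in the
tests. Collision energy is parsed but unused by the scorers.

Adducts are a small editable table (`adductTable()`): each maps neutral
mass M to observed m/z via mz = (M + δ)/|z| with δ including the
electron mass (δ = +1.007276 Da for [M+H]+). An optional isotopologue
shift of n × 1.003355 Da supports annotating ¹³C isotope peaks against
the monoisotopic pattern.

# Scoring

**FragScorer** (`fragScore()`): each predicted neutral fragment mass
generates candidate ion m/z values under the query's adduct; with the
hydrogen correction enabled (default) also at ±1.007825 Da on the
neutral mass *before* adduct arithmetic. A query peak matches if it lies
within `max(20 ppm, 0.005 Da)` of any candidate ion; the score is the
summed intensity of matched peaks, each peak counted once (the recorded
match is its nearest candidate). On a normalized spectrum the score is
in [0, 1], and it is monotone both in the tolerance and in enabling the
H correction.

**FingerScorer** (`trainFingerModels()` / `fingerScore()`): the
featurization is a binned peak-intensity histogram over [0, mzMax] at
`binWidth` (default 0.01 Da) concatenated with equally binned
neutral-loss (precursor − peak) intensities. The per-bit SVMs however
see *presence/absence* per bin rather than raw intensities: a fragment's
diagnostic value for a substructure bit is whether it appears, and
near-zero intensities would otherwise crowd the decision boundary. This
binarization is recorded in the model set so scoring is reproducible.
Only bits with training occupancy in the closed interval [0.05, 0.95]
get a model (class balance; the boundary is deliberately inclusive —
occupancy exactly 0.05 or 0.95 is selected); the rest are predicted as
their training majority value. The SVM cost is chosen by an inner CV
inside each training fold (nested cross-validation, linear kernel); the
reported per-bit accuracy is the outer held-out mean. Candidate ranking
uses Jaccard similarity over the *selected* bits only — unselected bits
are majority-constant and would inflate every candidate's similarity
uniformly. An empty union (both fingerprints all-zero over selected
bits) is defined as similarity 1.

**Fusion** (`combineAndRank()`): TotalScore is the product of the
enabled scorers' values — a conjunction: a candidate must look right to
every scorer. One enabled scorer passes through unchanged. Ties break by
descending fragmentation score, then |Δmass|, then InChI key, making
full rankings deterministic. The report also carries each candidate's
score relative to the set maximum, which is more comparable across
queries than the absolute TotalScore.

# Filters

Between retrieval and scoring, three optional filters only ever remove
candidates (they are pure and commute): exact formula match after Hill
normalization (for formulas fully determined upstream, e.g. by an
isotope-pattern engine), element-set containment (e.g. "CHNOPS"), and a
metabolite-likeness SVM over the full compound fingerprint
(`trainMetaboliteClassifier()`, radial kernel, 5-fold CV accuracy
reported; threshold default 0.5). The likeness filter ships *off* by
default: it restricts the search space to biology-like compounds, which
is wrong for e.g. drug metabolites unless the user opts in. No
pre-trained model ships with the package; the classifier is trained on
user-supplied or synthetic labels.

# The synthetic benchmark generator

`makeToySet()` draws compounds from a curated list of 138 real
metabolite structures (amino acids, organic acids, sugars, nucleobases,
amines, lipids — shipped as a plain-text fixture) and simulates one MS2
spectrum per compound from its own fragmentation pattern: a random
subset of fragment ions, Gaussian m/z jitter, uniform decoy peaks, and
Dirichlet(1, …, 1) intensities normalized to 1. Defaults — 8 true peaks,
jitter σ = 0.001 Da, 4 decoys, [M+H]+ — put the jitter well inside the
match tolerance while the decoys carry a third of the intensity, making
self-retrieval sharp but not trivial.

`makeConfusableBenchmark()` stresses the filters specifically: 30% of
the store compounds are paired with a real metabolite of the same
*nominal* mass but different formula (element-set-differing pairs
preferred — e.g. hypoxanthine C5H4N4O vs threonic acid C4H8O5), and the
paired queries are chimeric, with 70% of their intensity at
decoy-specific fragment ions. Retrieval at a unit-resolution window then
ranks the decoy first until the element or formula filter removes it;
because the true compound passes both filters, the filters can never
demote it — the top-1 rate is structurally monotone, which the
acceptance tests assert together with the strict gain on the confusable
subset.

What the generator does *not* emulate: fragmentation intensity
structure (intensities are exchangeable noise, so passing self-retrieval
says nothing about modelling real intensity patterns),
collision-energy dependence, isotope envelopes, co-eluting chimeras
beyond the constructed case, and electrospray adduct diversity within
one run. Results on these benchmarks are an internal-consistency
surface, not an estimate of retrieval rates on experimental spectra.

# Parameters that matter

| Parameter | Default | Unit | Where | Why |
|---|---|---|---|---|
| `maxBonds` | 2 | bonds | fragmenter | pattern size grows combinatorially; two cuts cover most observed fragments |
| `dedupTol` | 1e-4 | Da | fragmenter | below accuracy, above float noise |
| retrieval `tol` | 20 | ppm | `annotate()` | high-accuracy instrument assumption |
| `matchPpm` / `matchDa` | 20 / 0.005 | ppm / Da | FragScorer | the larger of the two applies at a given m/z |
| `hCorrection` | on | — | FragScorer | ±1 H on neutral fragments; absorbs tautomerism |
| `mzMergeTol` | 0.002 | Da | merging | intra-merge peak clustering |
| occupancy bounds | [0.05, 0.95] | fraction | FingerScorer | closed interval; class balance for per-bit SVMs |
| `binWidth` / `mzMax` | 0.01 / 500 | Da | featurization | bin ≈ 2× match tolerance; benchmarks use 1 Da bins to keep the feature space small |
| likeness threshold | 0.5 | probability | filter | uninformative prior; filter off by default |
| `topN` | 20 | candidates | reports | reporting depth, not a scoring parameter |

# Problem sizes in the shipped benchmarks

The acceptance tests and `scripts/acceptance.R` use: 50 molecules × 3
fragmenter depths against the brute-force oracle; a 100-compound store
with 100 simulated queries for FragScorer self-retrieval; 100 wired
(spectrum, 16-bit fingerprint) pairs with 5-fold nested CV for the
fingerprint predictor; 400 synthetic fingerprints for the likeness
classifier; and a 100-compound confusable store with 70 queries (30
chimeric). These sizes exercise every code path at comfortable desk
scale; all scale linearly if enlarged.

# Known limitations

* Fragment patterns are mass sets without breakage energetics; isomers
  with identical heavy-atom graphs (stereoisomers) are indistinguishable
  to FragScorer and tie-broken lexicographically.
* The fingerprint layouts ship as OpenBabel family concatenations
  (`reference`: FP2+FP3+FP4+MACCS = 1856 bits; `toy`: MACCS = 256).
  The layout is pluggable and recorded in the store manifest — nothing
  downstream assumes a particular length — but models and stores must
  share a layout, which is checked at job start.
* The spectral featurization is a pragmatic binned representation;
  kernel methods over fragmentation trees would be stronger but require
  per-query tree inference, which conflicts with the engine's
  pre-computation design.
* One compound per query spectrum is assumed; deconvolution of chimeric
  spectra is upstream work.
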
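---
title: "Methods: fingerprints, the training protocol, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprints, the training protocol, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsardnn)
```

`qsardnn` is a benchmark pipeline for single-task QSAR regression with
feed-forward neural networks on pair-count fingerprints. This vignette is
the package's account of the science inside it: what each stage computes,
which choices were genuinely open and how they were fixed, and what the
synthetic benchmark does and does not demonstrate.

## Pair-count fingerprints

A molecule enters the pipeline as a hydrogen-suppressed graph: heavy atoms
with element, formal charge and an attached-hydrogen count, plus bonds
typed single/double/triple/aromatic. For every unordered pair of heavy
atoms at topological distance $1 \le d \le d_{\max}$ (shortest bond path),
the descriptor `type_i – d – type_j` is counted. Two atom-typing schemes
are provided:

* **AP (atom pair)**: element, heavy degree (bonded non-hydrogen
  neighbours) and π-electron count, written `El(degree,π)`.
* **BP (binding property / donor–acceptor pair)**: one of seven
  pharmacophoric classes — cation, anion, neutral donor, neutral
  acceptor, polar, hydrophobic, other.

Three conventions had to be fixed because the descriptor family is
described in the literature at the level of ideas, not of rule tables:

* **π-electron counting.** A double bond contributes 1 π electron to each
  end atom, a triple bond 2, an aromatic bond 1. This matches common
  atom-pair implementations; an explicit `pi_electrons` column on the
  atom table overrides it per atom.
* **BP rule table**, evaluated in fixed precedence: formal charge > 0 →
  cation; < 0 → anion; then for N/O, *donor* means at least one attached
  hydrogen and *acceptor* means an available lone pair (O always; N when
  heavy degree + attached hydrogens ≤ 3), with donor∧acceptor → polar,
  donor → neutral donor, acceptor → neutral acceptor; then C and the
  halogens → hydrophobic; everything else (S, P, metals) → other. The
  precedence makes the assignment total and unambiguous — e.g. a
  protonated amine is a cation regardless of its hydrogens, and a
  hydroxyl oxygen is polar.
* **Distance cutoff** $d_{\max}$: default 7 bonds, configurable. The
  descriptor definition leaves the cutoff open; 7 keeps the vocabulary in
  the usual atom-pair range. Pairs in different connected components are
  at infinite distance and never counted.

Keys serialize as `"AP|C(1,0)|2|C(2,0)"` with the endpoint types sorted
lexicographically, so a fingerprint is invariant under any relabelling of
atom indices, and keys are stable CSV headers. For a connected molecule
with $n$ heavy atoms and $d_{\max}$ at least the graph diameter, counts
total exactly $n(n-1)/2$ — one per pair — which the test suite checks
against a brute-force enumeration oracle (an independent BFS plus
exhaustive pair loop) on hundreds of random graphs.

SDF input delegates parsing to ChemmineR; explicit hydrogens are folded
into their neighbour's count, and remaining implicit hydrogens come from a
standard-valence model (C 4, N 3, O 2, halogens 1; aromatic bonds counting
1.5; charges shift the valence of N/O). This fills a gap rather than
replicating any particular toolkit's perception model, and is the one
place where typing can differ from descriptor sets generated elsewhere.

## Dataset handling

An activity table is `(molecule id, activity, descriptor counts...)`.
Activities are used exactly as given — these values (pIC50, pKi, log D,
...) are already logarithmic, so no normalization or centering is applied
anywhere in the pipeline, and value ranges legitimately differ across
targets. Competition-style files omit descriptor columns that are
all-zero within a split, so the two splits of a target differ in width;
`align_vocabularies()` restores the union vocabulary (sorted
lexicographically for reproducible column order) by zero-padding, never
altering a stored count. The unified width is what makes per-epoch
test-set evaluation cheap.

The LOG settings transform descriptor entries by $\log(1+x)$ — the only
finite logarithmic choice on count data with zeros — and leave activities
untouched.

## The regressor and the training protocol

The model is a fully connected network: hidden layers with ReLU, inverted
dropout (masks scaled by $1/p_{\text{keep}}$ at training time, evaluation
always dropout-free), and a single linear output neuron. The loss is the
mean squared error; the optimizer is Adam. Parameters the protocol fixes
per setting: hidden sizes, per-hidden-layer dropout percentages (input
layer always 0 %), mini-batch size, and the optional log transform. The
reference grid of 13 settings spans depth (HL4–HL1 at a constant 8000
hidden neurons), width (HL1/2–HL1/16), mini-batch size (HL4//k = batch
100/k), and the LOG variants.

Choices left open by the protocol's description, fixed here and exposed in
`train_config()` / `build_model()`:

* **Adam constants**: α = 0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e−8 — the
  customary defaults.
* **Initialization**: He-style fan-in-scaled normals,
  $W \sim N(0, 2/\text{fan\_in})$, biases zero, no pre-training.
* **Mini-batching**: molecules are reshuffled every epoch; the final
  partial batch is trained on, so updates per epoch are
  $\lceil n_{\text{train}} / \text{batch} \rceil$.
* **RNG discipline**: run $r$ of a setting uses seed
  $\text{base\_seed} + r - 1$; within a run, initialization and the
  shuffle/dropout sequence draw from two independent streams
  (the second seeded at seed + 1000003), so changing the epoch count
  never changes the initial weights. Streams snapshot and restore
  `.Random.seed`, leaving the caller's RNG untouched. Training is
  bit-reproducible given (seed, setting, data).

The evaluation protocol: after every epoch the test-set squared Pearson
correlation is computed with dropout off; a run's score is the **best**
value of this trace (ties resolve to the first maximizing epoch); a
setting's score on a target is the mean best-R² over `n_runs` repeated
runs (default 5); the grid report adds a per-setting average across
targets and a per-target standard deviation across settings. Selecting
the epoch on the test trace is deliberate replication of the benchmark's
design and is labelled for what it is — an *oracle-epoch* score that
upper-bounds blind-test performance. The report therefore also carries
the final-epoch cell matrix (`final_cells`) as the honest companion
metric, and every run can emit a JSON log (seed, setting, full traces) so
the means are auditable.

Numerical conventions: all accumulation is double precision; the R²
of a zero-variance vector (a collapsed, constant-output model) is defined
as 0 with a warning rather than NaN, so one degenerate epoch cannot crash
or win a 1000-epoch run.

## The synthetic benchmark

The generator produces datasets with the statistical structure the
pipeline assumes, so the whole stack runs and is testable without any
external download:

* **Counts**: per-column Bernoulli inclusion thinning a negative-binomial
  count (1 + NB(size = 1/dispersion, μ = 1)), with inclusion
  probabilities following a power law over column ranks (exponent 0.7),
  rescaled so the expected zero fraction matches `zero_fraction`. This
  reproduces the qualitative shape of substructure-count matrices — very
  sparse, a few ubiquitous scaffold descriptors, a long tail of rare
  fragments — without claiming any real target's distribution.
* **Vocabulary mismatch**: the test split shares `vocab_overlap` of the
  training columns and replaces the rest with novel ones, exercising
  alignment exactly as disguised competition files do.
* **Covariate shift**: test-split column frequencies are multiplied by
  log-normal factors of scale `shift_strength`, emulating the drift a
  time-series split induces.
* **Censoring**: assays report concentrations beyond their dynamic range
  as constants; with `censor_floor` set, activities below the floor are
  emitted as exactly the floor, and the censored fraction is monotone in
  the floor's level.
* **Mechanisms** (a complexity ladder): `linear_logD_like` is a sparse
  linear map of the counts placed in a log D-like window (location 2.5,
  unit scale) — simple partition-like chemistry, learnable without depth;
  `single_index_nonlinear` pushes one standardized latent index through a
  saturating tanh around a pKi-like level of 6.5 ± 1.5 and then through
  the Cheng–Prusoff relation IC50 = Ki·(1 + [S]/Km) with per-molecule
  log-normal [S]/Km jitter (sd 0.5), emulating assay-condition dependence
  of pIC50; `composed_multimechanism` combines three latent sigmoidal
  sub-responses as $\log_{10}(1 + 100\,u_1 u_2 (1-u_3))$ with
  heteroscedastic noise scaled by $0.5 + u_3$, an intentionally hard
  bioavailability-like composite. Active coefficients are sampled with
  probability proportional to column frequency: activity-driving
  substructures are common scaffolds, and signal placed on descriptors
  seen in a handful of molecules would be unlearnable by any method,
  synthetic or not.

Defaults are the package's standing study conditions: 1000 training and
300 test molecules, 400 descriptors per split, zero fraction 0.9,
dispersion 0.6, vocabulary overlap 0.8, shift 0.1, noise sd 0.25. The
ground truth (coefficients, noiseless activities, drawn substrate ratios)
is returned alongside the tables, and regeneration from the same spec is
bit-exact.

**What passing the synthetic suite shows — and does not.** It shows the
machinery is correct: fingerprints match brute-force enumeration,
alignment conserves counts, the protocol is deterministic, the network
optimizes its loss, and the qualitative orderings the benchmark design
predicts (smaller mini-batches help at fixed epochs; simple mechanisms
score higher best-R² than composed ones) emerge from the pipeline itself.
It does not show performance on real chemistry: synthetic counts carry no
activity cliffs, no correlated substructures from shared synthesis
campaigns, no assay noise structure beyond the stated models, and the
scaled-down networks (tens of neurons) are far from production size.
Quantitative R² values on real competition data are outside what this
test bed can certify.

## Problem sizes in the shipped checks

The test suite and the reproduction script use deliberately desk-scale
configurations: grids of 2 synthetic targets × 3 scaled settings (hidden
layers [64, 32], [64], [16]; batches 100 and 25) × 2 runs × 30 epochs,
mechanism comparisons over 3 seeds at 40 epochs, and oracle comparisons
over 200 random molecules of ≤ 12 atoms. These sizes were chosen so a
full check runs in about a minute on one CPU while still exercising every
protocol element (multi-run averaging, best-epoch selection, aggregate
recomputation) at genuine signal-to-noise; the full 13-setting grid with
thousands-of-neuron layers and 1000 epochs is the same code path scaled
up via `builtin_settings()` and `train_config()`.

## Known limitations

* The AP/BP typing conventions are documented package choices; exact
  vocabulary-level agreement with any proprietary descriptor generator is
  not claimable (or testable against disguised data).
* The trainer is plain R matrix arithmetic over BLAS — adequate for
  benchmarking and for the shipped problem sizes, but not tuned for
  thousands-of-neuron layers on tens of thousands of molecules.
* Oracle-epoch scoring is leaky by construction; use `final_cells` (or an
  external validation split) for any claim about prospective performance.
* The implicit-hydrogen valence model covers the common organic elements
  only; exotic valences fall back to zero added hydrogens.
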
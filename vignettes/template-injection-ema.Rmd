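---
title: "Template-injection estimation of protein model accuracy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-injection estimation of protein model accuracy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyrank)
```

## The protocol

Modern structure predictors emit calibrated confidence estimates —
per-residue pLDDT (a prediction of the local Distance Difference Test
score of their own output) and pTM (a prediction of the output's TM-score
against the true structure). `decoyrank` exploits those confidences to
rank candidate structures ("decoys") whose true accuracy is unknown. The
decoy is injected into the predictor as a *template*, the structural
prior channel through which predictors normally receive homologous
structures, and the target amino-acid sequence is supplied as the query.
If the predictor's internal scoring of sequence–structure compatibility
is good, its confidence in the resulting output tracks the quality of the
injected decoy.

Two precautions keep the decoy's amino-acid identity from leaking through
the template and biasing the confidence:

1. the template's one-hot sequence consists entirely of *gap tokens* (the
   symbol for a missing residue). Supplying the decoy's real sequence
   instead is known to cause overconfidence when it matches the target;
   `featurize_template(..., sequence_mode = "native")` exposes exactly
   that control, and nothing else changes between the two modes (a unit
   test asserts that only the one-hot block differs);
2. all side-chain atoms beyond Cβ are removed, and every residue —
   glycine included — receives a Cβ so that it participates in the
   template's Cβ distance matrix. Missing Cβ atoms are rebuilt from the
   local backbone frame (`virtual_cbeta()`).

Each decoy is then scored by the composite confidence

$$ c = \frac{\overline{\mathrm{pLDDT}}}{100} \cdot \mathrm{pTM} \cdot
   \mathrm{TM}(\mathrm{decoy}, \mathrm{output}), $$

a product in $[0,1]$. The TM factor exists because the confidences
describe the predictor's *output*, which can drift away from the decoy it
was seeded with; multiplying by the decoy-to-output TM-score transfers
the confidence back onto the decoy being ranked.

Two aggregation choices are deliberately explicit. pLDDT enters as the
unweighted mean over residues (the community convention; a
`plddt_aggregate` knob offers the median). The TM factor is normalized by
the decoy length; decoy and output share the target sequence, so the
choice is symmetric in practice, but fixing it makes the score
deterministic.

## The predictor contract and the mocks

The predictor is pluggable: anything that maps
`(target sequence, optional template, recycles, seed)` to a structure,
per-residue pLDDT, pTM and a distogram satisfies the contract
(`new_predictor()`, validated by `predict_structure()`). An adapter for a
real network would translate the feature encoding (the 22-token alphabet
order is fixed in one place for that reason) and pass its confidences
through; it is intentionally out of the testable core, because weights
are a multi-gigabyte external artifact.

The shipped mocks make every downstream protocol runnable at desk scale:

* `geometry_mock()` scores local backbone plausibility with no knowledge
  of any native: per-residue $p_i = 100\,
  \exp\!\big[-\big(\bar e_i/0.5\big)^2\big]$ where $\bar e_i$ is the mean
  absolute deviation of the residue's virtual CA–CA bonds from 3.8 Å,
  damped multiplicatively by the fraction of non-neighbor CA pairs closer
  than 3.5 Å; pTM is a rescaled logistic of the mean. The 0.5 Å width
  means a backbone whose virtual bonds are off by half an Ångström loses
  roughly a factor $e$ of plausibility — tight enough to separate noise
  rungs, loose enough not to zero out realistic decoys.
* `oracle_mock(native)` is a pipeline-correctness oracle, not a
  simulation: it returns pLDDT $= 100\times$ true per-residue lDDT of the
  template against a hidden native, pTM $=$ true TM-score, and a
  distogram one-hot at the native Cβ distances. With it, end-to-end
  ranking must recover true quality almost perfectly, which is exactly
  what the acceptance suite asserts.
* `sequence_match_mock()` and `planted_generator_mock()` plant a signal
  (a hidden sequence / key) whose recovery the optimizers are tested on.

All mocks return the template backbone as the output structure; the TM
factor of the composite is then exactly 1, so the mocks probe the
confidence path in isolation.

## Metrics

TM-score, GDT_TS and lDDT are implemented natively on the CA trace, with
positional residue correspondence (decoys share the target sequence, so
no alignment search is performed) over the intersection of residues with
CA present in both structures; the normalization length defaults to the
reference length, so incomplete decoys are penalized.

* **TM-score** uses $d_0 = 1.24\,(L-15)^{1/3} - 1.8$ floored at 0.5 Å
  (the formula is non-positive below $L \approx 21$ and undefined below
  15). The maximization over superpositions seeds Kabsch fits from
  contiguous windows (plus every 3- and 4-subset for chains of ≤ 10
  residues) and iterates include-set refits until the set fixes. For
  short chains the floored $d_0$ makes the objective spiky, and the
  subset-refined optima land slightly off-center; the leading distinct
  candidates are therefore polished with a multistart Nelder–Mead search
  over the six rigid-motion parameters, using a fixed table of start
  offsets so the metric never touches the global RNG. The test suite
  checks the result against an independent dense rotation-grid oracle to
  $10^{-3}$ on perturbed pairs in the decoy regime (noise ≤ 0.75 Å). At
  extreme noise (TM ≈ 0.2) the floored-$d_0$ landscape degenerates into
  many near-tied micro-basins and *no* finite-seed global search — grid
  or subset-based — is reliable to $10^{-3}$; that regime is outside what
  decoy ranking needs and outside what we claim.
* **GDT_TS** averages, over the 1/2/4/8 Å thresholds, the maximal
  fraction of CA atoms within threshold. The search seeds from all
  contiguous windows of lengths 3–7 plus the global fit and iterates
  threshold-subset refits; converged include-sets are memoized across
  seeds. This is a documented deterministic heuristic, not the LGA
  program. A fixed-frame mode (no superposition) exists so hand-counted
  examples are exact.
* **lDDT** is superposition-free: reference CA–CA pairs within 15 Å and
  sequence separation ≥ 2 are tested for distance preservation at
  0.5/1/2/4 Å; a residue's score is the mean preserved fraction over its
  pairs and the global score is the mean over residues with at least one
  pair. (Classical all-atom lDDT differs in using all atoms and slightly
  different pair rules; this CA variant is what the mocks and the
  ranking statistics need.)

Kabsch superposition is the standard SVD construction with the
determinant correction; Spearman correlation is mid-rank Pearson (via
`stats::cor`), with explicit errors on degenerate input.

## Ranking statistics

`evaluate_target()` reports, per target, the Spearman correlation between
composite and true TM, the top-ranked decoy (ties break
lexicographically, so rankings are deterministic), its true TM, and the
top-1 GDT_TS loss — best achievable GDT_TS minus the GDT_TS of the decoy
actually picked. `ema_evaluation()` compares methods the way EMA
assessors do: targets whose best decoy has GDT_TS ≤ 0.4 are dropped
(nothing worth finding), and per surviving target each method's loss is
converted to a Z-score over methods, $(\overline{\ell} - \ell_m)/s_\ell$
with the sample standard deviation, signed so lower loss scores higher.
We deliberately use the simple estimator — no iterative outlier trimming
or flooring at $-2$ as in full assessor pipelines — because it is
deterministic and sufficient for method comparison; this divergence is
documented rather than hidden. GDT_TS lives on $[0,1]$ internally (the
CLI offers a display scale). Figure-style uncertainty is provided as a
percentile bootstrap of the mean (10,000 resamples, fixed seed).

## The optimizers

Both application protocols are black-box searches over the predictor
contract with a pluggable proposal engine; the shipped engine is a greedy
discrete hill-climb (1 uniform point mutation per step, strict-improvement
acceptance, 1000 steps by default — the simplest reproducible baseline;
every knob sits in `config`). Gradient ascent through a differentiable
predictor is specified at the interface level only (a capability tag),
since true backpropagation exists only inside a real network.

**Fixed-backbone design** (`design_sequence()`) featurizes the target
backbone once as a gap-token template and minimizes the categorical
cross-entropy between the predictor's distogram and the template's Cβ
distances. The cross-entropy is the differentiable surrogate for the
composite score: when the predictor is unsure, its distance distributions
widen and the cross-entropy rises, so the surrogate also tracks
confidence. The pair mask includes all $|i-j| \ge 1$ pairs with valid
Cβ — near-diagonal pairs keep the loss sensitive to local geometry — and
probabilities are floored at $10^{-12}$. The loss is exactly 0 iff every
scored pair is one-hot on the target bin, which happens with the oracle
mock; a flat landscape like that is detected (no proposal changes the
loss within a patience window) and reported instead of searched further.

**Structure search** (`fold_by_search()`) maintains a mutable generator
input sequence, initialized to the target sequence. Each step the
generator predicts a candidate structure (no template), the candidate is
featurized as a gap-token template, the discriminator predicts the target
sequence with it, and the composite confidence is the objective. The
best-so-far objective is non-increasing in loss terms / non-decreasing as
a maximization by construction, and `steps = 0` returns the single-pass
baseline. Step counts and proposal rates are ours — the protocol itself
does not prescribe them — and are labeled as such.

The distogram bin layout (64 bins, inner edges 2.3125–21.6875 Å in
0.3125 Å steps, open final bin) mirrors the published distance-head
convention and is configurable.

## The synthetic generator

`make_toy_native()` builds idealized backbones in torsion space with
ideal bond geometry (helix at φ = −57°, ψ = −47°, ω = 180°; a
helix-hairpin with a fixed four-residue turn chosen so the helices pack
without CA clashes; a random-compact sampler drawing per-residue torsions
from helix/sheet/polyproline basins with whole-chain rejection of
non-neighbor CA contacts under 3.5 Å). `perturb_structure()` degrades a
native gradually: Cartesian mode draws i.i.d. Gaussian residue
displacements, smooths them along the chain with a window-5 moving
average and rescales to RMS σ per coordinate — whole residues move
rigidly, so bond geometry degrades gracefully the way real decoys do
(unsmoothed i.i.d. noise would wreck bond geometry at almost no TM cost
and decouple the geometry mock's signal from true quality, which is why
the smoothing exists); torsion mode jitters φ/ψ and rebuilds with ideal
geometry. Ladders derive one sub-seed per decoy from a stable
multiplicative hash of (seed, rung, index), so regeneration is
byte-identical regardless of order.

What the generator emulates is precisely the property the statistics
need: a graded, wide spread of decoy quality around a known native, with
local geometry that degrades together with global accuracy. What it does
not emulate: fragment-assembly artifacts, side chains beyond Cβ,
compactness under a physical force field, sequence-dependent geometry.
Green tests therefore demonstrate pipeline correctness and statistical
behavior under known signal, not performance on physical decoy sets —
that requires a real predictor adapter and real decoys.

## Problem sizes and numerical choices

The shipped experiments use ladders of 10 targets × 50 decoys at 32
residues, ten-rung geometry-mock ladders at 30 residues, 30-residue
design runs of 2000 steps, and 40-step generator–discriminator searches
at 20 residues — sizes at which every protocol completes in minutes on
one CPU while leaving the statistics well clear of their thresholds
(observed: mean Spearman ≈ 0.99 under the oracle against a ≥ 0.95 check;
geometry-mock rank correlation ≈ 0.96 against ≥ 0.8).

Degenerate inputs are errors, not silent fallbacks: fewer than 3 common
CA atoms, constant vectors in a correlation, an all-tied loss column in a
Z-score, a backbone frame too collinear to place a Cβ, templates whose
length disagrees with the sequence. Residues whose Cβ cannot be
virtualized have their distance-matrix pairs flagged invalid rather than
silently substituted (a `ca_fallback` flag enables CA substitution
explicitly). ω is assigned to the peptide bond preceding each residue,
with the first residue masked; side-chain torsion channels are masked
invalid rather than zeroed, and the alternative (zero-filling) would be
an adapter-level decision.

## Known limitations

* No real-network adapter ships; all empirical claims are about the
  protocol machinery under mocks.
* TM-score/GDT_TS searches are strong deterministic heuristics, not
  certified global optima (see the metrics section for the regime where
  equivalence with an independent searcher is asserted).
* lDDT is CA-based; multi-chain assemblies, mmCIF, heteroatoms and NMR
  multi-model files are out of scope (first MODEL only, one chain per
  structure).
* The Z-score comparison uses the simple sample-sd estimator, not the
  full assessor protocol with outlier exclusion.
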
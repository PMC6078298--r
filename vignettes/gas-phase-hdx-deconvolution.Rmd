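---
title: "Resolving co-populated oligomer conformers by gas-phase HDX-MS envelope deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving co-populated oligomer conformers by gas-phase HDX-MS envelope deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxgold)
```

## The measurement and the model

Gas-phase hydrogen/deuterium exchange mass spectrometry (gas-phase
HDX-MS) exposes electrosprayed peptide ions to ND~3~ gas inside the
instrument, on sub-millisecond timescales. Under these conditions only
heteroatom-bound side-chain and terminus hydrogens exchange; backbone
amide protons exchange far too slowly in vacuum to be observed, so they
are excluded from every count in this package. For amyloid-beta 1--40
the neutral molecule carries 27 such exchangeable protons, distributed
very unevenly: 19 sit in the N-terminal 16 residues, 8 in the C-terminal
24. In positive mode each of the $z$ charging protons is itself
exchangeable, so an ion's total site count is
$n_\mathrm{sites} = n_\mathrm{monomers}\cdot n_\mathrm{neutral} + z$
(e.g. 32 for the 5+ monomer). The per-residue neutral-form table behind
these numbers (`default_exchange_table()`) assigns Asp/Glu/Ser/Thr/Tyr/
His/Trp/Cys one hydrogen, Gln/Asn/Lys two, Arg four, two for the free
N-terminal amine and one for the free C-terminal acid; it is overridable
from a flat YAML/JSON config.

Native ESI of oligomerizing peptides produces overlapping n-mer/charge
signals. Ions sharing a charge density (charge per monomer, `CpM`)
overlap *exactly* in m/z: the 2164--2169 window of amyloid-beta contains
MON^2+^, DIM^4+^, TRI^6+^ and TET^8+^ at CpM 2, distinguishable only by
their 1/z isotope spacing or by ion-mobility drift time. Uptake may be
compared across oligomer orders only at matched charge density, which is
why the pipeline reports HDX per monomeric unit (HDX/M) and why
`compare_variants()` matches ions by CpM before differencing.

## The single-state family

The central modelling assumption: within one conformational state every
exchangeable site exchanges with the same probability $f$. The number
of incorporated deuterons is then $\mathrm{Binomial}(n_\mathrm{sites},
f)$ and the deuterated envelope is the natural isotope envelope
convolved with that distribution, each deuteron adding
$\Delta m_D = 1.006277$ Da. The binomial is computed exactly by
convolution (no normal approximation); uptake in deuterons is always a
centroid shift divided by $\Delta m_D$.

The equal-probability assumption is deliberately conservative. For any
per-site probability vector $p$ with mean $\bar p$, the count variance
is the Poisson-binomial $\sum_i p_i(1-p_i) \le n\,\bar p(1-\bar p)$,
with equality only when all $p_i$ are equal. A single state can
therefore never be *wider* than its equal-probability model, and the
number of states recovered against this family is a lower bound on the
true number — heterogeneous-rate single states must never be split, a
property the test suite checks directly against Poisson-binomial
forward simulations.

`build_family()` generates the theoretical dictionary: 200 single-state
envelopes at uptake fractions $k/199$, $k = 0\ldots199$, spanning 0% to
100% inclusive (the endpoints-inclusive reading of the grid; the
undeuterated envelope is always the first member).

## Deconvolution

`deconvolve_envelope()` fits one ion's deuterated envelope:

1. Control and deuterated centroid lists are converted from m/z to the
   oligomer mass domain (equivalently per-monomer mass times
   $n_\mathrm{monomers}$); fitting in m/z would be equivalent up to
   scaling.
2. The family is built from the *control-derived* envelope — not a
   theoretical envelope — so that instrument peak-shape and minor
   adducts common to both spectra cancel.
3. Measured and theoretical envelopes are rendered as 500-element
   vectors: Gaussian kernels at the centroid positions, sampled on a
   uniform grid over `[control centroid - 5 D, control centroid +
   n_sites * dm_D + 5 D]`. Columns are normalized to unit sum.
4. The linear system is solved with the boosted Gold algorithm
   (defaults 10000 iterations, 100 boosting steps, $p = 1.2$).
5. Runs of adjacent non-zero family weights are merged into one
   component each, with uptake linearly interpolated
   (weight-weighted) between member uptakes; weights below 1% of the
   total are zeroed first. Component uptakes are reported per monomer.

### Numerical choices

**Kernel width.** The Gaussian kernel sigma defaults to 0.75 times the
1.00235 Da average isotope spacing. The choice is a compromise measured
during development: the kernel must be a few grid steps wide (the
500-point grid over a typical monomer range has ~0.08 Da steps) so the
discretized system is smooth, but a kernel as wide as 1.5 spacings
makes the columns of closely spaced family members nearly collinear, and
the solver then misplaces components separated by ~3.5--4 D even on
noiseless data. At 0.75 spacings, mixtures with components 3 D apart
are recovered reliably; the parameter stays exposed (`sigma`).

**Solver schedule.** The Gold update
$w_i \leftarrow w_i\,(A^\top y)_i/(A^\top A w)_i$ preserves
non-negativity and converges to a non-negative least-squares fixed
point, but slowly along the flat directions created by overlapping
columns. Boosting ($w \leftarrow w^p$, renormalized) sharpens the
iterate toward few non-zero members. Two scheduling details matter and
are deliberate:

* boosting is confined to the second half of the iteration budget
  (`burnin = 0.5`): sharpening the still-diffuse early iterate locks
  weight onto misplaced members that the multiplicative update cannot
  recover (a zeroed weight can never regrow);
* a run never ends on a raw boost — the final block is always pure
  refinement, so reported weights satisfy the Gold fixed point rather
  than a freshly sharpened $w^p$ (ending on the boost biases mixture
  weights by a few percent).

Both were validated against a non-negative least-squares oracle and
seeded mixture recovery (40 random 2--4-component mixtures across two
disjoint seed sets). Early stopping on a $10^{-10}$ relative-residual
plateau is enabled by default and changes nothing but runtime.

**Merging and thresholds.** The 1% `min_weight` threshold encodes the
distinction between "major" and "minor" forms; if every weight falls
below it the fit degrades to a single flagged low-confidence component
at the weighted-centroid uptake. Ties and degenerate inputs: an empty
centroid window is an error, a deuterated envelope identical to the
control yields one component at 0 D.

## Assignment and drift-time splitting

`isobar_family()` enumerates the (n, z) ions whose average-mass m/z
falls in a window; `infer_charge_from_spacing()` recovers z from the
1/z isotope comb by an area-weighted vote over adjacent gaps, demanding
a 60% supermajority and <20% gap dispersion, and flags overlapped combs
(peaks off the winner's lattice holding >10% of the area) as mixed.
`drift_profile()` projects an m/z window of a 2D IM-MS map onto drift
time; `detect_conformer_split()` reports prominence-filtered apexes
(default 10% — the data give no sharper criterion for a "split"
signal) with valley-to-valley integrated shares; the shortest-drift
apex is labelled *compact*, the longest *extended*.
`slice_envelope_at_drift()` then extracts per-conformer envelopes so
compact and extended populations can be deconvolved separately. Drift
times stay in milliseconds throughout; collisional cross-section
calibration is out of scope.

## The synthetic-data generator

`simulate_spectrum()` / `simulate_drift_map()` generate ground-truthed
data with exactly the statistical structure the analysis assumes:
overlapping oligomer/charge envelopes, each a mixture of conformers
with distinct binomial uptake fractions, Gaussian peak shapes (default
sd 0.02 m/z, resolving isotopes up to charge 8), separable Gaussian
drift profiles, additive Gaussian noise (default sd 0.5% of the signal
maximum) with optional Poisson counting noise, all driven by one
recorded seed. Reagent flow-rate labels (20/30/40/50 mL/min) map to
multiplicative fraction scalings 0.4/0.6/0.8/1.0 — a phenomenological
stand-in for the observed flow dependence of labeling, not a kinetic
model. Conformer fractions are per species, not per charge state.

What the generator deliberately does *not* emulate: chemical noise and
baseline, adducts, detector saturation, m/z-dependent resolution,
ND~3~ collision-complex kinetics, charge-site microsolvation. Passing
recovery tests on this generator therefore demonstrate correctness of
the inference chain under its own assumptions, not robustness to every
artifact of real spectra.

The bundled scenarios (`fixture_suite()`) encode the canonical study
conditions: a monomer 2+ with four states at 4/10/18/28 D, a dimer 4+
with three states at 4/9/14 D per monomer, a trimer 6+ drift map with a
compact (6 D, 60%, 5 ms) / extended (10 D, 40%, 8 ms) split, a
fully-scrambled-variant-like single-population map, and a small
unimodal Leu-enkephalin-style control. The scrambled stand-ins
(`abeta_scrambles()`) are fixed synthetic permutations of the WT
sequence; every in-scope quantity is permutation-invariant.

## Problem sizes and runtime

The defaults used throughout the tests are the analysis defaults: a
200-member family vectorized on 500 points solves in well under a
second per ion; the full test suite (including 20-mixture recovery
studies and all end-to-end fixture gates) runs in about half a minute.
Simulated spectra use a 0.005 m/z grid over the envelope's
neighborhood; drift maps use 0.01 m/z by 0.2 ms.

## Known limitations

* Components closer than ~3 D per monomer merge or trade weight; this
  is the resolution limit of the widest-envelope family, not a solver
  defect (the count remains a lower bound by construction).
* The "slower" subset of side-chain hydrogens is not modelled
  kinetically; all counted sites are treated identically, so partial
  protection appears as a reduced uptake fraction.
* Negative-mode spectra, metal adducts, PTMs, disulfides and per-site
  exchange-rate chemistry are out of scope; charge carriers are always
  protons at 1.007276 Da.
* 1D mode pairs control and deuterated spectra by metadata only — no
  retention or drift alignment is attempted.
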
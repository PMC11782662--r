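---
title: "Real-space modelling of condensate SAXS and the XL-MS pipeline"
author: "condensaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-space modelling of condensate SAXS and the XL-MS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensaxs)
```

# The scientific problem

Phase-separated protein droplets scatter X-rays in a way that encodes their
interior organisation. When a small-angle X-ray scattering (SAXS) signal
from droplets decays as $I(q) \propto q^{-d}$ over a wide window of momentum
transfer $q$, the interior behaves as a mass fractal of dimension $d$: the
mass inside a radius $r$ grows as $r^d$, so $d = 2$ indicates an open,
chain-like network rather than a homogeneous liquid ($d = 3$) or a surface
fractal. For the microtubule plus-end tracking protein Bik1 — an elongated
coiled-coil dimer orthologous to CLIP-170 — droplet SAXS shows exactly this
$q^{-2}$ regime between roughly 300 and 3000 Å.

`condensaxs` turns that qualitative observation into real-space models. It
fits measured (or simulated) droplet profiles with two particle
representations refined by reverse Monte Carlo (RMC), quantifies the fitted
structures with translational and orientational order metrics, generates
synthetic inputs with known ground truth so the whole pipeline is testable
end to end, and implements the post-identification crosslinking mass
spectrometry (XL-MS) computations used to track the protein's
conformational rearrangements between dilute and condensed states.

# Scattering model

## Gaussian blobs

The coarse mass distribution is modelled by $N$ Gaussian blobs of common
standard deviation $\sigma$ inside a bounding sphere. Blobs are convenient
because both real- and reciprocal-space representations are Gaussian: the
form amplitude is $f(q) = e^{-q^2\sigma^2/2}$ (`blobFormAmplitude()`). The
droplet-scale defaults are 4000 blobs, $\sigma = 40$ Å, in a 10,000 Å
sphere.

## The Gaussian window

A finite container would contribute its own form factor at low $q$ and
corrupt the fit. A Gaussian window of width $\sigma_w$, centred on the
configuration's centre of mass, multiplies every copy amplitude
(`windowWeight()`), suppressing the container envelope so only internal
structure is fitted. The window sets the resolution $q_{\min} = 2\pi/\sigma_w$
(`fitResolution()`): $\sigma_w = 3000$ Å gives $\approx 0.002$ Å$^{-1}$
(blob stage), $\sigma_w = 1500$ Å gives $\approx 0.004$ Å$^{-1}$
(spherocylinder stages). `fitConfig()` refuses windows below this
resolution; a 5% grace factor accepts the conventionally rounded
0.002 Å$^{-1}$ for $\sigma_w = 3000$ Å, whose exact value is
0.00209 Å$^{-1}$.

During refinement the window centre is computed once, at fit start, and
held fixed. A single-particle move shifts the centre of mass by
$O(\mathrm{step}/N) \approx 0.01$–$0.05$ Å, five orders of magnitude below
$\sigma_w$; fixing the centre makes the objective a pure function of the
configuration and allows $O(\text{moved particle})$ incremental amplitude
updates.

## Spherocylinder chains

The dilute-solution structure of the Bik1 dimer is an elongated, segmented
coiled coil, so droplet fits use capped cylinders: model 1 is a single rod
($R = 12$ Å, $L = 300$ Å, aspect ratio $L/2R = 12.5$), model 2 two linked
segments (155 + 135 Å), model 3 three (155 + 76 + 50 Å). Segments join end
cap-centre to start (`rollCapExtend()`); the inter-segment angle convention
is 180° for the stretched, collinear continuation and 0° for a chain folded
back on itself.

Segment amplitudes use a dense axial line of Gaussian beads (`chainBeads()`):
spacing $\le R/2$, bead width $\sigma_b = R/2$ (matching the transverse
radius of gyration of a uniform disc), and per-slice volume weights obtained
by exact integration, so the weights sum to the spherocylinder volume
$\pi R^2 L + \tfrac{4}{3}\pi R^3$. This gives one uniform code path for
blobs and segments with trivially correct inter-segment phases. Its
accuracy has sharp edges worth stating: the transverse amplitude matches
the exact disc transform within 1% up to $qR \approx 1.3$; along the axis
the beads carry an extra smearing factor $e^{-q^2\sigma_b^2/2}$ (about
−1.6% amplitude at $q = 0.03$ Å$^{-1}$); the orientation-averaged
intensity — the quantity actually fitted — agrees with a semi-analytic
integration oracle within 0.5% across the whole fit window
($qR \le 0.36$) and within 1% to $qR = 1$. No axial bead line can match a
hard cylinder's transverse profile at $qR = 3$ (the Gaussian and the
$2J_1(x)/x$ disc transform diverge by tens of percent there), which is why
the validation stops at $qR = 1$; the fit window never approaches that
regime. At a joint, two hemispherical caps overlap; a collinear two-segment
chain therefore carries one buried cap of extra material and its
normalised intensity deviates from a single summed-length rod by up to
~3% over the fit window.

## Orientation averaging and the objective

Droplet measurements average over many droplets, so the model intensity is
an orientation average,
$$ I(q) = \frac{1}{M}\sum_{m=1}^{M}\Big|\sum_j w_j A_j(q\,\hat n_m)\Big|^2, $$
with $M = 300$ random momentum-transfer directions by default
(`ensembleIntensity()`). One fixed, seed-controlled orientation set is used
for every objective evaluation within a fit: re-sampling directions between
evaluations would inject noise into the greedy accept/reject decision and
destroy determinism. The exact orientational average is available as an
independent oracle through the Debye formula (`debyeIntensity()`,
$O(N^2)$), and the Monte-Carlo average converges to it with the expected
$1/\sqrt{M}$ error.

The objective is
$\chi^2 = \sum_i \left[(c\,I_{\mathrm{mod}}(q_i) - I_{\mathrm{exp}}(q_i))/\sigma_i\right]^2$
with the scale $c$ minimised in closed form at every evaluation
(`chiSquared()`); experimental uncertainties are used when present and unit
weights otherwise. The global scale absorbs the unknown contrast, so no
electron-density model is needed.

# Reverse-Monte-Carlo refinement

`fitBlobs()` initialises blobs uniformly at random in the container
(seeded) and proposes random single-blob translations; `refineCopies()`
proposes whole-chain translations, whole-chain reorientations (single
segments) and single-segment reorientations about the shared joint
(multi-segment chains, links preserved by construction). Acceptance is
strictly greedy — a move is kept only if $\chi^2$ strictly decreases, the
reference point stays inside the container and, with clash checking on, no
new core overlap appears — so the $\chi^2$ trace is non-increasing and
every accepted state is clash-free by construction. An optional Metropolis
temperature exists but defaults to off. Two chains clash when any pair of
core segments approaches closer than $2R$ (`clashCheck()`); consecutive
segments of one chain share a cap and are exempt, while segments 1 and 3
of a folded three-segment chain are checked.

Choices the method description leaves open, fixed here once:

* **Step sizes.** Translation 50 Å, rotation 0.3 rad by default — a
  fraction of the nearest-neighbour spacing at the full-scale copy
  densities; both configurable.
* **Stopping.** A fixed proposal budget, plus an optional stall criterion
  (stop after $K$ consecutive rejections), since no convergence rule is
  stated for the original fits.
* **Copy placement.** `placeCopiesFromBlobs()` samples chain centroids
  from the window-weighted Gaussian mixture defined by the blob fit
  (truncated to the container) — the natural reading of placing copies
  "according to" the blob mass distribution — with uniform random
  orientations. A clash-rejected placement redraws both centroid and
  orientation; at realistic local densities (volume fraction 0.05–0.1)
  redrawing only the orientation can jam.
* **Stage seeding.** Model 2 superimposes its 155 Å segment on one end of
  each refined model-1 rod (collinear, shared endpoint) and appends the
  second segment clash-free at a random orientation; model 3 is seeded
  from model 2 analogously. A strongly folded-back model-2 chain can leave
  no orientation of the third segment clear of segment 1 (consecutive
  segments being exempt, a model-2 chain may legally fold almost flat); in
  that case the appended segment is placed inter-chain clash-free only,
  and every subsequent move still enforces the within-chain rule without
  letting the pre-existing contact veto unrelated moves.
* **Degenerate input.** Fit windows containing fewer than 5 profile
  points are rejected.

The volume fraction is not constrained; it emerges from the copy count and
container volume.

# Structure metrics

* **Radial distribution function.** `radialDistribution()` normalises
  observed pair counts per shell by the expectation for the same number of
  points uniform in the same bounded sphere, estimated by Monte Carlo (10
  seeded replicates averaged). This finite-volume normalisation avoids
  analytic shell-intersection formulas while controlling edge effects. For
  chains the "centre" is the volume-weighted centroid of the segments. A
  uniform process gives $g(r) = 1$; the fractal network shows a
  nearest-neighbour peak followed by a power-law-like decay
  ($\sim r^{d-3}$) that never plateaus at 1 inside the probed range.
* **Nematic order.** `nematicOrder()` grids the container into 400 Å
  boxes (origin-centred; boxes truncated by the container are kept if
  populated enough) and computes
  $S = \tfrac{3}{2} e_{\max}\!\left(\langle u \otimes u\rangle - I/3\right)$
  per box over the particle axes, reporting only boxes with at least 30
  particles because the estimator's finite-count bias scales as
  $1/\sqrt{n}$ (for $n = 30$ isotropic axes $S$ is typically 0.1–0.25
  without any true order). $S$ is invariant under global rotations and
  per-particle sign flips. For multi-segment chains the default operates
  on per-segment axes; single-rod (model 1) ensembles are the primary use,
  matching how the orientational analysis is defined.
* **Fractal dimension.** `fractalDimension()` regresses $\log I$ on
  $\log q$ over a window (default 0.002–0.02 Å$^{-1}$) and returns
  $d = -\text{slope}$ with its standard error; it is exact on pure power
  laws. When the constituent particle's form amplitude is known — always
  true for simulated structures — passing it as `formFactor` fits the
  structure factor $S(q) = I(q)/f(q)^2$ instead, the standard
  $I = P \cdot S$ decomposition. This matters quantitatively: a 40 Å blob
  contributes $e^{-q^2\sigma^2}$, steepening the apparent slope by about
  0.2 over the default window, which would masquerade as a higher fractal
  dimension.
* **Guinier radius.** `guinierRg()` performs the iterative low-$q$ fit of
  $\ln I$ versus $q^2$ with the usual $qR_g \le 1.3$ admission rule. That
  rule presumes near-globular particles; for a 300 Å rod the expansion
  breaks down earlier and a stricter cutoff (`qRgLimit = 0.8`) is needed
  to land within a few percent of the true $R_g$ — the package's tests use
  exactly that and the documentation says why.

# Synthetic data: what it emulates and what it does not

`generateRandomWalkStructure()` builds a 3-D fixed-step random walk of
blob centres. An ideal chain has mass-fractal dimension exactly 2, making
it the simplest stand-in matched to the measured $d \approx 2$;
aggregation-style generators for other target dimensions were deliberately
left out. Two quantitative caveats are documented rather than hidden: the
discrete walk's structure factor over the default window has a
window-averaged exponent of 2.08 (exact freely-jointed-chain sum at
$n = 2000$, step 200 Å), not 2.00, because the upper window edge
approaches the step-length crossover; and a single configuration carries
speckle noise, so seed-averaged estimates recover $d$ to within about
±0.1. With `confineRadius` set, steps leaving a sphere are redrawn, so a
walk can be packed into a prescribed container while staying fractal below
the confinement scale.

`generateDropletProfile()` computes the windowed, orientation-averaged
intensity of a structure and applies multiplicative Gaussian noise (default
2% — the reduced droplet curves publish no counting statistics, so a small
relative error is assumed) with uncertainties set to the noise level.
`generateDiluteProfile()` produces the exact orientation-averaged
single-chain curve via the Debye formula — the stand-in for a
dilute-solution form-factor measurement. `generateXlTables()` emits
identification and transition tables with programmed per-condition link
populations, score distributions and fold changes, returning the ground
truth for tests. All generators are pure functions of their arguments and a
mandatory seed.

What the synthetic data do **not** emulate: inter-droplet scattering,
droplet-size polydispersity, beam geometry, detector effects, buffer
mismatch, or any spectral-level realism in the XL-MS tables (retention
times, decoys, isotope envelopes). Passing tests therefore demonstrate the
correctness and internal consistency of the computations, not instrument
realism.

# The XL-MS post-identification pipeline

Inputs are identification tables from a crosslink search engine and
targeted transition-area tables; everything upstream (spectral search, FDR
estimation, peak picking) is out of scope. The computations, with every
printed threshold implemented as a strict inequality exactly as printed:

* `classifyLink()`: crosslink (two different residues), monolink (single
  modified residue), selflink (two positionally identical residues —
  necessarily inter-molecular, hence a reporter of oligomerisation),
  zerolink (direct bond, hydrazide chemistry, carried through but never
  quantified).
* `filterQualitativeDSS()`: ld.Score > 20 in every contributing
  observation **and** identification in ≥ 2 of 3 replicates within a
  condition. The stricter reading — the score cut applies per replicate —
  is implemented; the filter is idempotent.
* `filterQualitativePDH()`: ld.Score > 25 ∧ deltaS > 0.9 ∧ FDR < 0.05, no
  replicate rule (those experiments were single runs); records missing
  deltaS or FDR are rejected with a warning.
* `assignDomains()` / `domainPairCounts()`: positions map to the
  computed top-level regions (CAP-Gly 1–80, L1 81–188, coiled coil
  189–389, C-terminal 390–440; boundary residue 80 is CAP-Gly, 81 is L1)
  and spectral counts aggregate over order-normalised region pairs.
* `normalizeQuant()`: peptide abundance = sum of ten transition areas
  (five heavy + five light) divided by the householder (non-crosslinked
  reference) peptide area per replicate; fewer than five transitions per
  form or a missing householder is an error naming the replicate.
* `differentialAnalysis()`: $\log_2$ fold change of condition means and a
  two-sided unpaired Student's t-test (pooled variance by default, Welch
  optional), enrichment flagged at $\log_2\mathrm{FC} > 1$ strictly. No
  multiple-testing correction is applied by default, matching how the
  volcano analyses report raw significance; degenerate constant groups
  return p = 1 (equal means) or 0 rather than erroring. A peptide absent
  in a replicate is excluded from that condition's mean, not imputed.
* `conformoSpecific()`: peptides present in exactly one condition's
  filtered set, the candidates for targeted quantification.
* Peptide uniqueness everywhere is the order-normalised position pair plus
  link type plus reagent, at position (not sequence) resolution.

# Worked example

A small end-to-end run (a few seconds; the numbers shown are what the code
prints):

```{r example, eval = FALSE}
library(condensaxs)

## a fractal arrangement of blob centres and its noisy scattering curve
walk <- generateRandomWalkStructure(800, 200, seed = 19, sigmaBlob = 40)
qGrid <- exp(seq(log(0.002), log(0.02), length.out = 25))
profile <- generateDropletProfile(walk, qGrid, noiseFraction = 0.02,
                                  seed = 19)

## mass-fractal dimension of the structure factor
fractalDimension(profile, c(0.002, 0.02),
                 formFactor = function(q) blobFormAmplitude(q, 40))
#> Fractal dimension d = 2.082 +/- 0.024 (q in [0.002, 0.02] A^-1)

## fit rod copies to the curve
cfg <- fitConfig("model1", nCopies = 800, containerDiameter = 6000,
                 windowSigma = 1500, qMin = 0.0042, qMax = 0.02,
                 nOrientations = 150, maxMoves = 2000, seed = 19)
init <- placeCopiesFromBlobs(walk, modelGeometry("model1"), cfg)
fit <- refineCopies(profile, init, cfg)
fit
#> FitResult: chi2 772.1 -> 339.4 over 2000 proposals (633 accepted),
#>   scale = 9.582e-11, seed = 19
```

# Problem sizes and numerical choices

The package's own test and acceptance runs use deliberately reduced
problem sizes chosen to exercise every code path at full fidelity: blob
fits with 60–200 blobs, rod refinements with 300–5000 copies, orientation
sets of 50–300 directions, and random walks of up to 2000 vertices. The
5000-copy model-1 fit in a 6000 Å container with $\sigma_w = 1500$ Å
mirrors the full-scale setup at one-tenth the copy count; its synthetic
target is a 300-vertex walk of 300 Å steps with 150 Å blobs confined to a
2500 Å radius, which gives a local rod volume fraction near 0.07 —
comparable to the 0.05–0.1 the full-scale fits produce — so that 400 Å
boxes reach the 30-particle cutoff and clash-free placement is feasible.
Incremental amplitude updates are exact (the phase sum over a moved copy's
beads is subtracted and re-added; an arithmetic $q$ grid additionally
enables a per-point phase recurrence), greedy acceptance uses strict
inequality with no tolerance, and all randomness flows from explicit seeds
with the global RNG state restored afterwards.

# Known limitations

* The original fitting code's amplitude formulation is not described;
  the bead decomposition here reproduces its stated inputs and outputs,
  validated against integration oracles, but is not guaranteed to be the
  identical formula.
* Whether the original 300 orientations were re-drawn between objective
  evaluations is not stated; this implementation fixes them per fit for
  determinism.
* $g(r)$ bin width and the treatment of container-edge boxes in the
  orientational analysis are not stated; defaults here are 50 Å bins and
  edge boxes retained when sufficiently populated.
* The XL-MS stage starts from identification tables; reproducing the
  published crosslink counts would require the deposited raw data and a
  spectral search engine, both out of scope.
* Real droplet data (beamline measurements) are not bundled; all shipped
  checks run on synthetic inputs whose ground truth is known by
  construction.
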
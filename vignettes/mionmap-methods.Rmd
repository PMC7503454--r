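---
title: "Models and methods behind mionmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mionmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mionmap)
```

`mionmap` is a simulation and analysis toolkit for blocked passive-viewing
fMRI experiments run with the intravascular contrast agent MION, of the kind
used to map where the primate brain encodes an object's learned value
(good-vs-bad, "GB") and its perceptual novelty (novel-vs-familiar, "NF").
Every analysis stage is paired with a seeded generator so the whole chain is
testable on a desk without any scanner data. This vignette explains the
models, the defaults, and the choices made where the design was genuinely
open.

## The experimental design being emulated

A run lasts 480 s: 16 blocks of 30 s, acquired at TR = 2.5 s, so 192
volumes, with base (fixation-only) and probe (object-presentation) blocks
strictly alternating. The four probe types are the two object categories of
the scan dimension crossed with the stimulated hemifield, and the eight
probe blocks form two cycles, each a seeded permutation of the four types —
so every cycle of four sequential probe blocks shows all four types.
`make_design()` produces this structure; its invariants (192 volumes,
alternation, per-cycle balance, two blocks per probe type) are enforced by
tests. The first three volumes are treated as a magnetization transient and
excluded from all regressions, leaving 189 usable rows. Blocks can be
flagged excluded (emulating broken fixation) at a configurable rate,
default 0; excluded blocks are censored by row removal at regression time,
not at acquisition time.

## MION hemodynamics

MION tracks cerebral blood volume, and an increase in blood volume darkens
the T2*-weighted signal, so the impulse response is negative-going. Its
exact shape is not standardized; `mion_irf()` uses a sign-inverted
gamma-variate with configurable peak delay (default 10 s, a typical value
for contrast-agent responses, slower than BOLD), an optional positive
rebound lobe (default off), and the normalization that a sustained unit
boxcar asymptotes to exactly −1. The shape is a package choice exposed as
parameters rather than a fixed constant; everything downstream only assumes
causality, the sign convention, and the boxcar normalization.

## The synthetic-data generator

`ground_truth()` fixes the study conditions: a voxel grid (default
24×24×16) partitioned into contiguous box-shaped regions (default 24
regions in 4 networks of 6), per-network percent-signal effects, a sparse
symmetric positive-definite precision matrix over regions for resting
covariance, the spatial noise autocorrelation, and the temporal
signal-to-noise target (tSNR 25, matching awake contrast-agent imaging).
Planted effects are of order 0.1 % of the mean signal — the effect size the
power calculation below is built around. Condition effects decompose as
`visual ± contrast/2`, so the good-minus-bad (or novel-minus-familiar)
difference equals the planted contrast exactly, and an optional
contralateral bias multiplies the effect by `1 ± bias` by hemisphere.

`simulate_task_run()` builds each voxel as
`baseline × (1 + percent_signal/100)` plus spatially autocorrelated
Gaussian noise with `sd = baseline / tsnr`, temporally white. The planted
percent signal is centered about its run mean, so the voxel temporal mean
equals the baseline and "percent change from the mean" recovers planted
betas exactly — with noise off, the GLM reproduces them to machine
precision, which the tests assert at 1e−8. Seventeen nuisance traces
(six motion parameters and their derivatives, reward delivery, blinks, eye
position horizontal/vertical and their product) are emitted with known
loadings, zero by default.

`simulate_rest()` draws i.i.d. Gaussian vectors with covariance equal to
the inverse of the planted precision matrix — exactly the faithful
Gaussian world in which partial-correlation tests characterize conditional
independence — optionally with two shared confound traces (white-matter and
ventricle analogues).

What the generator deliberately does not emulate: motion, distortion or
spike artifacts, slice timing, temporal autocorrelation of physiological
noise, non-Gaussian noise, or eye-movement physics. Passing tests therefore
demonstrate correctness of the estimators under their stated assumptions,
not robustness to every property of real scanner data.

## GLM in percent-signal units

`to_percent_change()` maps each voxel series to `100·(y/mean(y) − 1)`,
masking nonpositive-mean voxels. The design matrix holds, per scan type,
four MION-convolved condition boxcars (category × hemifield), the 17
nuisance regressors — all convolved except the 12 motion columns — and five
Legendre drift terms (orders 0–4), which realize fourth-order detrending
inside the regression; for ordinary least squares this is equivalent to a
separate detrending pass. Estimation is voxelwise OLS without prewhitening
(the simulated noise is temporally white; an AR option was considered and
left out as dead weight). Contrasts are `GB = mean(good L,R) − mean(bad
L,R)` and the NF analogue; the probe-vs-base "visual" beta comes from a
separate single-regressor fit, which makes it orthogonal to category and
hemifield labels by construction and therefore a selection variable that
does not bias value or novelty comparisons. Rank-deficient designs abort
with the collinear columns named.

## Cluster-extent correction

Familywise error over a search volume is controlled by the classical
Monte-Carlo recipe: simulate null fields with the target spatial
autocorrelation, threshold voxelwise (two-sided p < 0.001 by default),
record the maximum suprathreshold cluster size under the chosen
neighborhood (faces-only, NN = 1, by default), and take the size whose
exceedance probability is the familywise α (0.01). The spatial model is
the mixed Gaussian/mono-exponential ACF
`a·exp(−r²/2b²) + (1−a)·exp(−r/c)`; fields are synthesized by filtering
white noise with the square-root power spectrum of the ACF evaluated on
the torus of the grid, and the same synthesizer drives the task-noise
generator, so one spatial noise model serves both modules. The reported
threshold is fractional — linear interpolation of the empirical survival
curve at α — and `ceiling()` is applied at correction time, which coincides
with the conservative order-statistic rule. Because the original whole-brain
mask geometry behind any particular printed threshold is unknowable from
the outside, the package's claim is calibration: on fresh null fields the
surviving-cluster rate stays at or below α, which the acceptance tests
check for both published smoothness parameter sets at a 24³ volume with
10 000 iterations.

## Functional-connectivity graphs

Resting segments are confound-regressed (white-matter and ventricle means),
bandpassed to 0.01–0.1 Hz by FFT bin zeroing (bins strictly outside the
band and the DC bin set to zero), and re-centered. Region series are means
over the voxels surviving significance masking, with regions below
`min_voxels` (default 4, inside the 3–5 range where sparse regions stop
being trustworthy) dropped.

The skeleton is estimated with PC-stable: starting from the complete graph,
at each depth the neighbor sets are frozen, and an edge is removed as soon
as one Fisher-z partial-correlation test — `z = √(n−|S|−3)·atanh(ρ̂)`
against a standard normal, two-sided — is nonsignificant at `ci_alpha`,
with conditioning sets drawn from the frozen neighborhoods of either
endpoint. Freezing is what makes the result independent of node ordering,
and the tests verify both the order invariance and exact agreement with a
brute-force all-subsets oracle on a suite of 50 strong 5-node Gaussian
graphical models. A surviving edge is weighted by the signed partial
correlation of smallest magnitude seen across its tests — its "net"
correlation. Since an edge is removed at its first nonsignificant test,
every test a surviving edge saw was significant, so the two readings of
"smallest" (all tests vs significant tests only) coincide for survivors;
both are implemented behind a flag. The conditioning-set size is unbounded,
and no effective-sample-size correction is applied for the concatenation of
bandpassed segments — a known simplification, listed under limitations.

Clustering operates on the largest connected component (ties broken toward
the smallest node index): symmetric normalized Laplacian on absolute edge
weights (absolute values guarantee nonnegative affinities if a negative
partial correlation survives), embedding on the k eigenvectors of smallest
eigenvalue, row normalization, then k-means with k-means++ seeding and 50
restarts, best inertia kept. k is fixed at 4 by configuration; no model
selection over k is attempted. Subcortical-style seed maps correlate each
cluster centroid (mean of member series) with target voxels, threshold the
t-transform of r at p < 0.001, and reuse the cluster-extent machinery
within the caller's small-volume mask.

## Joint value/novelty classification

For region scatter plots, each region contributes the mean GB and NF beta
of its `n_top` (default 10) most visually active voxels — ranking only the
probe-vs-base beta, so the selection is orthogonal to what is being
compared. The joint null is a bivariate Gaussian fitted to the (GB, NF)
betas of all gray-matter voxels regardless of significance; a voxel lies
outside the q-level iso-probability contour iff its squared Mahalanobis
distance exceeds the χ²(2 d.o.f.) quantile at q (default levels 0.68 and
0.95). Gaussian contours are the primary model because the procedure is an
ellipse-based confidence construction; the calibration tests confirm that
for Gaussian betas the outside-95 % fraction is 5 % within binomial error.

The NF/GB time-course correlation needs a pairing rule between scans whose
probe orders were independently randomized: probe blocks are reordered
within each cycle to a fixed canonical sequence (positive category first,
left before right; good pairs with novel, bad with familiar), runs are
averaged within scan type, and the two averages are Pearson-correlated per
voxel. Base blocks stay in place. Because the hemodynamic response
carries over block boundaries, canonicalized alignment is exact only when
the two scans shared a block order; with independent orders the residual
misalignment is small (the tests bound it) but nonzero — the reason this
contract, and no stronger one, is claimed.

## The bilinear dynamic causal model

The neural model is `ż = (A + Σⱼ uⱼ Bⱼ) z + C u` with k = 4 nodes
(temporal and prefrontal, each hemisphere) and m = 8 condition inputs
(category × hemifield). `A` is identical across all nine candidate models
and across both scan dimensions: negative self-decay on the diagonal,
parameterized `−exp(θ)` so stability-favoring negativity is structural,
plus reciprocal temporal↔prefrontal connections within each hemisphere.
Good and Novel inputs modulate the forward and backward connections of the
hemisphere contralateral to the stimulated hemifield — the hemisphere
receiving the visual drive. The hemisphere scope of this modulation is a
genuine design choice; tying it to the contralateral side is the reading
consistent with contralateral visual processing, and it keeps the
modulation parameters identifiable from lateralized presentations. The 3×3 grid crosses the input scheme (contralateral drive to
the temporal node, the prefrontal node, or both) with the self-modulation
scheme (none; Good/Novel on all four self-connections; all eight inputs on
all four self-connections).

Each node's activity passes through a balloon-type hemodynamic model
(vasodilatory signal, flow, volume, deoxyhemoglobin; κ = 0.64 s⁻¹,
γ = 0.32 s⁻¹, τ = 2 s, α = 0.32, E₀ = 0.34, all held at these canonical
values) and is read out as `y = −ε(v − 1)`: MION weights blood volume, and
volume increases darken the signal. The deoxyhemoglobin state does not feed
this readout, so the fitting path skips its integration. Integration is
fixed-step classical Runge–Kutta at TR/16 (0.156 s), implemented in C++;
the tests verify fourth-order convergence and < 1e−6 step-halving changes
in the asymptotic regime. Inputs are zero-order-held over each TR, which is
exact here because the design is blocked at TR resolution.

Inversion is MAP plus a Laplace evidence — deliberately simpler than a full
variational scheme, with the same model-comparison semantics. The objective
is the Gaussian log-likelihood with the observation variance profiled as
RSS/N, plus zero-mean Gaussian shrinkage priors: sd 0.5 on all connectivity
parameters and on the log self-decay rates, and sd 0.1 on log ε. The tight
gain prior resolves the joint scaling of ε and `C` (the same degeneracy
that motivates tight hemodynamic priors in standard DCM practice).
Optimization is Levenberg–Marquardt on the prior-augmented residual vector
(`minpack.lm`), with the σ-profiling loop iterated to convergence and
multi-start jitter around the prior mean (default 8 starts; the smooth
small models used in the recovery studies converge from the prior mean, so
those studies use 1–2 starts). The evidence is
`log joint at MAP + (d/2)·log 2π − ½·log det H` with `H` the Gauss–Newton
curvature `JᵀJ` of the standardized residuals — the expected-curvature
approximation, exact for linear models and standard for penalized least
squares. Fixed-effects selection softmaxes log evidences; exact ties go to
the model with fewest free parameters; non-converged fits are excluded with
a warning.

Reference truths for simulation studies (`dcm_reference_theta()`) draw
excitatory forward connections (0.25–0.5), negative-feedback backward
connections (−0.4 to −0.15), signed inter-regional modulations
(|0.1–0.35|), positive contralateral drive (0.2–0.5), and unit gain,
rejecting draws whose single-condition systems are not comfortably stable.

## Scan-count power formula

`required_runs()` evaluates
`N_run = (8/TRnum) · (erfc⁻¹(p) / (tSNR · eff · f))²` with f = 5, the
sensitivity gain conventionally attributed to MION over BOLD. At p = 1e−3,
tSNR = 25, eff = 0.1 %, and the full 192-volume run, this gives 14.4 runs;
with the 189 usable volumes it gives 14.7. Both volume conventions are
meaningful — the formula's TRnum counts data points per run — so the
calculator takes `tr_per_run` explicitly instead of silently resolving the
ambiguity.

## Problem sizes used by the test suite

The acceptance-style tests run at desk scale, chosen once: GLM coverage
uses a 6×6×4 grid, 19 runs per replicate and 100 replicates, checking the
pooled network-averaged contrast (fitted per run, precision-pooled) against
±2 analytic standard errors — the nominal coverage of an honest 2·SE
interval is 95.4 %, so this check sits close to its own boundary by
construction. The PC-stable oracle suite uses 50 five-node models at
n = 2000, the network-recovery study 24 regions at n = 4000 over 20 seeds,
cluster calibration 10 000 Monte-Carlo iterations and 500 fresh nulls at
24³ for both published smoothness sets, and the DCM studies 20 replicates
each — 16 pooled runs per replicate for parameter recovery (the emulated
study pooled ~19–23 runs per dimension) and 2 runs per replicate for
9-model selection, both at SNR 5.

## Known limitations

- OLS assumes temporally white noise; real fMRI noise is autocorrelated.
- The ACF noise synthesizer is exact on the torus; near grid edges the
  effective correlation wraps around.
- No effective-sample-size correction after bandpassing and concatenating
  rest segments; the CI tests treat concatenated samples as independent.
- The Laplace/Gauss–Newton evidence ignores posterior skew; with strong
  nonlinearity or poor identifiability the evidence gaps it reports are
  approximate.
- Canonicalized NF/GB time-course alignment is exact only for shared block
  orders (see above).
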
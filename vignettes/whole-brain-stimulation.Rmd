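---
title: "Methods: stimulation-responsive networks in a synthetic whole-brain model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulation-responsive networks in a synthetic whole-brain model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stimnet` implements a whole-brain network model of stimulus-evoked energy
dissipation and the statistical pipeline that turns simulated responses into
*dynamically responsive networks* and matches them to resting-state-network
(RSN) masks. This vignette is the package's account of the science: the
model and its assumptions, the parameters that matter, what the synthetic
brain emulates, and the numerical and design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The node model and near-criticality

Each network node is a planar flow

$$\dot\psi_1 = \eta(\psi_2 - \gamma\psi_1 - \psi_1^3) + \text{drive},
\qquad \dot\psi_2 = -\eta\varepsilon\psi_1,$$

a damped nonlinear oscillator whose origin is a stable focus below a
supercritical Andronov–Hopf bifurcation. Linearized at the origin the
eigenvalues are $\eta(-\gamma/2 \pm \sqrt{\gamma^2/4-\varepsilon})$; at the
defaults ($\gamma = 1.21$, $\varepsilon = 12.3083$, $\eta = 76.74\,s^{-1}$)
this gives a decay rate $\eta\gamma/2 = 46.4\,s^{-1}$ and a gamma-band
natural frequency of $42.2$ Hz (`node_eigenfrequency()`). Coupling and
stimulus act on $\psi_1$ only, scaled by $\eta$ (coupling vectors
$(\eta, 0)$).

The criticality argument is quantitative: an instantaneous self-input of
weight $w$ shifts the effective damping to $\gamma - w$, so instability
requires $w > \gamma = 1.21$ (`critical_coupling()`). Both connectivities
are normalized so that no node's total incoming weight exceeds 1; the
network therefore cannot amplify activity, is silent at rest, and every
response is a transient damped oscillation. The slowest-decaying network
modes — sustained by re-entrant loops in the connectivity — dominate the
late response, which is why a handful of principal components capture
almost all of the dissipated energy (the center-manifold intuition).

Stimulation is a constant drive applied simultaneously to all nodes of one
area for one characteristic time $1/\eta \approx 13$ ms. The amplitude is
not free: `calibrate_stimulus_amplitude()` bisects it so the *isolated*
node's peak $|\psi_1|$ is 1 within $10^{-3}$. The alternative impulse
parameterization ($-5\eta\,\delta(t)$) is not used because its
normalization under time discretization is ambiguous; the calibrated
constant drive reproduces the defining property (unit peak) exactly.

## 2. The structural substrate

The synthetic brain states a world once and keeps it:

- **Geometry.** Each hemisphere is a closed 2-sphere of radius 50 mm
  (centres at $x = \pm 52.5$ mm), quasi-uniformly covered by a Fibonacci
  lattice with a seeded random rotation and triangulated by planar Delaunay
  after stereographic projection from a data-free pole (the residual polar
  hole is fan-filled; the result is a closed mesh, $F = 2V - 4$).
  Subcortical areas are single points drawn uniformly from a midline ball
  of radius 15 mm. The 50 mm radius gives a hemispheric surface of the
  right order of magnitude; with 500 nodes per hemisphere the mean node
  spacing is ~8 mm, so the full-scale kernel range $\sigma = 10$ mm is
  just resolvable — deliberately mirroring the full-scale situation where
  10 mm sits at the sampling limit of the cortical mesh.
- **Parcellation.** Contiguous patches grown by multi-source BFS over the
  mesh adjacency; one patch per hemisphere is seeded at the medial pole and
  flagged *callosal*: its nodes are excluded from all connectivity,
  emulating the corpus-callosum intersection where the short-range kernel
  is forced to zero.
- **Homogeneous SC.** $w_{ij} \propto e^{-d_{ij}^2/2\sigma^2}$ on
  great-circle distances (the kernel is translation-invariant on the
  sphere; chord distances would distort large $\sigma$), truncated at
  $4\sigma$ (>99.99 % of kernel mass) and renormalized to unit incoming sum
  per node, self-weight included. No interhemispheric entries; geodesic
  graph distances are used instead when a mesh is loaded from files.
- **Heterogeneous SC.** A directed Erdős–Rényi graph over the functional
  areas at density 0.3 (tracer-based connectomes are dense at the area
  level; a third of all pairs is a realistic middle ground) with
  heavy-tailed log-normal weights ($\ln w \sim N(0,1)$), tract lengths
  equal to centroid distances, delays $\tau = \ell/v$ at $v = 6$ m/s, and
  normalization to unity maximum in-strength, i.e.
  $\max_i \sum_j c_{ij} = 1$. With a single delay per connection the
  supremum-over-delays form of this normalization collapses to exactly
  this row-sum condition.
- **RSN masks.** Eight networks with the canonical names, each marking a
  random subset of cortical areas at levels none/medium/high coded
  0/1/2 and normalized to unit sum. The numeric coding of the ordinal
  levels is a declared convention, not empirical ground truth.

What the generator does **not** emulate: cortical folding (and thus any
systematic relation between geodesic and Euclidean distance), realistic
area size distributions, the topology of an empirical tracer connectome
(community structure, hubs), or empirically placed RSN cartography. A green
test therefore establishes that the machinery is correct on a brain with
the *stated statistical structure*, not that empirical findings at full
scale are reproduced; full-scale counts (e.g. repertoire sizes at specific
$\alpha$/$\sigma$) require the real connectome and a cluster-scale sweep and
are out of scope. Real connectomes in the weights/tract-lengths/centres
dialect load via `read_connectome()`.

## 3. Network integration

`simulate_network()` integrates, per node $i$ with area $a(i)$,

$$\text{drive}_i = (1-\alpha)\sum_j w^{hom}_{ij}\psi_1^j(t)
 + \alpha \sum_b c_{a(i)b}\,\langle\psi_1\rangle_{b}(t - \tau_{a(i)b})
 + I_i(t),$$

with Heun's method at $dt = 40\,\mu s$. Numerical choices:

- Delays are rounded to the nearest integer step (error $\le 20\,\mu s$, no
  interpolation). History before $t = 0$ is zero (silent network).
- The heterogeneous term transmits *area means*, so refining a mesh leaves
  the transmitted drive unchanged (asserted by a paired-simulation test).
- The stimulus is piecewise constant with edges on the step grid and is
  held at its interval value in *both* Heun stages; evaluating the second
  stage at the post-switch value would cost an order of convergence
  (verified by the step-halving test: error ratio 4 when $dt$ halves).
- Delayed terms for the corrector stage come from the history ring at
  $t{+}1{-}\tau$; zero-delay edges (only possible for co-located centroids)
  use the predictor means.
- Recording keeps every 25th step (1 ms) to bound memory; the decomposition
  operates on recorded samples, ~24 per oscillation cycle.
- The integrator is deterministic; identical inputs give bit-identical
  outputs, and a scalar-loop R reference reproduces it to $10^{-10}$.

## 4. Transient estimation

Delays alone decide how long stimulus-triggered activation keeps reaching
new areas. The cellular automaton makes this a shortest-path computation:
a cell active at $t$ activates each out-neighbour at $t + \tau$, activation
is permanent, so activation times are delay-weighted shortest paths from
the seed. `estimate_transient()` takes the maximum settling time over all
seeds; areas unreachable from a seed are reported but excluded (an
unreachable cell would otherwise make the estimate infinite — on strongly
connected empirical connectomes the case does not arise). Any positive
weight activates; the automaton has no weight threshold. The decomposition
window opens at this estimate rounded up to the next millisecond, with a
0.5 s default length (the full-scale convention of 0.5 s of data after
0.5 s of stimulus onset becomes the config default when a real connectome
is loaded).

## 5. Decomposition and the responsive-network repertoire

`decompose_response()` mean-centers each node's trace over the window and
takes the SVD of the centered data (the dual formulation handles
nodes ≫ samples); squared singular values over their sum are the variance
fractions, and the smallest $k \le 3$ components whose cumulative fraction
first exceeds 0.99 are retained (all three, with a warning, if the
threshold is never reached). Centering is assumed — standard PCA — since
the alternative is not stated anywhere. Signs are canonicalized
(largest-magnitude element positive) so downstream comparisons are
deterministic. The envelope (FFT analytic-signal amplitude) is provided for
visualization only; the covariance is computed on $\psi_1$ itself, which is
the variable that carries coupling and input.

Eigenspaces from different stimulation sites are compared by the mean
cosine of principal angles (mean singular value of $V_a^\top V_b$): the
"dot product of normalized eigenvectors" is ill-defined for 3-dimensional
subspaces under within-space rotation, and the principal-angle form is the
rotation-invariant completion that reduces to $|u^\top v|$ for 1-D spaces.
Clustering runs k-means (20 restarts, fixed seed) on the rows of the
similarity matrix — the similarity measure itself is the only embedding the
method prescribes — with the cluster count chosen by the gap statistic
(uniform reference over the feature bounding box, default 50 draws, first
$k$ with $\text{gap}(k) \ge \text{gap}(k{+}1) - s_{k+1}$, ties toward
smaller $k$). Within a cluster, members are rotated onto the member with
the highest mean similarity by orthogonal Procrustes, averaged, and
re-orthonormalized by the polar factor. `repertoire_counts()` reports the
chosen $k$ and the number of *effective* sites — sites whose eigenspace has
similarity $\ge 0.8$ to its cluster mean. The effective-site criterion is
not operationally defined in the source description; this threshold rule is
the implemented proxy and the threshold is an argument.

## 6. RSN matching and statistics

Node eigenvectors are coarse-grained to areas (squared — or absolute —
elements summed per area, callosal areas dropped) and normalized to unit
sum: the Bhattacharyya coefficient is defined on distributions, so the
probability-simplex normalization is the default (the alternative
unit-length reading is available as `candidate` input you normalize
yourself). The candidates per eigenspace are the $k$ single coarse-grained
vectors plus renormalized sums of every multi-vector combination (7 for
$k = 3$). Each candidate meets each mask with
$BC = \sum_i\sqrt{p_iq_i}$; significance comes from permuting the mask's
entries $N$ times ($p = (n+1)/(N+1)$, counting *strictly* greater permuted
coefficients, as worded), Holm-corrected over the whole family (default:
#masks × #candidates; the fixed historical family of 24 is available via
`m_comparisons = 24`), significant at 0.05. Default $N$ is 10,000 for
interactive use ($2\times10^6$ is the full-scale setting). Under the null
the p values are uniform to within the $1/(N{+}1)$ lattice — the
calibration test asserts Kolmogorov distance < 0.1 over 500 replicates.

`select_optimal_parameters()` averages, per (metric, $\alpha$, $\sigma$),
the per-RSN maximum significant $BC$ over the eight networks (missing
networks contribute 0) and returns the argmax, separately for cortical,
subcortical and combined stimulation sites. `graph_metrics()` supplies the
seven per-area structural measures (in/out/total degree and strength,
Fagiolo's weighted directed clustering coefficient) that are compared to
responsive networks with the same permutation machinery, and
`cortical_subcortical_tests()` runs the two-sample KS and Wilcoxon
rank-sum tests at the 0.01 level. In `build_stimulation_map()` ties
between candidates at equal $BC$ keep the lexicographically lowest
candidate id — a documented, deterministic choice.

## 7. Verification strategy and limitations

Every operation is tested against an independent oracle where one exists:
a scalar-loop integrator, igraph shortest paths for the automaton,
brute-force eigen-decomposition for the PCA, constructed rotations for
Procrustes, exact binomial bounds for the generator, closed forms for BC
and Holm. The acceptance suite additionally verifies the two headline
quantities end to end: the 42 Hz eigenfrequency, and — on the seeded
"small" brain (2×500 nodes, 28 functional areas), five sites at
$\alpha = 0.6$, $\sigma = 10$ mm — that the top three principal components
cover > 99 % of post-transient variance at every site. A planted-structure
test closes the loop: a strong directed cycle through the areas of one RSN
mask, inserted into an otherwise weak random heterogeneous SC, is recovered
as the top significant Bhattacharyya match among the eight masks.

Known limitations: no noise-driven resting fluctuations (the model is
silent without stimulation, by construction); no delayed homogeneous
coupling; binary cellular automaton only; no hierarchical or density-based
clustering alternatives; the gap statistic on a handful of eigenspaces is
coarse (with $k$ equal to the number of items, singleton clusters are
returned since Hartigan–Wong k-means requires $k < n$); full-scale
repertoire counts and empirical-mask matching require external data and
compute beyond a desk machine.
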
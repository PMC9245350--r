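---
title: "Well-tempered metadynamics for nucleic-acid mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Well-tempered metadynamics for nucleic-acid mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Coarse-grained models of DNA nanostructures — duplexes, four-way junctions,
origami joints — have free-energy landscapes with metastable minima separated
by barriers of many $k_BT$. Unbiased molecular dynamics started in one
conformer essentially never visits the others on affordable time scales, so
the deformation free energy $\Delta G(\vec s)$ projected on a collective
variable (CV) cannot be read off occupancy histograms. Metadynamics solves
this by building a history-dependent repulsive bias $B_t(\vec s)$ out of
Gaussians deposited at visited CV values, which progressively floods the
wells until the system diffuses freely. `metadyn` implements the
well-tempered, multi-walker flavour of this machinery with a gridded bias,
together with the CV families, free-energy estimators and worm-like-chain
(WLC) spring reweighting needed to predict the force response of compliant
nucleic-acid structures.

The package deliberately does not re-implement any nucleotide-level force
field. Its samplers run on analytic benchmark landscapes and on a kinkable
bead-spring chain; oxDNA-format topology and configuration files are read
only to define bead groups and evaluate CVs on externally produced
coordinates.

## The bias model

All energies are stored in units of $k_BT$ (so $\beta = 1$ internally;
conversions belong at I/O boundaries). The bias is tabulated on a 1D or 2D
grid (`grid_spec()`), with per-dimension spacing required to be at most
$\sigma/5$, one fifth of the deposited Gaussian width — enforced at
construction, because a grid coarser than the Gaussians it stores aliases
the very features being built. Between nodes the bias is evaluated by linear
(1D) or bilinear (2D) interpolation, exact at nodes.

Every MetaD iteration ($\tau$ sampler steps per walker) ends with one
Gaussian per walker:

$$B_{t+1}(\vec s) = B_t(\vec s) + w_t
  \exp\!\Big(-\sum_d \frac{(s_d - s_{t,d})^2}{2\sigma_d^2}\Big),
\qquad
w_t = A \exp\!\big(-B_t(\vec s_t)/\Delta T\big),$$

with $A$ the initial height increment and $\Delta T$ the tempering
temperature (in units of $T$, which equals $k_BT$ units here). The decaying
amplitude is what makes the scheme convergent rather than oscillatory: at
long times

$$B_t(\vec s) \to -\frac{\Delta T}{T + \Delta T}\,\Delta G(\vec s) + c,$$

so the converged bias implies
$\Delta G = -\frac{T+\Delta T}{\Delta T} B$ (`implied_free_energy()`), and
the residual landscape felt by the walkers is $\Delta G/(1 + \Delta T/T)$ —
$T + \Delta T$ acts as an effective temperature along the CV. $\Delta T \to 0$
recovers unbiased sampling; $\Delta T \to \infty$ recovers constant-height
deposition.

Numerical choices worth knowing:

* **Truncation.** Deposits touch only nodes within $5\sigma$ per dimension
  (relative error below $e^{-12.5}$), keeping deposition cost independent of
  grid size.
* **Edges.** Gaussian mass falling outside the grid is lost, not
  renormalised — renormalising would distort free energies at the borders.
  A warning fires when a deposit centre sits within $2.33\sigma$ of an edge
  (>1% mass loss). Domains should be generous, and for systems that can
  physically leave the mapped window the fixture adds harmonic CV walls
  (`with_cv_wall()`), since outside the grid the bias exerts no force at
  all.
* **Amplitude lookup.** $w_t$ uses the interpolated bias at $\vec s_t$, not
  the nearest node, for consistency with the potential the walker feels.
* **Bias snapshots fluctuate.** A deposited bias wobbles around its
  converged profile by roughly one Gaussian height. `metad_run()` therefore
  accumulates a time-averaged bias *shape* (snapshots every 10 cycles over
  the second half of the run, aligned by their spatial mean so the uniform
  late-time growth of $B$ cancels). The averaged shape, returned as
  `bias_avg`, roughly halves the error of the implied free energy relative
  to the final snapshot and is what the benchmarks use.

Bias forces on particles follow the chain rule
$F = -(\partial B/\partial s)(\partial s/\partial q)$: the CV-space
derivative comes from central differences of the interpolated bias at one
grid spacing (the Monte Carlo sampler instead uses the interpolated energy
directly), and $\partial s/\partial q$ from the CV's analytic gradient where
available, else central differences of the CV.

## Multiple walkers

`metad_run()` evolves $N$ replicas that feel and feed a single shared bias,
the standard route to an $N$-fold speed-up in bias convergence; early in a
run the walkers' own deposits push them apart into different regions. Within
a cycle, deposits are applied sequentially in walker order, each seeing the
bias left by its predecessors; the alternative (all amplitudes evaluated
against the pre-cycle bias) differs only at order $A^2/\Delta T$. Each
walker owns an independent Mersenne-Twister stream derived from the master
seed, so runs are bit-reproducible and independent of scheduling. By default
walkers start at evenly spaced quantiles of the CV domain.

## Samplers

*Langevin MD*: velocity-Verlet with an Andersen-like thermostat — dynamics
are Newtonian except that every `thermostat_interval` steps a fraction of
particles redraws velocities from the Maxwell–Boltzmann distribution. The
interval default is 1000 steps, the convention for coarse-grained nucleotide
models (the toy systems use 100 to reach the diffusive regime within short
runs); masses are 1.

*Metropolis MC*: single-particle uniform displacements accepted with
$\min(1, e^{-\Delta U})$, where $U$ includes the interpolated bias. MC is
the cheaper sampler for point-walker systems (no force evaluations) and
mixes faster across saddles at equal wall-clock cost; the 2D
state-probability benchmark builds its bias with MD walkers and samples the
frozen bias with MC for exactly that reason.

## Free-energy estimators

Two independent routes are implemented, and their agreement is itself a
convergence diagnostic:

1. **Implied free energy** from the converged bias (above).
2. **Histogram route** (`histogram_free_energy()`), the preferred estimator:
   sample under the *frozen* converged bias, then undo it per histogram bin,
   $\Delta G(s) = -\ln N(s) - B(s)$, min-shifted (the additive constant is
   immaterial). Because sampling occurred under whatever $B$ actually is,
   this estimator is exact in equilibrium even if $B$ is imperfect — bias
   imperfection only costs sampling efficiency. Empty bins are flagged, not
   interpolated, and per-bin standard errors are between-replica standard
   errors of the per-replica estimates (requiring at least two replicas),
   matching how replicate errors are usually quoted for these systems.

For 2D visualisation, `kde_landscape_2d()` wraps a Gaussian-kernel density
(bandwidth given as the kernel standard deviation; the conventional choice
for these landscapes is 0.05 CV units). Its output carries a caveat
attribute for a reason: near a hard feature — e.g. the kinked state, where
the stacking order parameter is exactly 0 and the density has an atom — the
$-\ln(\text{density})$ surface depends strongly on the bandwidth and shows
bistability rather than quantitative free energies.

## Collective variables

Shipped CV families, all rotation- and translation-invariant except where
noted:

* `cv_com_distance()` — distance between centroids of two bead groups
  (unweighted means: coarse-grained beads are treated as equal-mass).
  Biasing a many-bead group distance bends a duplex; biasing a two-bead
  distance concentrates the force on one interaction and tears it, which is
  why `check_cv_design()` warns on single-bead groups. Its analytic gradient
  makes it cheap inside MD loops.
* `cv_diagonal_distances()` — the 2D $(x_1, x_2)$ pair across a four-way
  junction's diagonals. The two stacked isomers sit at (small, large) and
  (large, small); the open intermediate has both large, so the transition
  state occupies unique CV values — the key design criterion for CVs meant
  to force transition-state sampling.
* `cv_sum_distance()` — the 1D $x_1 + x_2$ order parameter with closed-form
  gradient, for runs where a one-dimensional bias suffices.
* `bend_angle_phi()` — the signed bending angle on $(0^\circ, 360^\circ)$
  built from four reference groups (near/far on two arms) plus an
  orthogonal reference pair. The unsigned angle comes from the arm vectors'
  dot product; the lift to $(0,360)$ uses the sign of
  $(\vec v_{top} \times \vec v_{bottom}) \cdot \hat v_{ortho}$, with
  $\phi = 360^\circ - \phi^{(0,180)}$ when that indicator is positive. The
  handedness of this convention is arbitrary (the mirror image of a
  configuration maps $\phi \mapsto 360^\circ - \phi$, verified by a property
  test); what matters is that it is applied consistently to all frames of an
  analysis.
* `cv_stack()` / `kth_weakest_stack()` — the k-th least-negative
  per-junction stacking energy of the kinkable chain, an analysis CV that
  is exactly 0 when at least k junctions are fully kinked.

For real origami-scale structures, the reference-group recipe that works in
practice is: two groups of six nucleotides (three base pairs) per arm,
adjacent to crossovers, two helical turns (21 nt) apart, so the referenced
base pairs share an orientation. `duplex_topology()` encodes the analogous
rule for plain duplexes (multi-nucleotide end groups spanning both strands).
These are documented defaults, not enforced constraints.

## The kinkable chain

The desk-scale stand-in for duplex buckling is a bead-spring chain with
stiff harmonic bonds and a capped bending energy: junction $i$ contributes
$\min(\tfrac{1}{2}\kappa\theta_i^2,\ E_{kink})$. The cap models a local
break in coaxial stacking — beyond the threshold angle
$\theta^* = \sqrt{2E_{kink}/\kappa}$ the junction "kinks" and further
curvature is free, so a compressed chain either bends smoothly (curvature
spread over all junctions) or concentrates it in one kinked junction.
Constructor defaults ($\kappa = 40$, $E_{kink} = 10\,k_BT$, 16 beads) give a
buckling-barrier scale of order $10\,k_BT$.

The benchmark fixture stiffens this to $\kappa = 56$, $E_{kink} = 14\,k_BT$
(same $\theta^*$). The reason is an artefact of the cap: the junction
potential is *flat* beyond $\theta^*$, so a junction that touches the cap
lingers there. With 14 interior junctions, a run long enough to converge the
bias gives the uncompressed chain
$\sim\!10^4 \times e^{-E_{kink}}$ opportunities to kink spontaneously —
non-negligible at $10\,k_BT$, negligible at $14\,k_BT$. The fixture also
confines the end-to-end CV to $[0.5, 1.05]$ of the straight extension with
harmonic walls: the smooth-bend/kink crossover sits near 3/4 compression,
and without walls the walkers spend the run crumpling the chain into states
far outside the window being mapped (where the gridded bias cannot push
back).

## WLC springs and reweighting

Compliant origami joints are bent in experiment by single-stranded DNA
sections acting as entropic springs. Their free energy is modelled with the
integrated Marko–Siggia interpolation

$$\Delta G_{WLC}(L) = \frac{L_0}{L_p}\left[\frac{L^2}{2L_0^2}
  + \frac{1}{4(1 - L/L_0)} - \frac{L}{4L_0} - \frac{1}{4}\right],$$

normalised so $\Delta G(0) = 0$ (any constant offset cancels in reweighting
ratios), with $L_p = 2$ nm and contour length $0.676$ nm per nucleotide. One
convention deserves emphasis: the nucleotide parameter of a spring is **one
greater** than the number of nucleotides in the physical inserted chain —
with zero inserted nucleotides there is still one nucleotide of separation
between the attachment points. `wlc_spring_set()` applies this internally;
callers always pass physical counts. Attachment separations are measured
between group centroids.

A frame sampled under a frozen bias $B$ is reweighted to the
spring-constrained ensemble with

$$w \propto \exp\!\Big(+B(x) - \sum_{i=1}^{6}\Delta G_{WLC}^{N_i}(L_i)\Big),$$

the $+B$ undoing the bias and the sum applying the six spring penalties
(three short-gap, three long-gap). This sign structure is pinned down by two
independently tested requirements: with no springs the weights must invert
the frozen-bias histogram exactly, and with zero bias they must reduce to
the Boltzmann factor of the added spring energy. A frame with any
$L_i \ge L_{0,i}$ gets weight zero — the WLC's own divergent limit — and is
counted as an overstretch event rather than an error, since strongly biased
toy ensembles legitimately visit such frames. `reweighted_angle_stats()`
reports weighted $\langle\phi\rangle$ and $\sigma(\phi)$, between-replica
standard errors (replicas = runs from different initial conditions, the
scheme used for such error bars in practice), and the Kish effective sample
size $(\sum w)^2 / \sum w^2$ with a configurable degeneracy warning.
Angles are treated linearly, not circularly: joint-angle distributions live
far from the $0/360$ wrap (a warning fires if samples ever span both ends).
`spring_sweep()` evaluates many candidate $(N_{short}, N_{long})$ designs
against one frame set — the inverse-design workflow — with per-candidate
failure isolation and a monotonicity diagnostic of $\langle\phi\rangle$
versus spring length.

## What the synthetic systems do and do not show

The generator (`generate_fixture()`) ships five systems, each with an exact
reference:

* `double_well_1d` — quartic double well, barrier $8\,k_BT$, the
  convergence and ergodicity benchmark. Study conditions: 4 walkers,
  $\sigma = 0.15$, $A = 0.5\,k_BT$, $\Delta T = 8T$, $\tau = 25$ steps,
  2000 cycles, $dt = 0.005$, thermostat every 100 steps.
* `bistable_2d` — two minima and a saddle in a junction-like
  diagonal-distance plane (optionally tilted); exact state probabilities by
  quadrature of the Boltzmann weight.
* `kinkable_chain` — as above.
* `four_group_angle_frame` — a configuration whose signed bending angle is
  prescribed exactly (inverse construction).
* `spring_frame_table` — reweighting frames from a 1D latent variable
  $z$: $\phi$ and all six $L_i$ are linear in $z$, frames are drawn from a
  biased density by inverse-CDF sampling, and the reweighted moments have
  quadrature-exact references.

Sampler settings for these systems were calibrated once, against the study
conditions themselves (an unbiased walker must stay trapped at barrier
$8\,k_BT$ within the run budget, while walkers on the tempered landscape
must diffuse across the domain several times), and then frozen. Two caveats
are documented rather than hidden. First, the trapped-vs-crossing contrast
is a rare-event statement: at these budgets the expected number of unbiased
barrier crossings is small but not zero (the Kramers ratio between tempered
and untempered crossing rates is $e^{\Delta G - \Delta G/(1+\Delta T/T)}
\approx 10^3$, and the biased runs show $\sim\!10^2$ crossings), so an
occasional unbiased excursion over the barrier is physically expected.
Second, passing these benchmarks shows the machinery is correct — that
deposition, tempering, interpolation, force chaining, estimators and
reweighting do what their equations say on systems with known answers. It
does not show that any particular CV choice is adequate for a given real
nanostructure, that a real force field's landscape is converged at these
budgets, or anything about kinetics: the bias deliberately destroys
dynamical information, and no rate claims are made anywhere in the package.

## Problem sizes used by tests and benchmarks

The shipped benchmarks run $2\times10^5$ sampler steps for the 1D
convergence, histogram and ergodicity checks, $2\times10^5$ MD steps plus
$9\times10^5$ MC production moves per 2D state-probability experiment,
$8\times10^4$ chain MD steps per chain arm, and $10^5$ frames for the
reweighting oracle. These sizes were chosen so each benchmark resolves its
acceptance margin by a comfortable factor on a single CPU; the same
machinery accepts larger budgets unchanged.

## Known limitations

* Grids are 1D or 2D only, matching the method's practical use; the cost of
  gridded deposition grows geometrically with dimension.
* The bend-angle CV has no analytic gradient (it is an analysis CV; biasing
  it would fall back to finite differences of the CV).
* Bias files store node values at full precision in a text format chosen
  for diff-ability, not compactness.
* The histogram estimator assumes equilibrated sampling under the frozen
  bias; it flags empty bins but cannot detect unvisited metastable states.
* Replica-based standard errors understate uncertainty when replicas share
  an initial-condition bias; use genuinely different starting states, as
  the production helpers encourage.
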
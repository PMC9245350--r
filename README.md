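# metadyn

Well-tempered, multi-walker metadynamics for coarse-grained nucleic-acid
mechanics, in R.

DNA nanostructures — duplexes, four-way junctions, origami compliant joints
— hide their mechanics behind free-energy barriers of many k<sub>B</sub>T:
unbiased simulation started in one conformer essentially never visits the
others, so the deformation free energy ΔG(s) projected on a collective
variable (CV) cannot be read off occupancy histograms. Metadynamics floods
the landscape with a history-dependent bias built from Gaussians deposited
at visited CV values,

&nbsp;&nbsp;B<sub>t+1</sub>(s) = B<sub>t</sub>(s) + w<sub>t</sub>
exp(−Σ<sub>d</sub> (s<sub>d</sub> − s<sub>t,d</sub>)² / 2σ<sub>d</sub>²),
&nbsp; w<sub>t</sub> = A·exp(−B<sub>t</sub>(s<sub>t</sub>)/ΔT),

where the decaying amplitude (well-tempering) makes the bias converge to
−ΔT/(T+ΔT)·ΔG(s) instead of oscillating, so the landscape is recovered
either directly from the bias or — preferably — from histograms sampled
under the frozen bias, via ΔG(s) = −ln N(s) − B(s). N walkers share one
bias for an N-fold convergence speed-up.

The package provides, for people building or analysing coarse-grained
nucleic-acid models:

* the gridded bias (1D/2D, bilinear interpolation, numerical-derivative
  forces, δx ≤ σ/5 enforced, text persistence);
* CV families: centre-of-mass group distances, junction diagonal-distance
  pairs (and their 1D sum with closed-form gradient), the signed bending
  angle φ ∈ (0°, 360°) of a compliant joint, stacking order parameters, plus
  design-heuristic checks;
* samplers: velocity-Verlet Langevin MD with an Andersen-like thermostat,
  and Metropolis Monte Carlo, both biased through the shared grid, with
  bit-reproducible per-walker random streams;
* free-energy estimators (implied and histogram routes, with
  between-replica standard errors), 2D KDE landscapes, and state
  classification with the conventional −1 k<sub>B</sub>T hydrogen-bond /
  −5 k<sub>B</sub>T stacking thresholds;
* worm-like-chain spring reweighting: the integrated Marko–Siggia free
  energy (L<sub>p</sub> = 2 nm, 0.676 nm/nt, the "+1 nucleotide"
  convention), frame weights exp(+B − ΣΔG<sub>WLC</sub>), reweighted angle
  statistics with Kish effective sample sizes, and design sweeps over
  (N<sub>short</sub>, N<sub>long</sub>) spring pairs;
* analytic benchmark landscapes, a kinkable bead-spring duplex analogue,
  and readers/writers for oxDNA-format topology/configuration files
  (coordinates in, CVs out; the oxDNA force field itself is not simulated).

## Worked example

Map the 8 k<sub>B</sub>T double-well benchmark with four walkers, then
check the recovered profile against the closed form:

```r
library(metadyn)

fx <- generate_fixture("double_well_1d")          # landscape + study settings
run <- metad_run(fx$potential, fx$cv, fx$grid,
                 n_walkers = 4, n_cycles = 800, tau = 25,
                 sigma = 0.15, height = 0.5, delta_T = 8,
                 sampler = fx$sampler, seed = 42, init_fn = fx$init_fn)
glance(run)
#> # A tibble: 1 × 5
#>   n_walkers n_cycles deposits_made max_bias clamp_events
#>       <int>    <int>         <int>    <dbl>        <int>
#> 1         4      800          3200     29.3            0

ife <- implied_free_energy_result(run)            # -(T+dT)/dT * averaged bias
ref <- analytic_reference(fx$landscape, ife$s)
sel <- ref < 10
cat(sprintf("implied-FE RMSE vs analytic (region dG < 10 kT): %.2f kT\n",
            sqrt(mean((ife$delta_G[sel] - ref[sel])^2))))
#> implied-FE RMSE vs analytic (region dG < 10 kT): 0.42 kT
cat(sprintf("barrier estimate at s = 0: %.2f kT (true 8)\n",
            ife$delta_G[which.min(abs(ife$s))]))
#> barrier estimate at s = 0: 8.19 kT (true 8)
```

3200 Gaussians (4 per cycle, one per walker) flatten both wells within 800
cycles; the implied free energy reproduces the quartic profile to ~0.4
k<sub>B</sub>T and puts the barrier at 8.19 k<sub>B</sub>T. `autoplot(ife)`
draws the profile.

Reweighting a biased ensemble by six ssDNA entropic springs (three per gap,
physical lengths 6 and 12 nt):

```r
sf <- generate_fixture("spring_frame_table", seed = 7, n = 20000)
reweighted_angle_stats(sf$frames, sf$springs)
#> # A tibble: 1 × 7
#>   mean_phi sd_phi se_mean  se_sd    ess n_frames overstretch_events
#>      <dbl>  <dbl>   <dbl>  <dbl>  <dbl>    <int>              <int>
#> 1     182.   23.9  0.0884 0.0720 12133.    20000                  0
cat(sprintf("quadrature reference: mean phi %.2f deg, sd %.2f deg\n",
            sf$mean_phi_true, sf$sd_phi_true))
#> quadrature reference: mean phi 182.18 deg, sd 24.04 deg
```

The weights undo the metadynamics bias and apply the spring penalties; the
reweighted mean angle and spread match the fixture's quadrature-exact
reference within the quoted replica standard errors, at an effective sample
size of ~12k of the 20k frames.

A thin command-line front end (`inst/cli/metad.R`) exposes `run`,
`produce`, `fe`, `reweight`, `fixtures` and `validate` subcommands over a
declarative YAML run configuration; every run writes a log with the
effective parameters, seed and clamp/overstretch event counts.

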
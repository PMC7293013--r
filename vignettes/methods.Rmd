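---
title: "Maximum-entropy ensemble refinement and state discovery with rnareweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy ensemble refinement and state discovery with rnareweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnareweight)
```

## The problem

Molecular-dynamics simulations of RNA produce conformational ensembles that
rarely match solution NMR data perfectly: force fields are imperfect and
sampling is finite. Rather than re-running the simulation under restraints,
one can refine the ensemble *a posteriori* by assigning a new weight to each
frame so that the reweighted averages agree with a set of experimental
observables within their errors, while perturbing the original ensemble as
little as possible. `rnareweight` implements this Bayesian/maximum-entropy
(BME) reweighting together with the forward models needed to back-calculate
NMR observables from coordinates, a base-arrangement metric (eRMSD) for
assigning frames to conformational states, and a random-forest procedure
that asks the complementary question: *which* structural degrees of freedom,
and *which* individual measurements, distinguish the states that the
refined ensemble contains?

## The BME model

Given $n$ frames with prior weights $w^0_j$ and $m$ measurements with
experimental values $F^{\mathrm{exp}}_i$, uncertainties $\sigma_i$ and
per-frame back-calculated values $F_i(x_j)$, the refined weights minimize
the relative entropy to the prior subject to soft agreement with the data.
The dual problem is the unconstrained minimization over Lagrange
multipliers $\lambda_1 \dots \lambda_m$ of

$$\Gamma(\lambda) \;=\; \log Z(\lambda) \;+\; \sum_i \lambda_i
F^{\mathrm{exp}}_i \;+\; \frac{\theta}{2} \sum_i \lambda_i^2 \sigma_i^2,
\qquad
Z(\lambda) = \sum_j w^0_j \exp\Big[-\sum_i \lambda_i F_i(x_j)\Big],$$

with refined weights $w^*_j \propto w^0_j \exp[-\sum_i \lambda_i
F_i(x_j)]$. The hyper-parameter $\theta \ge 0$ trades confidence in the
prior against fit to the data: $\theta \to \infty$ returns the prior,
$\theta \to 0$ enforces the constraints exactly (when feasible).
$\Gamma$ is smooth and convex, so the solution is unique for $\theta > 0$.

Agreement is quantified by the reduced chi-squared
$\chi^2 = \frac{1}{m}\sum_i (\langle F_i\rangle - F^{\mathrm{exp}}_i)^2 /
\sigma_i^2$ and per-measurement Z-scores
$|\langle F_i\rangle - F^{\mathrm{exp}}_i| / \sigma_i$; $\chi^2 \lesssim 1$
means agreement within experimental error. The effective frame fraction
$\varphi_{\mathrm{eff}} = \exp(-\sum_j w^*_j \ln(w^*_j/w^0_j))$ reports how
much of the original ensemble survives reweighting.

### Numerical choices

`bme_solve()` minimizes $\Gamma$ with BFGS using the analytic gradient
$\partial\Gamma/\partial\lambda_i = F^{\mathrm{exp}}_i - \langle
F_i\rangle_{w(\lambda)} + \theta\lambda_i\sigma_i^2$, followed by a damped
Newton polish using the analytic Hessian
$\mathrm{Cov}_{w(\lambda)}(F) + \theta\,\mathrm{diag}(\sigma^2)$.
Internally the problem is reparametrized as
$\tilde\lambda_i = \lambda_i\sigma_i$ acting on
$\tilde F_i = (F_i - F^{\mathrm{exp}}_i)/\sigma_i$; this leaves $\Gamma$
and the minimizer unchanged but makes the gradient a Z-score and keeps the
objective $O(1)$, so the default gradient-norm tolerance of $10^{-8}$ is
reachable even when r$^{-6}$-space NOE rows (values around $10^{-3}$ Å$^{-6}$)
sit next to couplings of several Hz. $Z$ is always evaluated with
log-sum-exp stabilization. The multiplier start is $\lambda = 0$ (the
prior); the solver is deterministic.

$\theta$ is chosen by k-fold cross-validation (`select_theta()`, default
k = 5): measurements are partitioned by a seeded shuffle, BME is solved on
the training folds, and the $\chi^2$ on the held-out fold is averaged; the
$\theta$ minimizing validation $\chi^2$ wins, with ties going to the
*larger* $\theta$ (prefer the prior). The default grid is logarithmic,
$10^{-2} \dots 10^{4}$ in 13 points. Folds are unstratified; an explicit
`folds` argument allows designed partitions.

### Averaging spaces

BME requires observables that are linear in the weights. NOE-derived
effective distances average as $\langle r\rangle_{\mathrm{eff}} =
(\sum_j w_j r_j^{-6})^{-1/6}$, so NOE rows enter the solver in $r^{-6}$
space, with the experimental value transformed as
$F' = F^{-6}$ and the uncertainty propagated to first order as
$\sigma' = 6\,\sigma F^{-7}$. Couplings and RDCs average linearly.
Reports back-transform NOE averages to Å; $\chi^2$ is computed in the
linear-averaging space used by the optimizer, Z-score reports are given in
the measurement's native units.

## Forward models

* **NOE distances** — $r^{-6}$ ensemble averages of inter-proton distances
  (the standard isolated-spin-pair convention for effective distances
  extracted from NOE buildups).
* **Scalar couplings** — the Karplus relation
  $J(\theta) = A\cos^2(\theta+\phi) + B\cos(\theta+\phi) + C$ on backbone or
  glycosidic torsions. Karplus parameterizations are empirical and
  revisable, so the coefficients ship as an editable TSV
  (`system.file("extdata", "karplus_defaults.tsv", package =
  "rnareweight")`) keyed by coupling type; angles are degrees in I/O and
  radians internally.
* **RDCs** — $D_i = D_{\max,i}\, \hat u_i^{\mathsf T} S\, \hat u_i$ with a
  single global alignment (Saupe) tensor $S$: a symmetric traceless 3×3
  matrix with five free components, fitted by weighted linear least squares
  (`fit_alignment_tensor()`) to at least five RDCs, minimizing
  $\sum_i (D_{\mathrm{calc},i}-D_{\mathrm{exp},i})^2/\sigma_i^2$ over the
  weighted ensemble average of the bond-orientation products. The tensor is
  fitted on the *prior* ensemble and held fixed during reweighting; this
  linearization keeps each BME solve convex. Rank-deficient designs (all
  bonds parallel) are rejected as unidentifiable. Per-bond normalization
  constants $D_{\max}$ are configuration (default 1, i.e. RDCs in units of
  $D_{\max}$).

## eRMSD and state assignment

The eRMSD compares two nucleic-acid structures through the relative
arrangement of their bases only. For each base, a body-fixed frame is
placed at the centroid of the six-membered ring (x toward C2, z normal to
the C2/C4 plane, y completing the triad). For every ordered base pair the
inter-base vector, expressed in the first base's frame, is anisotropically
scaled by (5, 5, 3) Å — de-emphasizing in-plane offsets relative to
stacking offsets — and mapped to a smooth four-component G-vector that
decays to zero at scaled distance 2.4 (with $\gamma = \pi/2.4$). The eRMSD
is the root-mean-square G-vector difference over all ordered pairs,
normalized by the number of bases. It needs no superposition, is symmetric
and non-negative, and vanishes exactly on rigid copies. These constants are
pinned in the package for reproducibility.

Frames are assigned to the major state A when their eRMSD from the
reference conformation is strictly below a threshold (default 0.7, the
conventional boundary between native-like and rearranged base
arrangements); the boundary value itself is state B. State populations are
weight sums over labels, and their uncertainties can be estimated with
`block_standard_error()`: frames are split into contiguous, time-ordered
blocks (default 4, matching trajectory-correlation logic; remainder frames
go to the last block), the weighted statistic is recomputed per block with
renormalized weights, and the SE is the across-block standard deviation
divided by $\sqrt{n_{\mathrm{blocks}}}$. Free-energy surfaces over two
collective variables are weighted log-histograms in units of $k_BT$,
anchored so the occupied minimum is zero (absolute free energies are
undefined), with empty bins masked.

Prior weights for enhanced-sampling ensembles come from the deposited
final bias potential: $w^0_j \propto \exp(V_j / k_B T)$, invariant to
uniform shifts of $V$. Because deposited files sometimes store $-V$, the
sign is an explicit argument rather than a guess.

## Random-forest state discovery

To characterize *what distinguishes* the states, the package trains an
ensemble of 100 randomized decision trees of maximum depth 2 (via
`ranger`) to classify bootstrap samples (drawn with probability equal to
the refined weights; default 50 000 draws) into states A/B, using either
structural features (torsions, ring-center distances) or back-calculated
per-frame experimental values as inputs. 80% of the samples train the
forest; the held-out 20% report accuracy. The classifier itself is
disposable — the product is the impurity-based feature-importance ranking,
normalized to sum to one, with a strict cutoff (default 0.2) selecting the
state-sensitive features or measurements.

Two encoding choices matter. Torsions are circular, so each angle enters as
a (sin, cos) pair to avoid wrap-around artifacts in axis-aligned splits;
the importance of a pair is summed back under the torsion's name. (A raw
degrees encoding is selectable.) NOE features use per-frame *distances*
rather than $r^{-6}$ values, for interpretability; RDC features use the
prior-ensemble tensor, because per-frame tensor fitting is ill-posed.
Correlated features share importance in impurity rankings — a set of
perfectly co-discriminating features splits the score among its members —
so candidate feature sets should be chosen to match the question asked, as
is done per dataset for measurement features.

## The synthetic two-state generator

Because the package's claims are about *recovery* — can the pipeline find
the truth it was given? — every stage is exercised on synthetic ensembles
with known ground truth (`make_two_state_ensemble()`). The generator
builds a 14-residue hairpin of pseudo-nucleotides: idealized hexagonal
six-membered rings, a simplified sugar/backbone with every atom needed to
define the seven standard torsions, and named protons for NOE pairs. It is
deliberately not chemically realistic — forward models and metrics depend
only on named atoms and geometry.

Two rigid templates define the states: in state A the loop is closed, with
the designated ring-center contacts 6–8 and 6–9 below 5 Å and the
residue-8 ζ torsion in the gauche+ well (+55°); in state B residues 8 and 9
swing out (contacts above 8 Å) and ζ₈ flips to gauche− (−70°), while
residue 7 bridges. Inter-residue phosphates are placed by internal
coordinates so ζ is controlled exactly. Frames add isotropic Gaussian
coordinate jitter (default 0.15 Å), small enough that eRMSD labels against
template A reproduce the construction labels exactly while keeping the
states well inside/outside the 0.7 threshold (template separation ≈ 1.0).
Templates are checked for steric clashes below 0.5 Å.

Half the frames come from each template (`frame_fraction_a = 0.5`), and the
*true* weights are uniform within each state, scaled so the true state-A
population equals `population_a` (default 0.6). A uniform prior therefore
starts at population 0.5 and reweighting must travel to the truth — if the
true weights equaled the prior, recovery would be vacuous. Synthetic
measurements (defaults: 30 NOE pairs, 10 ζ couplings, 8 C1′–H1′ RDCs from a
fixed generator tensor) are exact truth-weight averages plus independent
Gaussian noise whose standard deviation is honestly reported as the
measurement σ (`noise_scale` times a per-class scale: 1 Å, 5 Hz, 0.5 Hz).

What passing these tests shows — and does not show. The generator
reproduces the *structure* of the inference problem: two states, ensemble-
averaged data of three observable classes, honest noise, a prior that
disagrees with the truth. It does not emulate force-field bias with
realistic conformational diversity within states, spin diffusion or motional
corrections to NOEs, alignment-medium physics for RDCs, or Karplus-curve
uncertainty. Recovery on synthetic data is therefore necessary, not
sufficient, evidence for conclusions about real ensembles.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (ensembles
of 80–200 frames, 48 measurements, 100-seed forest replicates) were chosen
as the smallest at which the statistical checks are stable; all scale
linearly if larger runs are wanted.

## Known limitations

* Upper/lower-bound NOE restraints are treated as equalities with their
  stated σ inside BME (their `sense` is parsed and retained); one-sided
  multipliers are not enforced.
* The alignment tensor is not refitted during reweighting (linearization);
  iterating fit-and-reweight to self-consistency is straightforward but not
  automatic.
* Trajectory input is multi-model PDB or DCD with a PDB topology;
  coordinates are Å internally with nm conversion on read.
* No base-pair annotation, RMSD clustering, spin-relaxation-matrix NOE
  treatment, or solvent-PRE/cross-correlated-relaxation forward models.

## A minimal run

```{r example, eval = FALSE}
bundle <- make_two_state_ensemble(n_frames = 150, population_a = 0.83,
                                  seed = 1)
meas <- make_synthetic_measurements(bundle, noise_scale = 0.02, seed = 2)

w0 <- uniform_weights(bundle$ensemble)
om <- build_observable_matrix(bundle$ensemble, meas, weights = w0)
sel <- select_theta(om, w0, seed = 1)
fit <- bme_solve(bme_problem(om, w0, theta = sel$theta))

labels <- assign_states(ermsd_traj(bundle$ensemble, bundle$template_a))
population(labels, w0)           # prior population (0.5 by construction)
population(labels, fit$weights)  # recovered population (~0.83)
fit                              # chi2 before/after, phi_eff
```
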
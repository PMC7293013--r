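# rnareweight

Maximum-entropy refinement of RNA conformational ensembles against NMR
data, with eRMSD-based state assignment and random-forest discovery of
state-discriminating features.

## What it is for

Molecular-dynamics ensembles of structured RNAs (the package's running
example is a UUCG-tetraloop-style 14-mer hairpin) rarely agree perfectly
with solution NMR measurements. `rnareweight` refines such an ensemble *a
posteriori*: it assigns new weights to the existing frames so that
back-calculated averages match experimental NOE distances, scalar couplings
and residual dipolar couplings within their errors, while maximizing the
relative Shannon entropy to the original ensemble. It then answers the
structural question the refinement raises — if the refined ensemble
contains a minor conformational state, which torsions, base-base contacts,
and which individual measurements are sensitive to it?

The target audience is computational structural biologists combining MD (or
enhanced-sampling) ensembles with NMR data.

## The model

Refined weights solve the Bayesian/maximum-entropy (BME) dual problem: with
prior weights $w^0_j$, observables $F_i(x_j)$, data $F^{exp}_i$ and errors
$\sigma_i$, minimize over Lagrange multipliers $\lambda$

$$\Gamma(\lambda) = \log Z(\lambda) + \sum_i \lambda_i F^{exp}_i +
\tfrac{\theta}{2}\sum_i \lambda_i^2\sigma_i^2, \qquad
Z = \sum_j w^0_j e^{-\sum_i \lambda_i F_i(x_j)},$$

giving $w^*_j \propto w^0_j \exp[-\sum_i \lambda_i F_i(x_j)]$. The
confidence parameter $\theta$ is chosen by 5-fold cross-validation.
Agreement is reported as reduced $\chi^2$ and per-measurement Z-scores;
NOEs average in $r^{-6}$ space, couplings through Karplus equations, RDCs
through a least-squares-fitted alignment tensor. Frames are assigned to a
major/minor state by eRMSD (a superposition-free base-arrangement metric)
against a reference structure, with the conventional 0.7 threshold. A
depth-2 random forest trained on weighted bootstrap samples ranks features
(torsions, ring-center distances, back-calculated measurements) by their
ability to separate the states. See `vignettes/methods.Rmd` for the full
account, including the synthetic two-state generator used to validate
every stage against known ground truth.

## Worked example

Generate a synthetic two-state hairpin whose true state-A population is
0.83, with noisy ensemble-averaged measurements, then recover that
population from a uniform prior and identify the discriminating features:

```r
library(rnareweight)

bundle <- make_two_state_ensemble(n_frames = 150, population_a = 0.83,
                                  seed = 1)
meas <- make_synthetic_measurements(bundle, noise_scale = 0.02, seed = 2)

w0  <- uniform_weights(bundle$ensemble)
om  <- build_observable_matrix(bundle$ensemble, meas, weights = w0)
sel <- select_theta(om, w0, theta_grid = 10^seq(-2, 4, length.out = 7),
                    seed = 1)
fit <- bme_solve(bme_problem(om, w0, theta = sel$theta))

labels <- assign_states(ermsd_traj(bundle$ensemble, bundle$template_a))
population(labels, w0)           # 0.5      (uniform prior)
population(labels, fit$weights)  # 0.8116   (recovered, truth 0.83)
fit
#> <bme_result> theta = 100  chi2: 70.56 -> 0.3573  phi_eff = 0.769

idx <- bootstrap_samples(150, fit$weights, n_samples = 5000, seed = 3)
fs  <- structural_features(bundle$ensemble, idx, torsions = "zeta",
         ring_pairs = lapply(setdiff(1:14, 5:7), function(r) sort(c(6, r))))
clf <- train_state_classifier(fs, labels[idx], seed = 4)
clf$accuracy                     # 1 (held-out)
head(rank_importance(clf), 4)
#>    feature            kind importance
#> 1   zeta_8     torsion_deg 0.36419263
#> 2 ring_6_9 ring_distance_A 0.35667620
#> 3 ring_6_8 ring_distance_A 0.21422496
#> 4  zeta_10     torsion_deg 0.01736027
```

The refinement moves the population from the prior's 0.5 to 0.81 against a
truth of 0.83, drops the training $\chi^2$ from 70.6 to 0.36 (below 1, i.e.
within experimental error) while retaining 77% of the effective frames, and
the importance ranking singles out exactly the features the generator
planted: the flipped residue-8 ζ torsion and the opened 6–8/6–9 ring
contacts.

File-based workflows (multi-model PDB/DCD ensembles, measurement TSVs,
bias-potential weight files, YAML run configs) go through
`read_run_config()` / `run_simulate()` / `run_refine()` / `run_classify()`;
a thin command-line wrapper ships in `inst/scripts/rnareweight.R`.

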
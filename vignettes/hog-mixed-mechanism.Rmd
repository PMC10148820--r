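---
title: "Modelling distributive, processive and mixed Hog1 phosphorylation"
author: "hogmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling distributive, processive and mixed Hog1 phosphorylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hogmix)
```

## The scientific problem

Activation of the MAP kinase Hog1 in *Saccharomyces cerevisiae* requires
phosphorylation of two sites by the MAP kinase kinase Pbs2.  Two limiting
mechanisms are classically distinguished.  Under a **distributive**
mechanism, Hog1 dissociates from Pbs2 after each phosphorylation event and
the mono-phosphorylated form must rebind before the second site can be
modified.  Under a **processive** mechanism both sites are phosphorylated
within a single binding event.  The distinction matters because
distributive multisite phosphorylation is a canonical generator of
ultrasensitivity, while processive phosphorylation is usually associated
with graded responses.  A **mixed** mechanism lets the Pbs2-bound
mono-phosphorylated intermediate either proceed immediately to the doubly
phosphorylated form (rate constant `k_phospho`) or dissociate (rate
constant `k_off`); the ratio of these fluxes is the effective processivity
and can be shifted in time by feedback, for example by Hog1-dependent
phosphorylation of Pbs2 serine 248 which increases Hog1--Pbs2 affinity.

`hogmix` implements this question end to end: an overcomplete reaction
network of the high-osmolarity glycerol (HOG) pathway whose submodels
("topologies") differ in the phosphorylation mechanism, the positive
feedback target (Pbs2, or Sln1/Ssk1 plus Ste20) with separable *catalytic*
and *affinity* components, and negative feedback on Ssk2; a stiff ODE
simulator with an osmotic volume module; observables matching
mass-spectrometry fold changes, western-blot percent phosphorylation,
single-cell nuclear:cytosolic Hog1 ratios and cell-area traces; a
`-2 log L` objective with multistart likelihood optimisation and AIC
ranking; and the post-fit analyses (processivity score, Hill/EC50 fits,
robustness ensembles, Harrell--Davis quantile-shift statistics).

## Model structure

### Signalling network

The overcomplete network (`build_network()`) contains:

* the Sln1 branch, collapsed to a two-state relay: active Sln1 represses
  Ssk1; turgor loss inactivates Sln1, releasing Ssk1 to activate Ssk2;
* the Sho1 branch: stress-activated Sho1 binds Ste20 (Ste50 is lumped into
  this scaffolded step) and the complex activates Ste11;
* Pbs2 activation by either MAPKKK, as a Michaelis--Menten step saturable
  in Pbs2 -- active Pbs2 therefore does not scale freely with Pbs2
  abundance, which is what makes overexpression experiments informative;
* the Hog1 core: binding of cytosolic Hog1 to active Pbs2, a first
  phosphorylation producing the nascent complex `Pbs2PPHog1P`, and from it
  either the immediate second step (`k_phospho`, processive route) or
  dissociation (`k_off`, distributive route); free mono-phospho Hog1 can
  rebind (species `Pbs2PPHog1P_re`) and complete phosphorylation.  The
  pure mechanisms are exact limits of the mixed network: dropping the
  immediate second step gives the distributive variant, dropping
  dissociation and rebinding the processive one (a structural test asserts
  trajectory equality below 1e-6);
* a constitutive, catalytically dead Pbs2--Hog1 scaffold complex
  (`kon_scaf`/`koff_scaf`, weak by default).  Pbs2 is a scaffold protein,
  and a tight scaffold titrates Hog1 away when Pbs2 is in excess;
* positive feedback: doubly phosphorylated cytosolic Hog1 converts active
  Pbs2 into a feedback-modified form whose catalytic rates are multiplied
  by `fb_cat` and whose association rates by `fb_aff`; the conversion is
  Michaelis--Menten in Pbs2 (the Hog1 kinase saturates), so the
  feedback-modified *fraction* is diluted when Pbs2 is overexpressed.
  `k_off` is shared between basal and feedback complexes;
* negative feedback: Hog1-PP-dependent deactivation of active Ssk2;
* phosphatases: Ptp2 (nuclear) and Ptp3 (cytosolic) as explicit
  Michaelis--Menten enzymes, plus small first-order background rates
  standing for the Ser/Thr phosphatases Ptc1 and Ptc2/3;
* nucleocytoplasmic shuttling of all Hog1 forms, with faster import of the
  doubly phosphorylated form.  The nucleus is taken as 10% of cell volume
  for concentration conversion.

Every protein has an exact conserved total (checked as a left null vector
of the stoichiometry matrix, for every enumerated topology).  Amounts are
normalised so wild-type totals are 1; all observables are ratios or
percentages and therefore scale-free.

A note on the mono-phosphorylated species: the model carries a single
mono-phospho Hog1 form, interpreted as phosphotyrosine-176 (the form the
mass-spectrometry observable reports); the order of the two
phosphorylations is collapsed.  For the same reason the two western-blot
observables (`wb_percent_total_phospho`, `wb_percent_pY`) coincide in this
model.

### Volume module

States: relative volume $V$ and intracellular glycerol $G$ (osmolar
units).  Turgor is a smooth saturating-linear function of $V$ above a
loss point $V_{lp}$ (default 0.6), equal to its resting value $\Pi_t^0$
(0.2 osmolar equivalents) at $V = 1$.  Volume follows the osmotic
imbalance $dV/dt = -k_p(\Pi_e + \Pi_t - (osm_i + G)/V)$ against a medium
baseline of 0.25 M.  Glycerol production has a Hog1-PP-dependent term (a
Gpd1 proxy; zeroed when Hog1 is chemically inhibited) and a smaller
Hog1-independent term proportional to the stress signal, which is what
lets pbs2-deleted cells recover volume slowly and partially within the
experimental window.  Efflux is proportional to $G$ times
$(\Pi_t/\Pi_t^0)^3$: the Fps1 channel closes under stress and reopens
when turgor is restored or excessive, which bounds the hyperactive
steady state of the Ptp2/Ptp3 deletion.  The osmosensor input to both
branches is the relative turgor deficit
$s = \max(0, 1 - \Pi_t/\Pi_t^0)$, smoothly clipped; all clamps use a
smooth positive part with width $10^{-3}$ because hard kinks in the
Jacobian make the stiff integrator chatter near equilibria.

This module deliberately omits two things: signalling rates are not
concentration-corrected for cell shrinkage (molecular crowding is a
candidate contributor to processivity changes that the package does not
model), and there is no transcriptional memory beyond the Gpd1 proxy, so
after adaptation the model can show small damped reactivation transients
that real cells buffer.

### Strains

`hog_strain()` covers gene deletions (zeroed conserved totals),
overexpression (scaled initial totals), Hog1 chemical inhibition (all
Hog1-catalysed rates zeroed, binding and Hog1's own phosphorylation
intact), a feedback-dead Ssk2 (negative-feedback reaction removed), and
the Pbs2 serine-248 alleles.  `S248A` removes the affinity component of
the feedback (the multiplier collapses to 1; the catalytic component is
untouched).  `S248E` is phosphomimetic: Pbs2 is constitutively in the
S248-phosphorylated state, implemented as a fast Hog1-independent
conversion to the feedback form, so the Hog1-association parameters sit
at their feedback-modified values from the start.  This constitutive-state
reading (rather than rescaling the basal association constants) is what
makes the pre-stimulus processivity score of the phosphomimetic exceed
the wild type's, because the score weighs the feedback-complex share.

## Simulation and objective

Integration uses `deSolve`'s `lsoda` with an analytic Jacobian generated
from the reaction structure (relative tolerance 1e-8, absolute 1e-10 by
default; the structural equivalence tests run at 1e-10/1e-12).  Step and
pulse discontinuities restart the solver at the break points, so the
forcing is exact.  Pre-equilibration integrates the unstimulated system
until the right-hand-side norm falls below 1e-9 (relative), with a hard
time cap; non-convergence and solver breakdowns return failure signals
that the objective converts into large finite penalties -- multistart
optimisation must survive pathological parameter draws, never crash on
them.  Negative amounts beyond solver noise (-1e-12) are a failure;
smaller excursions are clipped.

The objective is the Gaussian `-2 log L`:
$\sum_i (y_i - \hat y_i)^2/\sigma_i^2 + \log(2\pi\sigma_i^2)$, with
additive error on each observable's own scale (fold change, percent,
ratio) and no log transform.  Error scales are fixed per error class by
default; classes can instead be declared fitted (log10-parameterised,
floored at 1e-3) -- the Ptp2/Ptp3 western-blot series carries its own,
deliberately wide, error class.

## Fitting pipeline

`hog_fit()` is the central interface: it builds the network for a
topology, compiles the dataset into strain x protocol conditions, and
minimises the objective by multistart local optimisation
(`refine()`).  Defaults mirror the reference pipeline -- 10,000 uniform
starting vectors in log10 bounds (-3..3 per parameter, or class-wise
physiological bounds), bound-constrained descent (L-BFGS-B) stopped at
400 iterations or an objective change below 1e-6, then repeated rounds
sampling from a multivariate normal fitted to the 100 best vectors of the
previous round, until the best objective of the latest round is as good
or worse than the round before.  Ties in the elite selection break by
start index; a degenerate elite covariance is floored on the diagonal.
Model comparison uses `AIC = 2k - 2 ln(L_max)` with `k` the number of
fitted parameters (kinetic plus fitted error-model parameters);
differences above ten are flagged as highly significant.

Desk-scale experiments (tests, the acceptance script, examples) use
reduced budgets set through `hog_control()` -- a handful of starts, a
restricted free-parameter set with the remaining parameters anchored at
known values, and a subset of the catalogue conditions.  The vignette's
problem sizes below are those choices, stated once: identifiability uses
three wild-type 0.4 M series (mass-spec fast, western blot,
nuclear:cytosolic) with four free parameters and 5 starts x 2 rounds;
model recovery uses the two mass-spec series plus the western-blot series
with three free parameters, 2 starts, and five seeded replicates; the
basic-cascade comparison fits five parameters from 3 starts x 2 rounds.

## Synthetic corpus

`design_catalogue()` returns the packaged design emulating the multimodal
fitting corpus; rows with `use == "fit"` total exactly 533:

| block | series | points |
|---|---|---|
| MS fold change, Hog1-PP | 0--60 s every 5 s (the 60-s slot is the mean of two emulated source studies, sigma/sqrt 2) + 5--30 min | 19 |
| WB percent | wild type; ptp2 ptp3 deletion (pY observable, wide error class); Hog1-inhibited with/without salt | 24 |
| nuclear:cytosolic ratio | steps 0.05--0.6 M (7 doses); pulse trains 0.2 M at 2/4/8/16 min; sln1, sho1, S248A, S248E; late-time feedback-dead Ssk2 | 409 |
| cell area | wild type 0.2/0.4 M; pbs2 deletion 0.4 M | 81 |

A 0.2 M linear-ramp nuclear:cytosolic series is generated but held out
(`use == "test"`), and the mono-phospho MS series carries an
`include_best_fit` flag: excluded from the canonical eight-topology
experiment, flipped into the fit set by `catalogue_with_mono()` for the
best-fitting mixed-mechanism experiment.  Exact per-dataset grids of the
original corpus are not public; the packaged grids (5-s mass-spec
cadence, 90-s microscopy cadence over 40 min, six western-blot times)
are plausible reconstructions that preserve the corpus's statistical
structure and its total size.

`generate_dataset()` simulates every condition under a ground-truth
network, evaluates the observables at the catalogue times and adds
Gaussian noise at each row's error scale (seeded).  What passing tests on
this corpus do *not* show: the generator draws independent Gaussian
errors around a deterministic model, so it cannot expose misfit caused by
cell-to-cell variability, correlated measurement error, or observable
misspecification in real data.

## Reference calibration

The package ships one frozen reference parameter set per mechanism
(`hog_reference_params()`), each with both feedback components and
negative feedback.  They were hand-calibrated once against the qualitative
behaviour of the system -- low basal Hog1-PP (<1%) with fast strong
activation at 0.4 M NaCl and adaptation within ~15 min; volume drop to
~80% and glycerol-driven recovery, partial in pbs2-deleted cells; raised
basal (~40-50%) and prolonged phosphorylation without Ptp2/Ptp3; a
double-peaked mono-phospho time course under the distributive mechanism
and its absence under the processive one; suppression of activation under
10x Pbs2 in the processive variant only -- and then frozen.  The
processive reference differs from the shared set in a faster immediate
second step and a tight dead scaffold complex.  Known honest deviations
from the original study's figures: removing the affinity feedback (S248A)
lowers the 0.4 M peak strongly rather than slightly (the calibration sits
close to an activation threshold), and the second mono-phospho peak of
the distributive variant is not lower than the first.  Simulated
dose-responses of the frozen calibration give a shallow Hill coefficient
for the mixed variant (~1.2, EC50 ~0.016 M) and a very steep one for the
distributive variant (~14 at EC50 ~0.09 M); these are properties of this
calibration, not reproductions of the original fitted models, whose
headline coefficients depended on fits to the original data.

## Analyses

* **Processivity score** (`processivity_score()`): the ratio of the
  immediate second-phosphorylation flux of the nascent complexes (basal
  and feedback, with their respective rate constants) to their
  dissociation flux with the shared `k_off`.  It is scale-invariant in
  the complex amounts and undefined (NA) when both complexes vanish.  On
  the reference calibration it rises from ~0.6 before stimulus to ~6.5
  at the peak of the response -- the feedback switches the reaction from
  distributive-like to processive-like -- and relaxes slowly afterwards.
* **Hill fits** (`hill_fit()`): deterministic initialisation (n0 = 2,
  EC50 from half-maximal interpolation), n bounded in (0.1, 20), via
  Levenberg--Marquardt least squares; a monotonicity diagnostic flags
  degenerate inputs.
* **Robustness ensembles** (`perturbation_ensemble()`): log-uniform
  multipliers in [0.5, 2] (the source states only that concentrations
  were varied in that range; log-uniform treats halving and doubling
  symmetrically, recorded in the result's metadata) applied to Sln1,
  Ssk1, Ssk2, Ste20, Pbs2, Ptp2 and Ptp3; each run re-equilibrates and
  records maximal Hog1-PP percent; failures are recorded, never dropped.
* **Quantile shift** (`quantile_shift()`): Harrell--Davis quantiles on
  the 0.05..0.95 grid, percentile-bootstrap 95% intervals from 200
  resamples, and significance flags from bootstrap p-values controlled by
  Hochberg step-up at 5% across the 19 grid points (the multiplicity
  procedure is not named in the source; Hochberg is the convention
  adopted here).
* **Perturbation regression** (`regress_perturbations()`): ordinary least
  squares of the ensemble maxima on the seven multipliers with a QR rank
  check that refuses collinear designs.

## Numerical choices and limitations

Tolerances, clamp widths and penalties are listed above where they arise.
Further limitations worth stating: the Sho1 branch is a reduced
sequential-binding representation (no Ahk1, Ste50 lumped), so its fitted
association rates may drift to large values as in the original study;
deletion strains are implemented mechanically (zeroed totals), so
`sln1` deletion produces constitutive pathway activation rather than the
branch-dead behaviour of the corresponding published dataset; and the
model-recovery and identifiability experiments at desk scale anchor
non-free parameters at their generating values, so they probe the
identifiability of the chosen free set, not of the full 60+ parameter
vector.

## Reproducing the analyses

```{r, eval = FALSE}
net <- hog_reference_network("mixed")
tr  <- run_protocol(net, hog_protocol("step", 0.4, horizon = 2400),
                    tgrid = seq(0, 2400, 10))
plot(tr$time / 60, 100 * species_total(tr, c("Hog1PPc", "Hog1PPn")),
     type = "l", xlab = "time (min)", ylab = "Hog1-PP (%)")

d <- generate_dataset(net, design_catalogue(), seed = 1)
fit <- hog_fit(d, hog_topology("mixed"),
               hog_control(n_starts = 8, top_set = 4, iter_cap = 30,
                           free = c("kcat1", "kcat_ptp3")),
               anchors = hog_reference_params("mixed"))
summary(fit)
```

`scripts/acceptance.R` re-runs the whole desk-scale battery (structure
checks, mechanism limits, calibration features, Hill fits,
identifiability, model recovery, the basic-cascade comparison and a
robustness ensemble) and writes the computed quantities as JSON.
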
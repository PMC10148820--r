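# hogmix

Mechanistic ODE models of Hog1 activation in the budding-yeast
high-osmolarity glycerol (HOG) pathway, built to ask how the MAP kinase
acquires its two activating phosphates: **distributively** (Hog1 leaves
Pbs2 after each phosphorylation and must rebind), **processively** (both
sites in one binding event), or through a **mixed** mechanism in which the
Pbs2-bound mono-phosphorylated intermediate either proceeds immediately
(rate `k_phospho`) or dissociates (rate `k_off`), with positive feedback on
Pbs2 shifting the balance between the two routes over the course of the
osmotic-stress response.

The package is aimed at systems biologists who want to enumerate and
compare feedback/mechanism topologies of a MAPK cascade against multimodal
data by maximum likelihood.  It provides:

- an overcomplete HOG reaction network (`build_network()`) whose submodels
  are selected by a `hog_topology()` (mechanism; positive-feedback target
  with separable catalytic and affinity components; negative feedback on
  Ssk2), plus gene deletions, overexpression, Hog1 inhibition and Pbs2
  S248A/S248E alleles via `hog_strain()`, and a Huang–Ferrell-style basic
  three-tier cascade (`build_basic_cascade()`);
- a stiff simulator (compiled right-hand side + analytic Jacobian under
  `deSolve::lsoda`) with an osmotic cell-volume/glycerol module and exact
  step / ramp / pulse-train forcing (`run_protocol()`);
- observables and a Gaussian `-2 log L` objective over mass-spectrometry
  fold changes, western-blot percent phosphorylation, single-cell
  nuclear:cytosolic Hog1 ratios and cell-area traces (`objective()`);
- the fitting pipeline: multistart bound-constrained optimisation in log10
  space with multivariate-normal resampling from the top-100 elite set and
  the stop rule "repeat until a round no longer improves"
  (`hog_fit()`, `refine()`), ranked by `AIC = 2k − 2 ln L_max` with the
  ΔAIC > 10 significance convention (`rank_models()`);
- post-fit analyses: the processivity score
  `([C]·k_phospho + [C_fb]·k_phospho_feed) / (([C]+[C_fb])·k_off)` along
  trajectories, Hill/EC50 fits of simulated dose–responses, robustness
  ensembles under 0.5–2× protein-abundance perturbations with OLS
  regression, Harrell–Davis quantile-shift statistics with percentile
  bootstrap and Hochberg multiplicity control, and bootstrapped histogram
  errors;
- a synthetic-data module (`design_catalogue()`, `generate_dataset()`,
  `recovery_experiment()`) that emulates the structure of the 533-point
  multimodal fitting corpus for identifiability and model-recovery
  experiments.

`hog_fit()` returns a classed model object with the familiar methods
(`print`, `summary`, `coef`, `logLik`, `AIC`, `predict`, `fitted`,
`residuals`, `simulate`, `plot`).

## Worked example

```r
library(hogmix)

net <- hog_reference_network("mixed")          # frozen reference calibration
tr  <- run_protocol(net, hog_protocol("step", 0.4, horizon = 2400),
                    tgrid = seq(0, 2400, 10))
pp  <- 100 * species_total(tr, c("Hog1PPc", "Hog1PPn"))
sc  <- processivity_timecourse(tr)

d   <- generate_dataset(net, design_catalogue(), seed = 1)
fit <- hog_fit(d, hog_topology("mixed"),
               hog_control(n_starts = 4, top_set = 2, iter_cap = 20,
                           max_rounds = 1, free = c("kcat1", "kcat_ptp3")),
               seed = 1, anchors = hog_reference_params("mixed"))
fit
```

printing

```
basal Hog1-PP: 0.17%  peak: 63.3% at 100 s
processivity score: 0.62 (pre-stimulus) -> 6.46 (peak)
synthetic corpus: 579 rows (533 fit)

HOG model fit
  topology:     mixed | positive feedback on pbs2 (affinity+catalytic) | negative feedback on | unconstrained bounds
  data points: 533 (fit)
  -2 logL:      -6.3033
  k:            2 fitted parameters
  AIC:          -2.3033
  rounds:      1 (best per round: -6.303)
```

Read: at 0.4 M NaCl the reference model activates from a sub-percent basal
to a ~63% doubly phosphorylated Hog1 peak within two minutes, while the
processivity score — the ratio of the immediate second-phosphorylation
flux to the dissociation flux of the Pbs2-bound mono-phospho complex —
rises ten-fold, i.e. the positive feedback switches the reaction from
distributive-like towards processive-like behaviour.  The reduced fit
(two free parameters anchored otherwise at the generating truth) recovers
a goodness of fit near the noise floor of the 533-point synthetic corpus;
`AIC = 2k − 2 ln L_max` is reported per fit so that competing topologies
can be ranked with `rank_models()`.

A thin command-line wrapper over the same functions is in
`inst/scripts/hog-cli.R` (subcommands `topologies`, `synth`, `simulate`,
`fit`, `select`, `recover`, `processivity`, `hill`, `robustness`,
`qshift`).

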
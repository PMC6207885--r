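# cmcEEG

Receptor-resolved dynamic causal modelling of resting-state EEG.

Clinical EEG is ubiquitously available but, read visually, says nothing
about synaptic receptors. cmcEEG implements a biophysical assay that tries
to change that: a network of four conductance-based canonical
microcircuits (spiny stellate, superficial pyramidal, inhibitory
interneuron and deep pyramidal populations per source, AMPA / GABA-A /
NMDA channel kinetics, a voltage-dependent magnesium block on the NMDA
conductance) predicts the sensor-space cross-spectral density of
resting-state EEG through linearized transfer functions. Fitting that
prediction to a patient's spectra by variational Bayes turns the EEG into
estimates of receptor-specific parameters; group-level analyses then ask
which receptor class carries a clinical effect. The motivating application
is NMDAR-antibody encephalitis, where the ground truth — a selective NMDA
receptor deficit — is known from the serology.

The model, per population, is a capacitive membrane equation with
first-order channel kinetics:

```
C dV/dt  = gL (VL - V) + gA (EA - V) + gG (EG - V) + gN m(V) (EN - V) + u
dg_r/dt  = kappa_r ( u_r - g_r ),          r in {AMPA, GABAA, NMDA}
m(V)     = alpha / (1 + beta exp(-gamma V))         (magnesium block)
```

with reversal potentials 60 / 10 / −70 mV (sodium, calcium, chloride), a
potassium leak at −70 mV and channel time constants of 12 / 8 / 100 ms
(AMPA / GABA-A / NMDA). Four sources and four populations give 64 coupled
ODEs and 41 free neuronal parameters, partitioned 15 NMDA / 12 AMPA /
8 GABA-A / 6 other; every free parameter is a log-scaling factor on its
prior mean. Sensor-mode spectra are fitted over 20–48 Hz (1856 real +
1856 imaginary features) and 2–6 Hz (320 + 320).

Because no clinical recordings ship with the package, a synthetic cohort
generator (three groups, 18/18/29 by default, receptor-specific group
effects, between-subject variability, sensor noise, an optional occipital
alpha confound) makes the entire pipeline testable end to end. The
methods vignette (`vignettes/receptor-assay-methods.Rmd`) documents the
model, the numerical choices, and — candidly — where identifiability of
the receptor deficit ends under these synthetic conditions.

## A worked example

```r
library(cmcEEG)
net <- build_default_network()
net
#> cmc_network: 4 sources ( parietal.L, parietal.R, frontal.L, frontal.R )
#>   forward edges: 4 | backward edges: 4 | interhemispheric links: 4
#>   SP->SS NMDA variant: FALSE
count_parameters(net)
#> param_partition: 41 neuronal parameters ( NMDA=15, AMPA=12, GABAA=8, OTHER=6 )

# predicted spectra under an NMDA rate-constant deficit
lf <- make_lead_field(net)
set.seed(1)
modes <- qr.Q(qr(cbind(lf$gain, matrix(rnorm(21 * 4), 21))))[, 1:8]
fwd <- forward_model(net, lf, modes, 2:48)
deficit <- setNames(rep(-0.5, 4), paste0("kappa_NMDA.", net$sources))
ctrl <- predicted_csd(NULL, fwd)
enc  <- predicted_csd(deficit, fwd)
round(100 * (band_power_summary(enc, c(28, 40)) /
             band_power_summary(ctrl, c(28, 40)) - 1), 2)
#> [1] 0.33

stability_eigenspectrum(deficit, net)
#> stability_report: 64 eigenvalues | max Re = -0.006065 ms^-1 | ...

# fit the model to its own epoch-sampled prediction
set.seed(2)
obs <- cross_spectra(2:48, cmcEEG:::sample_csd(ctrl$S, 144), tol = 1e-6)
post <- variational_laplace(obs, fwd, default_priors(net),
                            vl_control(max_iter = 12))
post
#> cmc_posterior: 44 parameters | F = 4032.74 | iterations = 5 | R2 = 98.82 %
```

Reading the output: slowing the NMDA channels raises 28–40 Hz power by a
fraction of a percent (the deficit's spectral footprint is subtle, which
is the crux of this assay), moves the slowest eigenvalue of the
delay-adjusted Jacobian from −0.010 to −0.0061 ms⁻¹ — closer to
instability — and a fit to 144-epoch sampled spectra explains ~99 % of
the cross-spectral variance. Group-level analyses build on lists of such
posteriors: `build_design()`, `peb_fit()`, `bmr_search()` for the
Bayesian route, `cva()` and `classify()` for the multivariate one, and
`generate_cohort()` / `invert_cohort()` for full synthetic studies.

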
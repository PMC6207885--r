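---
title: "A conductance-based receptor assay for resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based receptor assay for resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cmcEEG estimates the functional status of ionotropic receptors — AMPA,
GABA-A and NMDA — from resting-state EEG. A biophysical network model
predicts sensor-space cross-spectral densities; variational Bayes fits the
prediction to each subject's spectra; and two group-level analyses
(canonical variates analysis, and parametric empirical Bayes with Bayesian
model reduction) ask which receptor-specific parameters carry group
differences, with NMDAR-antibody encephalitis as the motivating condition.
This vignette documents the model, the free parameters, the numerical
choices, and the limits of what the synthetic-cohort tests demonstrate.

## The neuronal model

Each cortical source is a canonical microcircuit of four populations —
layer IV spiny stellate cells (SS), superficial pyramidal cells (SP),
inhibitory interneurons (II) and deep pyramidal cells (DP). Every
population carries four states: the membrane potential $V$ and three
conductances $g_{\mathrm{AMPA}}, g_{\mathrm{GABA_A}}, g_{\mathrm{NMDA}}$.
The membrane equation balances capacitive current against leak and
ligand-gated channel currents,

$$C\,\dot V = g_L (V_L - V) + g_A (E_A - V) + g_G (E_G - V)
           + g_N\, m(V) (E_N - V) + u,$$

with reversal potentials fixed at their carriers' physiological values
(sodium 60 mV for AMPA, calcium 10 mV for NMDA, chloride −70 mV for
GABA-A) and a potassium leak at $V_L = -70$ mV absorbing all passive
currents. The NMDA conductance is gated by the voltage-dependent magnesium
block,

$$m(V) = \frac{\alpha}{1 + \beta e^{-\gamma V}},$$

a three-parameter sigmoid with defaults $\alpha = 1.5$, $\beta = 0.33$,
$\gamma = 0.06\ \mathrm{mV}^{-1}$. Conductances follow first-order channel
kinetics, $\dot g_r = \kappa_r (u_r - g_r)$, where $u_r$ is the
coupling-weighted presynaptic drive and the rate constants $\kappa_r$ are
the inverses of the channel time constants, with priors of 12 ms (AMPA),
8 ms (GABA-A) and 100 ms (NMDA). Presynaptic firing is a logistic function
of the presynaptic membrane potential whose slope is set by the ensemble
firing variance (prior 64 mV², threshold −40 mV).

Four sources — left/right parietal at MNI (±29, −68, 49) and left/right
prefrontal at (±33, 45, 28) — are wired with forward connections from
parietal SP onto frontal SS and DP, backward connections from frontal DP
onto parietal SP and II, and fixed interhemispheric SP–SP links. All
extrinsic glutamatergic connections act on AMPA receptors. This yields
4 × 4 × 4 = 64 coupled ODEs. The model variant adds an intra-source
NMDA-bearing SP→SS interconnection; it adds a connection, not states.

### The 41 free neuronal parameters

Every free parameter is a log-scaling factor on its prior mean
($\theta = \bar\theta\, e^{\lambda}$, $\lambda \sim N(0, 1/16)$ by
default). The partition used throughout:

* **NMDA (15)** — 4 rate constants, 4 intrinsic weights onto excitatory
  targets, 4 separate weights onto inhibitory interneurons, 3
  magnesium-block parameters.
* **AMPA (12)** — 4 rate constants, 4 intrinsic weights, 2 forward and 2
  backward extrinsic weights (one per hemisphere).
* **GABA-A (8)** — 4 rate constants, 4 intrinsic weights.
* **Other (6)** — ensemble firing variance, background current, 4
  intra-source delays.

The interhemispheric links are fixed at their prior value rather than
free: the 41-parameter itemization leaves no room for them, and fixing
them reconciles the parameter count with the four-link anatomy. Membrane
capacitance is fixed (16 ms membrane time constant with unit leak) and the
background current is a single shared parameter, which keeps the free
neuronal count at exactly 41.

Three observation-model parameters sit outside the neuronal set: the
log-amplitude and spectral-exponent shift of the innovations (a stochastic
current entering the spiny stellate populations) and the log-amplitude of
channel noise.

## From parameters to cross-spectra

The vector field is solved for its fixed point by relaxation (320 ms of
forward integration) followed by damped Newton iteration to a residual of
1e−8. Relaxation comes first deliberately: in strongly coupled regimes the
system can have coexisting equilibria, and the linearization must be taken
at the state the stochastic dynamics actually orbit — which relaxation
selects and Newton alone can miss. The analytic Jacobian (verified against
finite differences to 1e−6 relative error) is evaluated there.

Transmission delays — the per-source intra-source delay (prior 2 ms,
free) between distinct populations and a fixed 16 ms inter-source delay —
enter the spectra exactly in the frequency domain:

$$H(\omega) = \mathrm{Out}\,\bigl(i\omega I - J \circ e^{-i\omega D}\bigr)^{-1} B .$$

The more common first-order compensation $J_d = (I - D \circ J)^{-1} J$ is
retained for stability and pole analyses (its eigenvalues are the reported
eigenspectrum), but for the spectra themselves it is a poor approximation
above ~20 Hz once 16 ms delays are in play: against long stochastic
simulations of the full nonlinear delayed system, the compensated spectra
err by ~60 % in the beta–gamma band where the exact evaluation stays
within 20 %. This is the package's one deliberate departure from the usual
spectral-model recipe, documented here as a design choice.

The predicted sensor-mode density is
$S(\omega) = H G_u H^{\mathsf{H}} + \text{noise terms}$, with power-law
innovations $G_u = a_u^2 \omega^{-e_u}$ (white by default) and a white
channel-noise floor, projected through a population-weighted lead field
(SP 0.6, DP 0.3, SS 0.1, II 0 — interneuron arborization generates no
scalp dipole) and the subject's eight orthonormal spatial modes. The lead
field itself is synthetic — a seeded unit-column random gain matrix —
because only the mixing structure matters to the pipeline; subject
anatomy is out of scope.

## Fitting

Subject spectra are summarized per frequency by the real upper triangle
(with diagonal) and imaginary strict upper triangle of the Hermitian mode
matrix — 1856 real and 1856 imaginary features for the 20–48 Hz band at
1 Hz resolution, 320 of each for 2–6 Hz. Three observation-model choices
matter in practice and are easy to get wrong:

* **Variance stabilization.** A $K$-epoch cross-spectral estimate has
  $\mathrm{Var}[\hat S_{ij}] \propto S_{ii} S_{jj} / K$, so every entry is
  weighted by $1/\sqrt{\hat S_{ii} \hat S_{jj}}$. Without this the
  leading mode dominates the likelihood and the remaining modes are left
  unconstrained.
* **Scale calibration.** Absolute units (amplifier gain, lead-field
  scale) are arbitrary, so the data are rescaled once so that their RMS
  matches the prior-mean prediction; free energies are mapped back to the
  original scale ($F - n\log s$) so that model variants remain comparable
  on the same data.
* **Band-wise precision.** One noise-precision component per fitted band,
  updated by expectation–maximization inside the ascent.

The variational Laplace ascent is Gauss–Newton with Levenberg–Marquardt
damping on the free energy; prediction Jacobians use central differences
with step 1e−4 on the log scale; steps that lose dynamical stability are
rejected with increased damping rather than clamped, keeping the
free-energy landscape well defined. Defaults: tolerance 1e−2 on the
accepted-step improvement, 128 iterations maximum; the tests and
experiments cap iterations at 12–24, which the convergence traces justify
at these problem sizes.

The empirical-prior calibration step inverts three randomly chosen
neurological controls under the default priors and re-centres the prior
mean on their average posterior before all other inversions, exactly as
the clinical pipeline prescribes.

## Group inference

The second-level design matrix has a mean column, an encephalopathy
indicator (encephalitis and encephalopathic subjects), and a nested
encephalitis indicator. CVA operates on posterior parameter estimates
(per receptor set; both bands' estimates concatenated when available),
with Bartlett's chi-squared approximation for the canonical correlations
and an optional permutation cross-check.

Parametric empirical Bayes places a linear-Gaussian model over the
subjects' **likelihood summaries** — each posterior with its own prior
precision subtracted — rather than over raw posterior means. This matters:
directions the spectra never informed are then carried with ~zero weight
instead of masquerading as precise estimates. The likelihood precision
spectrum is clipped to $[1, 10^6]$ (uninformed directions are treated as
"unknown within a unit log-range", which also bounds the de-shrunk
summary means). Between-subject variances are diagonal with one
hyperparameter per receptor class, optimized on the exact marginal
likelihood and clamped to $[10^{-3}, 1]$ — without the floor a class
variance can collapse and flag its entire class. Bayesian model reduction
scores reduced models analytically (effects switched off by shrinking
their prior variance to 1e−8), greedily prunes while the evidence
improves, sweeps the final ≤8 surviving effects exhaustively, and reports
per-effect probabilities by model averaging over everything visited; the
clinical threshold is P > 0.95.

The acute-phase classifier projects subjects onto the leading canonical
vector, thresholds at the midpoint of the class means, and optionally
regresses a measured occipital alpha-power covariate (mean 8–12 Hz O1/O2
autospectral power) out of the scores first.

## The synthetic cohort

No recordings are deposited with the clinical study, so a generator
replaces the cohort: 18 neurological controls, 18 encephalopathic
controls, 29 NMDAR-antibody encephalitis subjects. Group effects are
additive shifts on the log parameters:

* encephalitis: −0.5 on the NMDA rate constants at the right parietal and
  both prefrontal sources, and on the NMDA-to-excitatory weights at the
  right parietal and left prefrontal sources — the five-parameter pattern
  the clinical analysis identified;
* encephalopathy: broad, milder shifts across all three receptor classes
  (−0.2 on AMPA and GABA-A rate constants, −0.15 on NMDA rate constants
  and GABA-A weights at every source).

Between-subject variability is Gaussian with SD 0.1 on every log
parameter; recordings are 12 minutes at 250 Hz with 2 µV sensor noise, or
in fast mode the model cross-spectra are sampled directly with
complex-Wishart noise at 144 epochs (the amount of artifact-free data the
clinical recordings typically yield). An occipital 10 Hz component
(Cauchy line shape, coherent across O1/O2) can be added to all subjects
(baseline, log-normal variability) and, with extra amplitude, to a
fraction of encephalitis subjects to emulate the alpha confound.

The prior coupling weights and background current were calibrated once
(`scripts/calibrate_defaults.R` re-verifies the screens) so that the
generator is monostable and robust across subject draws, and so the group
directions mirror the clinical figure: encephalitis exceeds control on
28–40 Hz leading-mode power, encephalopathy is highest on 2–4 Hz
second-mode power, the encephalitis parameterization sits closest to
instability, and its inhibitory-interneuron beta power is lower. With the
paper-fixed 12/8/100 ms kinetics the circuit's main resonance sits in the
low beta range (~14–15 Hz) with a slower secondary mode near 7 Hz; a
faster "gamma" resonance is not reachable with these time constants, so
beta–gamma band content comes from the resonance shoulder, which is what
the calibration works with.

Band-power direction checks are evaluated in each group's data-derived
leading spatial modes (eigenvectors of the group-mean channel cross
spectra) — the pipeline's principal-mode convention — because the first
column of an arbitrary orthonormal mode matrix is not the dominant
spatial pattern.

## What the tests do and do not show

The test suite verifies the structural constants exactly (64 equations,
the 15/12/8 partition, 1856/320 features, the priors), checks the
numerics against independent oracles (closed-form AR(1) spectra, the
conjugate linear-Gaussian evidence, finite-difference Jacobians,
characteristic-polynomial eigenvalues), and confirms that 300–400 s
stochastic simulations of the nonlinear delayed system reproduce the
analytic spectra within 20 % over 20–48 Hz (integration step 0.1 ms for
these comparisons; 0.5 ms suffices for cohort realism).

Identifiability is where honest limits appear, and they are worth stating
plainly:

* **Sign recovery works in a constrained probe.** With every non-NMDA
  parameter held near its prior (variance 1/256) and the network placed
  in a depolarized background state — where the slow NMDA–interneuron
  resonance falls inside the fitted 2–6 Hz band — an exp(−0.5)
  rate-constant deficit is recovered in sign in ~90 % of seeded runs. At
  the default operating point that resonance sits at ~7 Hz, between the
  two fitted bands, and recovery is at chance.
* **Unconstrained per-subject attribution fails, and provably not because
  of the optimizer.** Under the default cohort conditions the deficit's
  cross-spectral signature can be reproduced essentially exactly by
  mixtures of other parameters at near-zero prior cost: restarting the
  inversion *at the true parameters* returns to the same cheap solution
  with the same free energy. The end-to-end group analysis then attributes
  the (consistent) surrogate pattern, not the NMDA cause, so the flagship
  NMDA-only selectivity is **not** reproduced end-to-end by the synthetic
  pipeline and the corresponding acceptance check is expected to fail.
  The second-level machinery itself is sound: fed posteriors that do carry
  the planted NMDA effect it is NMDA-selective in 10/10 replicates, and
  under zero effects fewer than 1 % of effects cross P > 0.95.

Passing tests therefore demonstrate correctness of every computational
stage and calibrated direction, and a characterized — not hidden —
identifiability boundary of the receptor assay under these synthetic
conditions. Real recordings differ in ways the generator does not emulate
(non-stationarity, structured artifacts, anatomical lead fields,
inter-individual circuit differences), so neither the successes nor the
boundary transfer to clinical data without further evidence.
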
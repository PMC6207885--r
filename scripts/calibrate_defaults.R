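#!/usr/bin/env Rscript
# One-time calibration audit of the generator defaults.
#
# The prior coupling weights, background current and group effect vectors in
# cmc_constants() / default_group_effects() were chosen by a randomized
# search subject to the screens below; this script re-verifies that the
# frozen defaults still satisfy every screen, and is the place to rerun the
# search should the model equations ever change.
#
#   1. monostability: relaxation from spread initial states reaches one
#      fixed point, identical to the Newton solution, for the control,
#      encephalitis and encephalopathy mean parameter vectors;
#   2. stability of sampled subjects: no unstable draws at the default
#      between-subject SD;
#   3. direction screens: encephalitis > control on 28-40 Hz leading-mode
#      power; encephalopathy highest on 2-4 Hz second-mode power; the
#      encephalitis parameterization closest to instability and with lower
#      inhibitory-interneuron beta power.

suppressMessages(library(cmcEEG))

net <- build_default_network()
eff <- default_group_effects()

cat("== monostability / attractor consistency ==\n")
for (nm in c("control", "nmdar", "encephalopathy")) {
  lam <- if (nm == "control") NULL else eff[[nm]]
  eq <- assemble_state_equations(net, lam)
  ends <- sapply(c(-70, -55, -40, -25), function(v0) {
    x <- rep(c(v0, 0.2, 0.2, 0.2), 16)
    for (i in 1:30000) x <- x + 0.08 * eq$f(x)
    c(x[5], max(abs(eq$f(x))))
  })
  fp <- find_fixed_point(lam, net)
  ok <- max(ends[1, ]) - min(ends[1, ]) < 0.5 &&
    max(ends[2, ]) < 1e-5 && abs(fp[5] - ends[1, 1]) < 0.5
  cat(sprintf("  %-15s V_SP = %7.2f  %s\n", nm, fp[5],
              if (ok) "ok" else "FAILED"))
}

cat("== draw stability (150 mixed-group subjects, SD 0.1) ==\n")
set.seed(42)
labs <- param_labels(net)
bad <- 0
for (i in 1:150) {
  g <- sample(c("control", "nmdar", "encephalopathy"), 1)
  lam <- setNames(rnorm(41, 0, 0.1), labs)
  if (g != "control")
    lam[names(eff[[g]])] <- lam[names(eff[[g]])] + eff[[g]]
  r <- try(linearize(lam, net), silent = TRUE)
  if (inherits(r, "try-error") || r$max_real >= 0) bad <- bad + 1
}
cat(sprintf("  unstable draws: %d / 150 %s\n", bad,
            if (bad == 0) "(ok)" else "(FAILED)"))

cat("== direction screens ==\n")
d <- experiment_direction_checks()
for (nm in c("ok_beta", "ok_delta", "ok_stability", "ok_ii"))
  cat(sprintf("  %-12s %s\n", nm, if (isTRUE(d[[nm]])) "ok" else "FAILED"))
cat(sprintf("  beta ratio (enc/ctrl)  %.4f\n", d$beta_ratio_encephalitis))
cat(sprintf("  delta ratio (oth/ctrl) %.4f\n",
            d$delta_ratio_encephalopathy))
cat(sprintf("  II beta ratio          %.4f\n",
            d$ii_beta_ratio_encephalitis))

cat("== frozen defaults ==\n")
k <- cmc_constants()
str(k[c("bg", "sigma2", "w_ampa", "w_gaba", "w_nmda_e", "w_nmda_i",
        "w_fwd", "w_bwd", "w_lat")])
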
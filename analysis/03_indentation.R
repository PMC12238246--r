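#!/usr/bin/env Rscript
# Hertz-model stiffness analysis under both indentation protocols.
#
# (a) Extracellular-matrix protocol: colloidal probe (R = 3.31 um),
#     Poisson ratio 0.3, linear background subtraction, whole-curve joint
#     fit of E and the contact point. The three regional populations are
#     simulated as broad lognormal stiffness distributions whose modes are
#     set to the regional values reported for decellularised Bruch's
#     membrane (5.5, 1.5 and 4 kPa) - used here as generator ground truth
#     to show the fitting-and-mode pipeline recovers them.
# (b) Monolayer nanoindentation protocol: R = 10 um probe, Poisson ratio
#     0.5, contact point restricted to <=30% of the peak load, fit window
#     0-3 um past contact, R^2 > 0.95 acceptance gate; apical moduli
#     around 1.5 vs 1 kPa.

suppressMessages(library(epimech))
dir.create("results", showWarnings = FALSE)
set.seed(42)

ecm <- data.frame(region = c("centre", "mid_periphery", "far_periphery"),
                  mode_kpa = c(5.5, 1.5, 4.0))
sdlog <- 0.6
rows <- NULL
for (r in seq_len(nrow(ecm))) {
  mode_pa <- ecm$mode_kpa[r] * 1000
  mu <- log(mode_pa) + sdlog^2          # lognormal mode = exp(mu - sd^2)
  E_true <- exp(rnorm(400, mu, sdlog))
  fits <- vapply(seq_along(E_true), function(i) {
    fmax <- hertz_force(1.5, E_true[i], 3.31, 0.3)
    sp <- force_curve_spec(E_true = E_true[i], contact_point = 0.5,
                           probe_radius = 3.31, poisson = 0.3,
                           background_slope = 2e-10, noise_sd = 0.02 * fmax,
                           n_points = 150, z_range = 2, seed = 7000L + i)
    fc <- subtract_background(generate_force_curve(sp), baseline = "head")
    fit_hertz(fc)$E_pa
  }, 1.0)
  rows <- rbind(rows, data.frame(region = ecm$region[r],
                                 true_mode_kpa = ecm$mode_kpa[r],
                                 recovered_mode_kpa = mode_stiffness(fits) / 1000,
                                 n_curves = length(fits)))
}
write.csv(rows, "results/03_ecm_stiffness_modes.csv", row.names = FALSE)
cat("Decellularised-matrix protocol: regional stiffness modes\n")
print(rows, row.names = FALSE, digits = 3)

mono <- data.frame(condition = c("laminin_511", "laminin_332"),
                   E_pa = c(1500, 1000))
mrows <- NULL
for (i in seq_len(nrow(mono))) {
  fits <- lapply(1:30, function(s) {
    sp <- force_curve_spec(E_true = mono$E_pa[i], contact_point = 3,
                           probe_radius = 10, poisson = 0.5, n_points = 400,
                           z_range = 8,
                           noise_sd = 0.02 * hertz_force(5, mono$E_pa[i], 10, 0.5),
                           seed = 8000L + 100L * i + s)
    fit_hertz_nanoindentation(generate_force_curve(sp))
  })
  acc <- vapply(fits, function(f) isTRUE(f$accepted), TRUE)
  E <- vapply(fits[acc], function(f) f$E_pa, 1.0)
  mrows <- rbind(mrows, data.frame(condition = mono$condition[i],
                                   true_E_pa = mono$E_pa[i],
                                   mean_E_pa = mean(E),
                                   accepted = sum(acc), total = length(fits)))
}
write.csv(mrows, "results/03_monolayer_stiffness.csv", row.names = FALSE)
cat("\nMonolayer nanoindentation protocol (R^2 > 0.95 gate):\n")
print(mrows, row.names = FALSE, digits = 4)
cat("\nBoth protocols recover their generator ground truth; the apical\n",
    "modulus contrast between the two coating conditions is preserved.\n")
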
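#!/usr/bin/env Rscript
# Functional image quantification: particle internalization, proliferation
# and radial matrix-intensity gradients.
#
# Internalization: stacks with known internalized fractions emulate the
# contrast between relaxed (high-efficiency, ~70%) and contractile
# (low-efficiency, ~50% of maximum and below) monolayers. Proliferation:
# nuclear masks with a known positive fraction, restricted to a central
# region of interest. Matrix gradient: per-eye intensity profiles decaying
# with distance from the optic nerve head, normalized to each eye's
# maximum and binned into the three anatomical regions.

suppressMessages(library(epimech))
dir.create("results", showWarnings = FALSE)

conds <- data.frame(condition = c("relaxed", "control", "contractile"),
                    fraction = c(0.7, 0.5, 0.35))
prow <- NULL
for (i in seq_len(nrow(conds))) {
  effs <- vapply(1:4, function(s) {
    st <- generate_pos_stack(pos_spec(n_particles = 20,
                                      fraction_internalized = conds$fraction[i],
                                      seed = 10L * i + s))
    phagocytosis_efficiency(st)$efficiency
  }, 1.0)
  prow <- rbind(prow, data.frame(condition = conds$condition[i],
                                 truth = conds$fraction[i],
                                 mean_efficiency = mean(effs), n_fields = 4L))
}
write.csv(prow, "results/05_phagocytosis.csv", row.names = FALSE)
cat("Phagocytosis efficiency (4 fields per condition):\n")
print(prow, row.names = FALSE, digits = 3)

# proliferation: 6 of 90 nuclei EdU-positive inside the central ROI
set.seed(3)
dapi <- matrix(0L, 200, 200); edu <- matrix(0L, 200, 200)
centers <- expand.grid(r = seq(12, 190, 14), c = seq(12, 190, 14))
centers <- centers[seq_len(min(nrow(centers), 150)), ]
for (i in seq_len(nrow(centers)))
  dapi[centers$r[i] + (-2:2), centers$c[i] + (-2:2)] <- 1L
pos_idx <- sample(nrow(centers), 8)
for (i in pos_idx) edu[centers$r[i], centers$c[i]] <- 1L
roi <- matrix(FALSE, 200, 200)
rr <- matrix(rep(1:200, 200), 200); cc <- t(rr)
roi[(rr - 100)^2 + (cc - 100)^2 <= 80^2] <- TRUE
ratio <- proliferation_ratio(edu, dapi, roi)
cat(sprintf("\nProliferation ratio in the central ROI: %.3f\n", ratio))
write.csv(data.frame(proliferation_ratio = ratio),
          "results/05_proliferation.csv", row.names = FALSE)

# radial matrix gradient: two eyes, intensity decaying with distance
set.seed(4)
d_um <- rep(seq(350, 2950, by = 100), 2)
eye <- rep(c("eye1", "eye2"), each = length(d_um) / 2)
gain <- ifelse(eye == "eye1", 900, 1400)  # different detector gains
intensity <- gain * exp(-d_um / 1500) * (1 + rnorm(length(d_um), 0, 0.05))
norm <- normalize_per_eye(intensity, eye)
region <- region_of_distance(d_um)
tab <- aggregate(norm, list(region = region), mean)
names(tab)[2] <- "mean_normalized_intensity"
write.csv(data.frame(eye, d_um, intensity, norm, region),
          "results/05_ecm_profile.csv", row.names = FALSE)
write.csv(tab, "results/05_ecm_regions.csv", row.names = FALSE)
cat("\nPer-eye-normalized matrix intensity by region:\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nNormalization removes the between-eye gain difference and the\n",
    "binned means fall monotonically from centre to far periphery.\n")
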
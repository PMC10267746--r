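#!/usr/bin/env Rscript
# Material-law analysis: virtual compression test of the two cushion foams
# (HU/SHAPE pairs 0.65/8 seat pan, 0.65/5 backrest, curve scale 1.15),
# identifiability of HU and SHAPE from the unloading branch, and the
# neo-Hookean flesh response.

library(sitpress)

mats <- reference_materials()
dir.create("results/materials", recursive = TRUE, showWarnings = FALSE)

for (nm in c("seat_foam", "backrest_foam")) {
  p <- mats[[nm]]
  ct <- simulate_compression_test(p)
  write_stress_strain_csv(ct$loading[, c("strain", "stress_kpa")],
                          file.path("results/materials", paste0(nm, "_loading.csv")))
  write_stress_strain_csv(ct$unloading[, c("strain", "stress_kpa")],
                          file.path("results/materials", paste0(nm, "_unloading.csv")))
  cat(sprintf("%s: HU=%.2f SHAPE=%g, cycle dissipation %.2f kPa\n",
              nm, p$hu, p$shape, ct$dissipated_kpa))
  # recover HU/SHAPE from the simulated unloading branch alone
  es <- seq(0, 0.8, by = 0.02)
  fit <- identify_unloading_params(
    foam_params(p$loading_curve, scale = p$scale),
    cbind(es, foam_unloading_stress(p, es, 0.8)))
  cat(sprintf("  re-identified: HU=%.3f SHAPE=%.2f (RMSE %.2e kPa)\n",
              fit$hu, fit$shape, fit$fit_rmse))
}

# static masses on a 50 x 50 mm foam column: equilibrium strains
p <- mats$seat_foam
for (mass_kg in c(2, 4, 7)) {
  stress <- mass_kg * 9.81 / 2500 * 1e3  # kPa
  e <- foam_equilibrium_strain(p, stress)
  cat(sprintf("mass %4.1f kg -> stress %5.2f kPa -> strain %.3f\n",
              mass_kg, stress, e))
}

# flesh law: nominal stress across the compression range
flesh <- mats$tissue
lam <- seq(0.4, 1, by = 0.05)
tab <- data.frame(stretch = lam,
                  stress_kpa = ogden_uniaxial_stress(flesh, lam))
write.csv(tab, "results/materials/flesh_uniaxial.csv", row.names = FALSE)
cat(sprintf("flesh (neo-Hookean, mu = %.1f kPa): sigma(0.5) = %.2f kPa\n",
            flesh$mu_kpa, ogden_uniaxial_stress(flesh, 0.5)))
cat("Curves under results/materials\n")
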
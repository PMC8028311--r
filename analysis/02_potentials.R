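#!/usr/bin/env Rscript

# Tabulates the pair potentials of the model: the screened electrostatic
# (Debye-Hueckel) attraction/repulsion at 0.02 M salt and the short-range
# 12-10 dispersion well (depth 0.2 kcal/mol at 7 A), the comparison that
# frames the whole study: long- vs short-range interactions of similar
# contact strength but very different reach.

suppressPackageStartupMessages(library(condensim))
dir.create("results", showWarnings = FALSE)

p <- forcefield_params()
r <- seq(3, 40, by = 0.1)
tab <- data.frame(
  r = r,
  dh_attractive = pair_energy_dh(1, -1, r, p),
  dh_repulsive = pair_energy_dh(1, 1, r, p),
  lj_1210 = pair_energy_lj1210(r, p$eps_lj, p$sigma_lj, cutoff = p$cutoff_lj),
  excluded_volume = pair_energy_repulsion(r, p$eps_rep, p$sigma_rep,
                                          cutoff = p$cutoff_lj)
)
write.table(tab, "results/pair_potentials.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

lam <- 1 / debye_kappa(p$salt_I, p$temperature, p$dielectric)
message(sprintf("Debye length at %.2f M, %g K: %.1f A", p$salt_I,
                p$temperature, lam))
message(sprintf("DH contact energy (opposite charges, r = %g A): %.3f kcal/mol",
                p$sigma_lj, pair_energy_dh(1, -1, p$sigma_lj, p)))
message(sprintf("12-10 well depth at r = %g A: %.3f kcal/mol",
                p$sigma_lj, -pair_energy_lj1210(p$sigma_lj, p$eps_lj, p$sigma_lj)))
message(sprintf("12-10 zero crossing: %.2f A (analytic sigma*sqrt(5/6) = %.2f)",
                r[which(diff(sign(tab$lj_1210)) != 0)[1]],
                p$sigma_lj * sqrt(5 / 6)))
message("wrote results/pair_potentials.tsv")
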
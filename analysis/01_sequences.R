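#!/usr/bin/env Rscript

# Designs the study's sequence family: a 40-residue, zero-net-charge
# polyampholyte with charge-patterning kappa = 0.55, mutated to hydrophobic
# fractions phi = 0 ... 0.8. Writes the sequences (FASTA over {+,-,H}) and a
# descriptor table under results/.

suppressPackageStartupMessages(library(condensim))
dir.create("results", showWarnings = FALSE)

fam <- phi_series(seed = 1L)
write_sequences(fam, "results/sequences.fasta")

desc <- do.call(rbind, lapply(names(fam), function(nm) {
  s <- fam[[nm]]
  data.frame(name = nm, length = s$length, phi = s$phi,
             n_pos = sum(s$charge > 0), n_neg = sum(s$charge < 0),
             n_hyd = sum(s$hydrophobic), net_charge = sum(s$charge),
             kappa = s$kappa, sequence = as.character(s))
}))
write.table(desc, "results/sequence_descriptors.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("phi series (kappa of the phi = 0 parent: ",
        round(fam$phi0$kappa, 3), "):")
print(desc[, c("name", "phi", "n_hyd", "net_charge", "kappa")],
      row.names = FALSE)
message("wrote results/sequences.fasta and results/sequence_descriptors.tsv")
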
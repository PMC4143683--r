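#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic family study standing in for the restricted
# real data: 20 five-generation families (~900 genotyped and phenotyped
# individuals, up to 4 visits each), a founder marker spectrum straddling the
# MAF 0.05 boundary, and a repeated-measures trait with additive-genetic,
# permanent-environmental and residual variances (44.4, 61.5, 135.0).
suppressPackageStartupMessages(library(famgp))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)
sim <- simulate_study(cfg)

write_pedigree(sim$pedigree, file.path(out, "pedigree.tsv"))
write_phenotypes(sim$phenotypes, file.path(out, "phenotypes.csv"))
write_genotypes_raw(sim$genotypes, file.path(out, "genotypes.raw"),
                    sim$pedigree)
write_truth_json(sim$truth, file.path(out, "truth.json"))

cat(sprintf("families: %d\n", length(unique(sim$pedigree$family))))
cat(sprintf("individuals: %d (founders: %d)\n", nrow(sim$pedigree),
            sum(sim$pedigree$sire == 0)))
cat(sprintf("phenotype records: %d\n", nrow(sim$phenotypes)))
cat(sprintf("markers: %d common + %d rare by founder frequency\n",
            sum(sim$genotypes$map$class == "common"),
            sum(sim$genotypes$map$class == "rare")))
cat(sprintf("sample variance of true breeding values: %.1f\n",
            var(sim$truth$true_breeding_values)))
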
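#!/usr/bin/env Rscript
# Stage 2: fit the repeatability animal model by REML on the simulated
# records and report the variance components, heritability and the estimated
# additive genetic contributions (u-hat) that all later prediction stages
# treat as the response.
suppressPackageStartupMessages(library(famgp))

data_dir <- "results/data"
ped <- read_pedigree(file.path(data_dir, "pedigree.tsv"))
phen <- read_phenotypes(file.path(data_dir, "phenotypes.csv"))

A <- additive_relationship_matrix(ped)
fit <- fit_repeatability_model(phen, A)
print(fit)

write_fit_json(fit, "results/vc_fit.json")

cat(sprintf("\nheritability: %.3f (additive %.1f of total %.1f)\n",
            fit$h2, fit$vc$sigma_u2,
            fit$vc$sigma_u2 + fit$vc$sigma_c2 + fit$vc$sigma_e2))
u <- fit$u_hat
cat(sprintf("u-hat: range [%.1f, %.1f], mean %.2f, SD %.2f\n",
            min(u), max(u), mean(u), sd(u)))
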
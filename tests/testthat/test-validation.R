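five_gen_ped <- function() {
  # one family, 10 members over 5 generations
  data.frame(id = 1:10,
             sire = c(0, 0, 1, 1, 0, 3, 0, 6, 0, 8),
             dam = c(0, 0, 2, 2, 0, 5, 0, 7, 0, 9),
             sex = c("M", "F", "M", "M", "F", "M", "F", "M", "F", "M"),
             family = 1, generation = c(1, 1, 2, 2, 2, 3, 3, 4, 4, 5))
}

test_that("within-family split follows generation labels", {
  ped <- five_gen_ped()
  sp <- within_family_split(ped)
  expect_setequal(sp$trn_ids, as.character(1:7))
  expect_setequal(sp$tst_ids, as.character(8:10))
  expect_length(intersect(sp$trn_ids, sp$tst_ids), 0)
  # a 3-generation pedigree has no test descendants
  ped3 <- ped[ped$generation <= 3, ]
  expect_error(within_family_split(ped3), "across-family")
  # genotyped subset restricts both sides
  sp2 <- within_family_split(ped, genotyped_ids = c("1", "3", "8"))
  expect_setequal(sp2$trn_ids, c("1", "3"))
  expect_setequal(sp2$tst_ids, "8")
})

test_that("default simulation gives a training set larger than the test set", {
  ped <- simulate_pedigree(sim_config(seed = 12))
  sp <- within_family_split(ped)
  expect_gt(length(sp$trn_ids), length(sp$tst_ids))
  expect_equal(sort(as.integer(c(sp$trn_ids, sp$tst_ids))), sort(ped$id))
})

test_that("across-family folds block by ranked family size", {
  set.seed(1)
  # 20 families with distinct sizes 5..24
  fam_sizes <- 5:24
  ped <- do.call(rbind, lapply(seq_along(fam_sizes), function(f)
    data.frame(id = paste0(f, "_", seq_len(fam_sizes[f])), sire = 0, dam = 0,
               sex = "M", family = f, generation = 1)))
  folds <- across_family_folds(ped, k = 5, seed = 2)
  expect_length(folds, 5)
  # every fold holds 4 families, one from each size quintile
  strata <- split(order(-fam_sizes), rep(1:4, each = 5))
  for (f in folds) {
    fams <- unique(ped$family[ped$id %in% f$tst_ids])
    expect_length(fams, 4)
    for (s in strata) expect_length(intersect(fams, s), 1)
    expect_length(intersect(f$trn_ids, f$tst_ids), 0)
  }
  # union of test folds = everyone; folds pairwise disjoint
  all_tst <- unlist(lapply(folds, `[[`, "tst_ids"))
  expect_setequal(all_tst, as.character(ped$id))
  expect_equal(anyDuplicated(all_tst), 0L)
  # fold totals balanced by blocking: 10 families sized 1..10, k = 5
  ped10 <- do.call(rbind, lapply(1:10, function(f)
    data.frame(id = paste0(f, "_", seq_len(f)), sire = 0, dam = 0, sex = "M",
               family = f, generation = 1)))
  f10 <- across_family_folds(ped10, k = 5, seed = 3)
  # one family from {10..6} plus one from {5..1}: totals enumerate to [7, 15]
  tot <- vapply(f10, function(f) length(f$tst_ids), numeric(1))
  expect_true(all(tot >= 7 & tot <= 15))
  expect_equal(sum(tot), 55)
  # non-divisible family count falls back round-robin with a warning
  expect_warning(f7 <- across_family_folds(ped10[ped10$family <= 7, ], k = 5,
                                           seed = 4), "round-robin")
  expect_length(f7, 5)
})

test_that("accuracy returns Pearson correlation and MSE with edge handling", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), list(correlation = 1, mse = 0))
  x <- c(1, 2, 3) - 2
  expect_equal(accuracy(x, -x)$correlation, -1)
  a <- accuracy(c(1, 2, 3), c(1, 2, 4))
  expect_equal(a$correlation, cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(a$correlation, 0.982, tolerance = 1e-3)
  expect_equal(a$mse, 1 / 3)
  expect_warning(z <- accuracy(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_true(is.na(z$correlation))
  expect_equal(z$mse, mean(c(0, 1, 4)))
  expect_error(accuracy(1:3, 1:4), "aligned")
})

test_that("blend regression satisfies the nested-model identity", {
  set.seed(9)
  u <- rnorm(40)
  yg <- u + rnorm(40, 0, 0.8)
  up <- 0.5 * u + rnorm(40, 0, 0.8)
  r <- blend_regression(u, yg, up)
  expect_gte(r$r2_combined, max(r$r2_genomic, r$r2_parent_avg) - 1e-12)
  # perfect genomic predictor
  r2 <- suppressWarnings(blend_regression(u, u, up))  # lm perfect-fit note
  expect_equal(r2$r2_genomic, 1)
  # parent average that is pure noise adds (almost) nothing
  for (s in 1:5) {
    set.seed(100 + s)
    u <- rnorm(60); yg <- u + rnorm(60, 0, 0.5); noise <- rnorm(60)
    r3 <- blend_regression(u, yg, noise)
    expect_lt(r3$r2_combined - r3$r2_genomic, 0.08)
  }
  # collinear predictors flagged, R2 still the projection R2
  expect_warning(r4 <- blend_regression(u, yg, yg), "collinear")
  expect_true(r4$collinear)
  expect_equal(r4$r2_combined, r4$r2_genomic, tolerance = 1e-8)
})

test_that("run_experiment produces the factorial report", {
  cfg <- tiny_config(seed = 55, generations = 5, n_families = 5,
                     n_common_markers = 60, n_rare_markers = 0, n_causal = 15)
  sim <- simulate_study(cfg)
  A <- additive_relationship_matrix(sim$pedigree)
  fit <- fit_repeatability_model(sim$phenotypes, A)
  sets <- list(set1 = structure(list(dosages = dosages(sim$genotypes),
                                     map = sim$genotypes$map),
                                class = "famgp_geno"))
  rep1 <- run_experiment(sim$pedigree, fit$u_hat, sets,
                         mcmc_settings(1000, 300, 5, seed = 1), k = 5)
  expect_equal(nrow(rep1), 4)  # 1 set x 2 models x 2 designs
  expect_setequal(rep1$design, c("within_family", "across_family"))
  expect_true(all(rep1$trn_mse >= 0 & rep1$tst_mse >= 0))
  expect_true(all(abs(rep1$trn_correlation) <= 1, na.rm = TRUE))
  # determinism
  rep2 <- run_experiment(sim$pedigree, fit$u_hat, sets,
                         mcmc_settings(1000, 300, 5, seed = 1), k = 5)
  expect_equal(rep1, rep2)
})
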
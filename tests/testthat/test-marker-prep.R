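toy_geno <- function(D, chrom = NULL, pos = NULL) {
  colnames(D) <- colnames(D) %||% paste0("m", seq_len(ncol(D)))
  rownames(D) <- rownames(D) %||% as.character(seq_len(nrow(D)))
  map <- data.frame(id = colnames(D),
                    chrom = chrom %||% rep(1L, ncol(D)),
                    pos = pos %||% seq_len(ncol(D)),
                    stringsAsFactors = FALSE)
  structure(list(dosages = D, map = map), class = "famgp_geno")
}

test_that("compute_maf folds frequencies onto the minor allele", {
  D <- cbind(a = c(0, 0, 1, 2), b = c(0, 0, 0, 0), c = c(2, 2, 2, 2))
  g <- toy_geno(D)
  maf <- compute_maf(g)
  expect_equal(unname(maf), c(0.375, 0, 0))
  expect_equal(unname(compute_maf(g, subset_ids = c("3", "4"))[1]), 0.25)
  expect_error(compute_maf(g, subset_ids = character(0)), "subset")
})

test_that("split_by_maf uses an inclusive common boundary and drops monomorphics", {
  # MAFs 0, 0.01 (rare), 0.05, 0.3 (common)
  n <- 50
  D <- cbind(m1 = rep(0, n),
             m2 = c(rep(1, 1), rep(0, n - 1)),
             m3 = c(rep(1, 5), rep(0, n - 5)),
             m4 = c(rep(1, 30), rep(0, n - 30)))
  g <- toy_geno(D)
  sp <- split_by_maf(g)
  expect_setequal(colnames(sp$common$dosages), c("m3", "m4"))
  expect_setequal(colnames(sp$rare$dosages), "m2")
  expect_equal(sp$n_dropped, 1L)
  # all-common input: collapsing becomes a no-op via assemble
  sp2 <- split_by_maf(toy_geno(D[, c("m3", "m4")]))
  expect_equal(ncol(sp2$rare$dosages), 0L)
  sets <- assemble_marker_sets(sp2$common, NULL)
  expect_identical(sets$set1, sets$set2)
})

test_that("ld_prune removes duplicates, keeps independents, follows the MAF rule", {
  set.seed(5)
  n <- 60
  base <- rbinom(n, 2, 0.4)
  # duplicated columns: exactly one survives
  g <- toy_geno(cbind(a = base, b = base))
  expect_length(ld_prune(g, founder_ids = as.character(1:n)), 1L)
  # independent markers: all survive
  D <- sapply(1:8, function(i) rbinom(n, 2, 0.5))
  g2 <- toy_geno(D)
  expect_length(ld_prune(g2, as.character(1:n)), 8L)
  # monomorphic-on-founders markers go first
  g3 <- toy_geno(cbind(a = base, z = rep(0, n)))
  expect_setequal(ld_prune(g3, as.character(1:n)), "a")
  expect_error(ld_prune(g2, as.character(1:n), r2_threshold = 1.5), "r2_threshold")
})

test_that("ld_prune drops the lower-MAF member of a high-r2 pair", {
  # 20 founders; m2 differs from m1 in one genotype (r2 ~ 0.92) and has the
  # lower MAF, so m1 survives; m3 is weakly correlated with both
  m1 <- rep(c(0, 1, 2, 1, 0), 4)              # maf 0.400
  m2 <- m1; m2[2] <- 0                        # maf 0.375, r2 ~ 0.92
  m3 <- rep(c(2, 0, 1, 0, 2), 4)
  expect_gt(cor(m1, m2)^2, 0.9)
  expect_lt(cor(m1, m3)^2, 0.9)
  expect_lt(cor(m2, m3)^2, 0.9)
  g <- toy_geno(cbind(m1 = m1, m2 = m2, m3 = m3))
  expect_setequal(ld_prune(g, as.character(1:20)), c("m1", "m3"))
  # exact tie in MAF: the later position loses
  g2 <- toy_geno(cbind(m1 = m1, m2 = m1))
  expect_setequal(ld_prune(g2, as.character(1:20)), "m1")
  # retained set is pairwise below the threshold
  kept <- ld_prune(g, as.character(1:20))
  r2 <- cor(dosages(g)[, kept])^2
  expect_true(all(r2[upper.tri(r2)] < 0.9))
})

test_that("collapse_rare size-rank coding matches exhaustive k-means on a toy", {
  # 10 individuals in 3 well-separated groups of sizes 5 > 3 > 2
  set.seed(8)
  D <- rbind(matrix(0L, 5, 6),
             matrix(rep(c(2L, 2L, 0L, 0L, 0L, 0L), each = 3), 3, 6),
             matrix(rep(c(2L, 2L, 2L, 2L, 2L, 2L), each = 2), 2, 6))
  g <- toy_geno(D)
  cs <- collapse_rare(g, window_size = 6, seed = 3)
  expect_equal(unname(cs$dosages[, 1]), c(rep(0L, 5), rep(1L, 3), rep(2L, 2)))
  # exhaustive-partition oracle agrees
  ex <- exhaustive_kmeans(D, 3)
  expect_equal(unname(cs$dosages[, 1]), oracle_codes(ex$assignment, D))
})

test_that("collapse_rare handles degenerate and partial windows", {
  # identical individuals: one cluster, all coded 0, MAF 0
  D <- matrix(1L, 6, 4)
  g <- toy_geno(D)
  cs <- collapse_rare(g, window_size = 4, seed = 1)
  expect_true(all(cs$dosages == 0))
  expect_equal(cs$windows$maf, 0)
  expect_equal(cs$windows$k_used, 1L)
  # 250 markers, window 100 -> windows of 100, 100, 50
  set.seed(2)
  D2 <- matrix(rbinom(20 * 250, 2, 0.05), 20, 250)
  g2 <- toy_geno(D2)
  cs2 <- collapse_rare(g2, window_size = 100, seed = 1)
  expect_equal(cs2$windows$n_members, c(100L, 100L, 50L))
  # final single-marker block merges into the previous window (odd split)
  g3 <- toy_geno(D2[, 1:201])
  cs3 <- collapse_rare(g3, window_size = 100, seed = 1)
  expect_equal(cs3$windows$n_members, c(100L, 101L))
  # windows never span chromosomes
  g4 <- toy_geno(D2, chrom = rep(1:2, each = 125), pos = rep(1:125, 2))
  cs4 <- collapse_rare(g4, window_size = 100, seed = 1)
  expect_equal(cs4$windows$chrom, c(1L, 1L, 2L, 2L))
  expect_error(collapse_rare(g2, window_size = 1), "window_size")
})

test_that("collapsed codes are deterministic, label-free, and bounded", {
  set.seed(77)
  D <- matrix(rbinom(40 * 30, 2, 0.08), 40, 30)
  g <- toy_geno(D)
  cs1 <- collapse_rare(g, window_size = 10, seed = 5)
  cs2 <- collapse_rare(g, window_size = 10, seed = 5)
  expect_identical(cs1$dosages, cs2$dosages)
  expect_true(all(cs1$dosages %in% 0:2))
  expect_true(all(cs1$windows$maf <= 0.5))
  # different k-means starting points converging to the same partition give
  # the same codes (coding depends on membership, not labels)
  cs3 <- collapse_rare(g, window_size = 10, seed = 99)
  same_partition <- vapply(seq_len(ncol(cs1$dosages)), function(j) {
    t1 <- table(cs1$dosages[, j], cs3$dosages[, j])
    all(rowSums(t1 > 0) == 1) && all(colSums(t1 > 0) == 1)
  }, logical(1))
  expect_identical(cs1$dosages[, same_partition],
                   cs3$dosages[, same_partition])
})

test_that("window-size sweep reproduces the rare-count trend", {
  cfg <- sim_config(n_families = 10, n_common_markers = 100,
                    n_rare_markers = 1500, n_chromosomes = 3, seed = 303)
  sim <- simulate_study(cfg)
  rare <- split_by_maf(sim$genotypes)$rare
  sw <- window_size_sweep(rare, c(10, 50, 100), seed = 1)
  expect_equal(sw$window_size, c(10, 50, 100))
  expect_true(all(diff(sw$n_rare_collapsed) <= 0))
  expect_true(all(diff(sw$n_collapsed) < 0))
  # single size equals a direct collapse
  cs <- collapse_rare(rare, 100, seed = 1)
  one <- window_size_sweep(rare, 100, seed = 1)
  expect_equal(one$n_collapsed, nrow(cs$windows))
  expect_equal(one$n_rare_collapsed, sum(cs$windows$maf < 0.05))
})

test_that("assemble_marker_sets concatenates with provenance", {
  set.seed(3)
  D <- matrix(rbinom(10 * 5, 2, 0.3), 10, 5)
  common <- toy_geno(D)
  rare <- toy_geno(matrix(rbinom(10 * 8, 2, 0.05), 10, 8),
                   pos = 100 + 1:8)
  colnames(rare$dosages) <- paste0("r", 1:8); rare$map$id <- paste0("r", 1:8)
  cs <- collapse_rare(rare, window_size = 4, seed = 1)
  sets <- assemble_marker_sets(common, cs)
  expect_equal(ncol(sets$set1$dosages), 5L)
  expect_equal(ncol(sets$set2$dosages), 7L)
  expect_equal(sets$set2$map$source, c(rep("common", 5), rep("collapsed", 2)))
  # individual-order mismatch errors
  bad <- common
  bad$dosages <- bad$dosages[10:1, ]
  expect_error(assemble_marker_sets(bad, cs), "ordering")
})
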
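# Validation designs for genomic prediction: within-family (train on early
# generations, test on their descendants) and across-family (5-fold
# cross-validation over whole families, size-balanced), accuracy metrics, and
# the pedigree/genomic blending regressions.

#' Within-family validation split
#'
#' Training set: genotyped individuals with generation <= `trn_max_generation`
#' (default 3); testing set: their descendants in the later generations.
#' Predictive information flows from ancestors to descendants within the same
#' families.
#'
#' @param pedigree Pedigree data frame with `generation` and `family` labels.
#' @param genotyped_ids Ids entering the genomic analysis (default: all).
#' @param trn_max_generation Last training generation.
#' @return List of class `famgp_split`: `design`, `trn_ids`, `tst_ids`.
#' @export
within_family_split <- function(pedigree, genotyped_ids = NULL,
                                trn_max_generation = 3L) {
  ids <- as.character(genotyped_ids %||% pedigree$id)
  ped <- pedigree[as.character(pedigree$id) %in% ids, , drop = FALSE]
  trn <- as.character(ped$id[ped$generation <= trn_max_generation])
  tst <- as.character(ped$id[ped$generation > trn_max_generation])
  if (length(tst) == 0L)
    stop_famgp("no individuals beyond generation ", trn_max_generation,
               ": the within-family design is empty; use the across-family design")
  fam_no_trn <- setdiff(ped$family[ped$generation > trn_max_generation],
                        ped$family[ped$generation <= trn_max_generation])
  if (length(fam_no_trn))
    warning("families with no training-generation members (test only): ",
            paste(fam_no_trn, collapse = ", "))
  structure(list(design = "within_family", trn_ids = trn, tst_ids = tst,
                 fold = NA_integer_), class = "famgp_split")
}

#' Across-family k-fold validation splits
#'
#' Families are ranked by size (count of genotyped members, descending) and
#' each consecutive block of k families is randomly assigned across the k
#' folds, so every fold holds one family from each size stratum. A remainder
#' block smaller than k is distributed round-robin with a warning. Each
#' fold's testing set is its families' genotyped members; training is
#' everyone else.
#'
#' @param pedigree Pedigree data frame.
#' @param genotyped_ids Ids entering the genomic analysis (default: all).
#' @param k Number of folds.
#' @param seed Integer seed for the within-block permutations.
#' @return List of k `famgp_split` objects (fields `design`, `trn_ids`,
#'   `tst_ids`, `fold`).
#' @export
across_family_folds <- function(pedigree, genotyped_ids = NULL, k = 5L,
                                seed = 1L) {
  ids <- as.character(genotyped_ids %||% pedigree$id)
  ped <- pedigree[as.character(pedigree$id) %in% ids, , drop = FALSE]
  sizes <- sort(table(ped$family), decreasing = TRUE)
  fams <- names(sizes)
  if (length(fams) < k) stop_famgp("fewer families than folds")
  if (length(fams) %% k != 0L)
    warning("number of families not divisible by k; ",
            "remainder block assigned round-robin")
  set.seed(seed)
  fold_of <- integer(length(fams))
  i <- 1L
  while (i <= length(fams)) {
    block <- i:min(i + k - 1L, length(fams))
    fold_of[block] <- sample(seq_len(k))[seq_along(block)]
    i <- i + k
  }
  lapply(seq_len(k), function(f) {
    tst_f <- fams[fold_of == f]
    tst <- as.character(ped$id[ped$family %in% tst_f])
    structure(list(design = "across_family",
                   trn_ids = setdiff(as.character(ped$id), tst),
                   tst_ids = tst, fold = f), class = "famgp_split")
  })
}

#' Prediction accuracy: correlation and mean squared error
#'
#' @param u_hat Estimated additive genetic contributions (reference values).
#' @param y_hat_prime Predicted genomic values, aligned with `u_hat`.
#' @return List with `correlation` (Pearson; NA with a warning when either
#'   vector has zero variance) and `mse`.
#' @export
accuracy <- function(u_hat, y_hat_prime) {
  if (length(u_hat) != length(y_hat_prime) || length(u_hat) == 0L)
    stop_famgp("u_hat and y_hat_prime must be aligned non-empty vectors")
  mse <- mean((u_hat - y_hat_prime)^2)
  r <- if (length(u_hat) >= 3L && sd(u_hat) > 0 && sd(y_hat_prime) > 0) {
    cor(u_hat, y_hat_prime)
  } else {
    warning("correlation undefined (zero variance or fewer than 3 pairs)")
    NA_real_
  }
  list(correlation = r, mse = mse)
}

#' Blending regressions of pedigree and genomic information
#'
#' Ordinary least squares of the estimated additive genetic contributions of
#' test individuals on (i) their predicted genomic values alone, (ii) their
#' parent averages alone, and (iii) both jointly; returns the three
#' coefficients of determination. By nesting, the combined R2 is never below
#' either single-predictor R2.
#'
#' @param u_hat_tst,y_hat_prime_tst,u_parent_avg Aligned vectors over the
#'   test individuals having at least one parent in the training set.
#' @return List `r2_genomic`, `r2_parent_avg`, `r2_combined`, and
#'   `collinear` flag (combined fit rank-deficient, R2 via pseudoinverse).
#' @export
blend_regression <- function(u_hat_tst, y_hat_prime_tst, u_parent_avg) {
  n <- length(u_hat_tst)
  if (length(y_hat_prime_tst) != n || length(u_parent_avg) != n || n < 3L)
    stop_famgp("inputs must be aligned vectors of length >= 3")
  r2 <- function(fit) summary(fit)$r.squared
  f1 <- lm(u_hat_tst ~ y_hat_prime_tst)
  f2 <- lm(u_hat_tst ~ u_parent_avg)
  X <- cbind(1, y_hat_prime_tst, u_parent_avg)
  collinear <- qr(X)$rank < ncol(X)
  if (collinear) {
    # rank-deficient joint fit: R2 from the minimum-norm (pseudoinverse) fit
    b <- drop(MASS::ginv(X) %*% u_hat_tst)
    fitted <- drop(X %*% b)
    r2c <- 1 - sum((u_hat_tst - fitted)^2) /
      sum((u_hat_tst - mean(u_hat_tst))^2)
    warning("collinear predictors in the joint blending fit")
  } else {
    r2c <- r2(lm(u_hat_tst ~ y_hat_prime_tst + u_parent_avg))
  }
  list(r2_genomic = r2(f1), r2_parent_avg = r2(f2), r2_combined = r2c,
       collinear = collinear)
}

fit_one <- function(model, y, M, variance_ratio, mcmc, pi_init) {
  switch(model,
         gblup = fit_gblup(y, M, variance_ratio, mcmc),
         bayescpi = fit_bayescpi(y, M, mcmc, pi_init = pi_init),
         stop_famgp("unknown model: ", model))
}

#' Run the full factorial prediction experiment
#'
#' Fits every combination of marker set (set 1 = common SNPs, set 2 = common
#' plus collapsed), model (GBLUP, BayesC-pi) and validation design
#' (within-family, across-family), and reports training and testing
#' correlation and MSE between estimated additive genetic contributions and
#' predicted genomic values. Across-family metrics are unweighted means over
#' the folds.
#'
#' @param pedigree Pedigree data frame.
#' @param u_hat Named vector of estimated additive genetic contributions
#'   (from [fit_repeatability_model()]); its intersection with the genotype
#'   rows defines the analysis individuals.
#' @param marker_sets List of `famgp_geno` objects (typically from
#'   [assemble_marker_sets()]), named e.g. set1/set2.
#' @param mcmc [mcmc_settings()]; each fit derives its own seed from it.
#' @param models,designs Subsets of c("gblup", "bayescpi") and
#'   c("within_family", "across_family").
#' @param k Across-family fold count.
#' @param variance_ratio GBLUP genomic-to-residual variance ratio.
#' @param pi_init BayesC-pi initial pi.
#' @param trn_max_generation Last training generation of the within-family
#'   design.
#' @return Data frame with one row per (set, model, design):
#'   trn_correlation, trn_mse, tst_correlation, tst_mse.
#' @export
run_experiment <- function(pedigree, u_hat, marker_sets,
                           mcmc = mcmc_settings(),
                           models = c("gblup", "bayescpi"),
                           designs = c("within_family", "across_family"),
                           k = 5L, variance_ratio = 2 / 3, pi_init = 0.9,
                           trn_max_generation = 3L) {
  geno_ids <- rownames(dosages(marker_sets[[1]]))
  ids <- intersect(names(u_hat), geno_ids)
  if (length(ids) == 0L) stop_famgp("u_hat and genotypes share no individuals")
  splits_of <- list()
  if ("within_family" %in% designs)
    splits_of$within_family <- list(within_family_split(pedigree, ids,
                                                        trn_max_generation))
  if ("across_family" %in% designs)
    splits_of$across_family <- across_family_folds(pedigree, ids, k,
                                                   seed = mcmc$seed)
  rows <- list()
  fit_counter <- 0L
  for (set_name in names(marker_sets)) {
    M_all <- dosages(marker_sets[[set_name]])
    for (model in models) {
      for (design in names(splits_of)) {
        per_fold <- lapply(splits_of[[design]], function(sp) {
          fit_counter <<- fit_counter + 1L
          m_i <- mcmc
          m_i$seed <- mcmc$seed + 1000L * fit_counter
          Mtrn <- M_all[sp$trn_ids, , drop = FALSE]
          fit <- fit_one(model, u_hat[sp$trn_ids], Mtrn, variance_ratio,
                         m_i, pi_init)
          acc_t <- accuracy(u_hat[sp$trn_ids], predict(fit, Mtrn))
          acc_v <- accuracy(u_hat[sp$tst_ids],
                            predict(fit, M_all[sp$tst_ids, , drop = FALSE]))
          c(trn_r = acc_t$correlation, trn_mse = acc_t$mse,
            tst_r = acc_v$correlation, tst_mse = acc_v$mse)
        })
        m <- colMeans(do.call(rbind, per_fold))
        rows[[length(rows) + 1L]] <-
          data.frame(set = set_name, model = model, design = design,
                     trn_correlation = m["trn_r"], trn_mse = m["trn_mse"],
                     tst_correlation = m["tst_r"], tst_mse = m["tst_mse"],
                     n_folds = length(per_fold), row.names = NULL)
      }
    }
  }
  do.call(rbind, rows)
}

#' Blend genomic and parent-average predictions over a within-family split
#'
#' For every test individual with at least one parent in the training set,
#' computes the parent average of the estimated additive genetic
#' contributions and runs [blend_regression()] against the genomic
#' predictions.
#'
#' @param pedigree Pedigree data frame.
#' @param u_hat Named vector of estimated additive genetic contributions.
#' @param y_hat_prime Named vector of predicted genomic values over the test
#'   individuals.
#' @param split A within-family `famgp_split`.
#' @return List with the three R2 values, plus `n_blend` (test individuals
#'   retained) and the component vectors.
#' @export
blend_experiment <- function(pedigree, u_hat, y_hat_prime, split) {
  trn_u <- u_hat[split$trn_ids]
  keep <- vapply(split$tst_ids, function(id) {
    row <- pedigree[as.character(pedigree$id) == id, ]
    f <- as.character(row$sire); m <- as.character(row$dam)
    (f != "0" && f %in% names(trn_u)) || (m != "0" && m %in% names(trn_u))
  }, logical(1))
  ids <- split$tst_ids[keep]
  if (length(ids) < 3L)
    stop_famgp("fewer than 3 test individuals have a parent in the training set")
  up <- vapply(ids, function(id) parent_average(trn_u, pedigree, id),
               numeric(1))
  res <- blend_regression(u_hat[ids], y_hat_prime[ids], up)
  c(res, list(n_blend = length(ids), ids = ids, parent_avg = up))
}
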
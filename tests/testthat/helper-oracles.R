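# Independent oracles used by the tests; none of these share code with the
# package implementation they check.

# small, fast simulation configuration for structural tests
tiny_config <- function(seed = 1, n_families = 3, generations = 3,
                        founder_couples = 2, n_common_markers = 40,
                        n_rare_markers = 60, n_causal = 10, ...) {
  sim_config(n_families = n_families, generations = generations,
             founder_couples = founder_couples,
             n_common_markers = n_common_markers,
             n_rare_markers = n_rare_markers, n_causal = n_causal,
             seed = seed, ...)
}

# direct V-based REML: builds the n x n phenotypic covariance matrix and
# maximizes the restricted likelihood with optim (no mixed-model equations)
reml_oracle <- function(records, A, covariates = c("year", "age", "sex",
                                                   "meds", "smoking"),
                        start = NULL) {
  ids <- rownames(A)
  ri <- match(as.character(records$id), ids)
  n <- nrow(records)
  X <- cbind(1, as.matrix(records[, covariates, drop = FALSE]))
  Z <- matrix(0, n, length(ids))
  Z[cbind(seq_len(n), ri)] <- 1
  y <- records$y
  ZAZt <- Z %*% A %*% t(Z)
  ZZt <- tcrossprod(Z)
  negll <- function(lt) {
    su <- exp(lt[1]); sc <- exp(lt[2]); se <- exp(lt[3])
    V <- ZAZt * su + ZZt * sc + diag(se, n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi <- chol2inv(cV)
    XtVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
    as.numeric(2 * sum(log(diag(cV))) + determinant(XtVX)$modulus +
                 t(y) %*% P %*% y) / 2
  }
  st <- log(start %||% rep(var(y) / 3, 3))
  opt <- optim(st, negll, method = "BFGS", control = list(maxit = 500))
  list(vc = exp(opt$par), loglik = -opt$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte-Carlo gene-drop covariance between two pedigree members at one
# biallelic marker: drops genotypes down the pedigree n_rep times and returns
# the genotypic correlation (equals the A-matrix entry for non-inbred pairs)
gene_drop_cov <- function(pedigree, id1, id2, p = 0.5, n_rep = 10000) {
  ord <- order(pedigree$generation)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  row_of <- setNames(seq_len(n), as.character(ped$id))
  g1 <- numeric(n_rep); g2 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    dose <- integer(n)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      ms <- if (s == 0) rbinom(1, 1, p) else {
        ds <- dose[row_of[[as.character(s)]]]
        if (ds == 0) 0L else if (ds == 2) 1L else rbinom(1, 1, 0.5)
      }
      md <- if (d == 0) rbinom(1, 1, p) else {
        dd <- dose[row_of[[as.character(d)]]]
        if (dd == 0) 0L else if (dd == 2) 1L else rbinom(1, 1, 0.5)
      }
      dose[i] <- ms + md
    }
    g1[r] <- dose[row_of[[as.character(id1)]]]
    g2[r] <- dose[row_of[[as.character(id2)]]]
  }
  # covariance of relatives = A_ij * 2p(1-p); delta-method Monte-Carlo SE
  d <- (g1 - mean(g1)) * (g2 - mean(g2))
  list(cov = cov(g1, g2),
       a_entry = cov(g1, g2) / (2 * p * (1 - p)),
       se = sd(d) / sqrt(n_rep) / (2 * p * (1 - p)))
}

# exhaustive k-means: enumerates every assignment of n individuals to at most
# k clusters and returns the partition minimizing total within-cluster SSE
exhaustive_kmeans <- function(x, k = 3) {
  n <- nrow(x)
  best_sse <- Inf; best <- NULL
  assign <- rep(1L, n)
  repeat {
    sse <- 0
    for (cl in unique(assign)) {
      xi <- x[assign == cl, , drop = FALSE]
      ctr <- colMeans(xi)
      sse <- sse + sum(sweep(xi, 2, ctr)^2)
    }
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- assign }
    # next assignment in base-k counting
    i <- n
    repeat {
      assign[i] <- assign[i] + 1L
      if (assign[i] <= k) break
      assign[i] <- 1L
      i <- i - 1L
      if (i == 0L) break
    }
    if (i == 0L) break
  }
  list(assignment = best, sse = best_sse)
}

# size-rank coding applied to an arbitrary cluster assignment (re-derivation
# of the coding rule for oracle comparisons)
oracle_codes <- function(assignment, x) {
  cls <- sort(unique(assignment))
  sizes <- sapply(cls, function(cl) sum(assignment == cl))
  norms <- sapply(cls, function(cl) sqrt(sum(colMeans(x[assignment == cl, ,
                                                        drop = FALSE])^2)))
  ord <- cls[order(-sizes, norms)]
  codes <- match(assignment, ord) - 1L
  codes
}

# closed-form ridge solution for centered whole-genome regression
ridge_oracle <- function(y, M, lambda) {
  W <- sweep(M, 2, colMeans(M))
  drop(solve(crossprod(W) + diag(lambda, ncol(W)), crossprod(W, y - mean(y))))
}
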
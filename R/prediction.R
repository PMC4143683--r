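# Whole-genome regression of estimated additive genetic contributions on
# marker dosages: y' = mu + M a + e', fitted by Gibbs sampling under either a
# common marker-effect variance (GBLUP) or a spike-and-slab prior (BayesC-pi).

#' MCMC settings
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Burn-in iterations discarded from the front of the chain.
#' @param thin Thinning rate (every `thin`-th post-burn-in draw is kept).
#' @param seed Integer seed.
#' @return List of class `famgp_mcmc`.
#' @export
mcmc_settings <- function(n_iter = 12000L, burn_in = 2000L, thin = 10L,
                          seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop_famgp("burn_in must be < n_iter")
  if (thin < 1L) stop_famgp("thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)), class = "famgp_mcmc")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' K = W W' / (2 sum_j p_j (1 - p_j)) with W the column-centered dosage
#' matrix and p_j the observed allele frequencies.
#'
#' @param M Dosage matrix (individuals x markers) or `famgp_geno`.
#' @return Symmetric positive semidefinite matrix with individual dimnames.
#' @export
genomic_relationship_matrix <- function(M) {
  M <- dosages(M)
  if (nrow(M) < 2L) stop_famgp("need at least 2 individuals")
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_famgp("all markers are monomorphic")
  W <- sweep(M, 2, 2 * p)
  tcrossprod(W) / denom
}

center_to_train <- function(M, centers) {
  miss <- setdiff(names(centers), colnames(M))
  if (length(miss))
    stop_famgp("marker columns do not match the training set; first offender: ",
               miss[1])
  if (!identical(colnames(M), names(centers)))
    stop_famgp("marker columns do not match the training order; first offender: ",
               colnames(M)[which(colnames(M) != names(centers))[1]])
  sweep(M, 2, centers)
}

check_fit_inputs <- function(y_prime, M, mcmc) {
  if (!inherits(mcmc, "famgp_mcmc")) stop_famgp("mcmc must come from mcmc_settings()")
  if (length(y_prime) != nrow(M))
    stop_famgp("length(y_prime) != nrow(M): ", length(y_prime), " vs ", nrow(M))
  if (anyNA(y_prime) || anyNA(M)) stop_famgp("missing values in y_prime or M")
}

#' Fit GBLUP by Gibbs sampling (marker parameterization)
#'
#' Whole-genome ridge regression: all marker effects share a common variance
#' tied to the residual variance by a fixed genomic-to-residual variance
#' ratio (default 2/3). With the dosage columns centered, the posterior mean
#' of the marker effects coincides with the ridge/BLUP solution of the
#' mixed-model equations at lambda = 2 sum p(1-p) / variance_ratio.
#'
#' @param y_prime Estimated additive genetic contributions of the training
#'   individuals (response of the prediction model).
#' @param M Training dosage matrix (individuals x markers) or `famgp_geno`,
#'   rows aligned with `y_prime`.
#' @param variance_ratio Fixed ratio sigma_a2 / sigma_e2' at the genomic
#'   (not per-marker) level.
#' @param mcmc [mcmc_settings()].
#' @param fixed_sigma_e2 Optionally fix the residual variance (used by
#'   oracle-equivalence tests); NULL samples it.
#' @return Object of class `gp_fit` with the posterior means `mu`,
#'   `a_post_mean` (named per marker), `sigma_e2_prime`, the training column
#'   means used for centering, and bookkeeping fields.
#' @export
fit_gblup <- function(y_prime, M, variance_ratio = 2 / 3,
                      mcmc = mcmc_settings(), fixed_sigma_e2 = NULL) {
  M <- dosages(M)
  check_fit_inputs(y_prime, M, mcmc)
  if (variance_ratio <= 0) stop_famgp("variance_ratio must be > 0")
  p <- colMeans(M) / 2
  cscale <- 2 * sum(p * (1 - p))
  if (cscale <= 0) stop_famgp("all markers are monomorphic")
  centers <- 2 * p
  W <- sweep(M, 2, centers)
  lambda <- cscale / variance_ratio
  set.seed(mcmc$seed)
  res <- gblup_gibbs_cpp(as.numeric(y_prime), W, lambda,
                         mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                         fixed_sigma_e2 %||% -1)
  a <- drop(res$a_post_mean); names(a) <- colnames(M)
  a_sd <- drop(res$a_post_sd); names(a_sd) <- colnames(M)
  structure(list(model = "gblup", mu = res$mu, a_post_mean = a,
                 a_post_sd = a_sd,
                 sigma_e2_prime = res$sigma_e2_prime,
                 sigma_a2 = variance_ratio * res$sigma_e2_prime / cscale,
                 variance_ratio = variance_ratio, lambda = lambda,
                 centers = centers, n_kept = res$n_kept, mcmc = mcmc),
            class = "gp_fit")
}

#' Fit BayesC-pi by Gibbs sampling
#'
#' Spike-and-slab whole-genome regression: at each iteration every marker
#' effect is zero with probability pi or drawn from N(0, sigma_a2) through
#' its sampled inclusion indicator; pi gets a Uniform(0,1) prior and is
#' sampled from its Beta full conditional, sigma_a2 and sigma_e2' from scaled
#' inverse chi-square full conditionals. Hyperprior scales follow the usual
#' practice of matching the prior mean of sigma_a2 to half the variance of
#' y' spread over the expected number of included markers.
#'
#' @inheritParams fit_gblup
#' @param pi_init Initial value of pi (default 0.9).
#' @param nu Hyperprior degrees of freedom for both variances.
#' @param pi_fixed Clamp pi to a constant (0 gives the all-included
#'   common-variance model, 1 the pure spike); NULL samples pi.
#' @param fixed_sigma_a2,fixed_sigma_e2 Optionally fix a variance (oracle
#'   tests); NULL samples it.
#' @return Object of class `gp_fit` with posterior means `mu`, `a_post_mean`,
#'   `pi_post_mean`, per-marker `inclusion_prob`, `sigma_a2`,
#'   `sigma_e2_prime`.
#' @export
fit_bayescpi <- function(y_prime, M, mcmc = mcmc_settings(), pi_init = 0.9,
                         nu = 4.2, pi_fixed = NULL,
                         fixed_sigma_a2 = NULL, fixed_sigma_e2 = NULL) {
  M <- dosages(M)
  check_fit_inputs(y_prime, M, mcmc)
  if (pi_init < 0 || pi_init > 1) stop_famgp("pi_init must be in [0, 1]")
  p <- colMeans(M) / 2
  cscale <- 2 * sum(p * (1 - p))
  if (cscale <= 0) stop_famgp("all markers are monomorphic")
  centers <- 2 * p
  W <- sweep(M, 2, centers)
  vy <- var(as.numeric(y_prime))
  pi0 <- if (!is.null(pi_fixed)) pi_fixed else pi_init
  # prior scales: E[sigma_a2] = 0.5 vy / ((1 - pi) cscale), E[sigma_e2] = 0.5 vy
  s_a <- max(0.5 * vy / (max(1 - pi0, 0.01) * cscale), 1e-10) * (nu - 2) / nu
  s_e <- max(0.5 * vy, 1e-10) * (nu - 2) / nu
  set.seed(mcmc$seed)
  res <- bayescpi_gibbs_cpp(as.numeric(y_prime), W,
                            mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                            pi_init, nu, s_a, nu, s_e,
                            pi_fixed %||% -1,
                            fixed_sigma_a2 %||% -1,
                            fixed_sigma_e2 %||% -1)
  a <- drop(res$a_post_mean); names(a) <- colnames(M)
  a_sd <- drop(res$a_post_sd); names(a_sd) <- colnames(M)
  ip <- drop(res$inclusion_prob); names(ip) <- colnames(M)
  structure(list(model = "bayescpi", mu = res$mu, a_post_mean = a,
                 a_post_sd = a_sd, inclusion_prob = ip,
                 pi_post_mean = res$pi_post_mean,
                 sigma_a2 = res$sigma_a2,
                 sigma_e2_prime = res$sigma_e2_prime,
                 centers = centers, n_kept = res$n_kept, mcmc = mcmc),
            class = "gp_fit")
}

#' Predict genomic values for new individuals
#'
#' y-hat' = mu + (M_new - training centers) a-hat. Marker columns of `M_new`
#' must match the training markers in id and order; a mismatch raises an
#' error naming the first offending marker.
#'
#' @param object A `gp_fit` from [fit_gblup()] or [fit_bayescpi()].
#' @param M_new Dosage matrix (or `famgp_geno`) of the individuals to predict.
#' @param ... Unused.
#' @return Named numeric vector of predicted genomic values.
#' @export
predict.gp_fit <- function(object, M_new, ...) {
  M <- dosages(M_new)
  W <- center_to_train(M, object$centers)
  yhat <- object$mu + drop(W %*% object$a_post_mean)
  names(yhat) <- rownames(M)
  yhat
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit:%s> %d markers, mu = %.3f, %d kept samples\n",
              x$model, length(x$a_post_mean), x$mu, x$n_kept))
  if (x$model == "bayescpi")
    cat(sprintf("  pi (posterior mean) = %.3f\n", x$pi_post_mean))
  invisible(x)
}

#' Direct (non-MCMC) GBLUP solver
#'
#' Closed-form mixed-model-equation solution used as the independent oracle
#' for the Gibbs samplers: ridge regression of centered y' on centered
#' dosages with lambda = 2 sum p(1-p) / variance_ratio
#' (`parameterization = "marker"`), or the equivalent genomic-value BLUP
#' through the VanRaden kinship matrix (`"kinship"`).
#'
#' @inheritParams fit_gblup
#' @param parameterization "marker" returns marker effects and fitted values;
#'   "kinship" fits genomic values through K directly.
#' @return List with `mu`, `fitted`, and (`marker` only) `a`.
#' @export
gblup_direct <- function(y_prime, M, variance_ratio = 2 / 3,
                         parameterization = c("marker", "kinship")) {
  parameterization <- match.arg(parameterization)
  M <- dosages(M)
  y <- as.numeric(y_prime)
  p <- colMeans(M) / 2
  cscale <- 2 * sum(p * (1 - p))
  if (cscale <= 0) stop_famgp("all markers are monomorphic")
  W <- sweep(M, 2, 2 * p)
  mu <- mean(y)
  if (parameterization == "marker") {
    lambda <- cscale / variance_ratio
    WtW <- crossprod(W)
    a <- drop(solve(WtW + diag(lambda, ncol(W)), crossprod(W, y - mu)))
    names(a) <- colnames(M)
    list(mu = mu, a = a, fitted = mu + drop(W %*% a))
  } else {
    K <- tcrossprod(W) / cscale
    n <- nrow(K)
    # V-based BLUP with sigma_e2 = 1, sigma_g2 = variance_ratio
    V <- variance_ratio * K + diag(n)
    Vi <- solve(V)
    one <- rep(1, n)
    mu_gls <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
    g <- variance_ratio * drop(K %*% Vi %*% (y - mu_gls))
    list(mu = mu_gls, fitted = mu_gls + g)
  }
}
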
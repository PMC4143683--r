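# Repeatability animal model
#   y = X beta + Z u + T c + e,  u ~ N(0, A su2), c ~ N(0, I sc2), e ~ N(0, I se2)
# fitted by REML: EM steps with average-information (AI) acceleration, both
# driven by the mixed-model equations with the permanent-environmental block
# absorbed (it is diagonal), so each iteration factorizes a (p + q) system.

#' Design matrices of the repeatability model
#'
#' @param records Long-format phenotype data frame with columns `id`, `y` and
#'   the covariate columns.
#' @param pedigree Pedigree data frame; its individuals define the columns of
#'   the incidence matrices (phenotyped or not).
#' @param covariates Character vector of covariate column names entering X.
#' @param intercept Include a global intercept column in X.
#' @return List with `X` (n x p dense), `Z` and `T` (n x q sparse 0/1
#'   incidence matrices, identical for this model), and `ids` (column order).
#' @export
build_design_matrices <- function(records, pedigree,
                                  covariates = c("year", "age", "sex",
                                                 "meds", "smoking"),
                                  intercept = TRUE) {
  ids <- as.character(pedigree$id)
  ri <- match(as.character(records$id), ids)
  if (anyNA(ri)) {
    bad <- unique(records$id[is.na(ri)])
    stop_famgp("records refer to individuals absent from the pedigree: ",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop_famgp("missing covariate columns: ",
                               paste(miss, collapse = ", "))
  n <- nrow(records)
  X <- as.matrix(records[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = ri, x = 1,
                            dims = c(n, length(ids)),
                            dimnames = list(NULL, ids))
  list(X = X, Z = Z, T = Z, ids = ids)
}

#' Narrow-sense heritability
#'
#' h2 = sigma_u2 / (sigma_u2 + sigma_c2 + sigma_e2): the fraction of
#' phenotypic variance attributable to additive genetic variance under the
#' repeatability model.
#'
#' @param vc List or `famgp_vc_fit` with elements `sigma_u2`, `sigma_c2`,
#'   `sigma_e2`.
#' @return Heritability (scalar in \[0, 1\]).
#' @export
heritability <- function(vc) {
  if (inherits(vc, "famgp_vc_fit")) vc <- vc$vc
  tot <- vc$sigma_u2 + vc$sigma_c2 + vc$sigma_e2
  if (tot <= 0) stop_famgp("all variance components are zero")
  vc$sigma_u2 / tot
}

#' Fit the repeatability animal model by REML
#'
#' Estimates (sigma_u2, sigma_c2, sigma_e2) by restricted maximum likelihood.
#' The first iterations are EM-REML updates from the mixed-model equations;
#' thereafter average-information (AI) Newton steps are attempted, falling
#' back to EM whenever a step leaves the parameter space or decreases the
#' restricted likelihood. BLUPs of the additive genetic (u) and
#' permanent-environmental (c) effects are returned at the converged
#' variances, together with generalized-least-squares fixed effects.
#'
#' @param records Phenotype data frame (see [build_design_matrices()]).
#' @param A Additive relationship matrix over (at least) all phenotyped
#'   individuals; its dimnames define the individuals fitted.
#' @param covariates,intercept Passed to [build_design_matrices()].
#' @param include_pe Fit the permanent-environmental (repeated) effect c; set
#'   `FALSE` to drop it (used to show the inflation of the additive variance
#'   when repeated records are not modelled). Automatically disabled, with a
#'   warning, when no individual has repeated records.
#' @param start Optional starting values c(sigma_u2, sigma_c2, sigma_e2).
#' @param tol Convergence tolerance on the relative change of each component.
#' @param max_iter Iteration cap.
#' @param n_em Number of initial plain EM iterations before AI steps.
#' @return Object of class `famgp_vc_fit`: `beta`, `u_hat`, `c_hat`
#'   (named by id), `vc` (the three components), `h2`,
#'   `loglik_restricted`, `converged`, `n_iter`, `trace`.
#' @export
fit_repeatability_model <- function(records, A,
                                    covariates = c("year", "age", "sex",
                                                   "meds", "smoking"),
                                    intercept = TRUE,
                                    include_pe = TRUE,
                                    start = NULL, tol = 1e-6,
                                    max_iter = 500L, n_em = 3L) {
  ids <- rownames(A)
  ped_like <- data.frame(id = ids, stringsAsFactors = FALSE)
  dm <- build_design_matrices(records, ped_like, covariates, intercept)
  X <- dm$X; Z <- dm$Z
  y <- records$y
  if (anyNA(y)) stop_famgp("missing trait values; drop them upstream")
  n <- length(y); p <- ncol(X); q <- length(ids)
  if (qr(X)$rank < p) stop_famgp("fixed-effect design matrix is rank deficient")

  n_i <- Matrix::colSums(Z)                    # records per individual
  if (include_pe && max(n_i) < 2) {
    warning("no repeated records: permanent-environmental variance fixed at 0")
    include_pe <- FALSE
  }
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(X, Z))    # p x q
  Xty <- drop(crossprod(X, y))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  yty <- sum(y * y)
  Ach <- tryCatch(chol(A), error = function(e) chol(A + diag(1e-8, q)))
  Ainv <- chol2inv(Ach)
  logdetA <- 2 * sum(log(diag(Ach)))

  # one REML "evaluation" at (su2, sc2, se2): solves the absorbed MME and
  # returns solutions, traces needed by EM/AI, and the restricted loglik
  evaluate <- function(su2, sc2, se2) {
    lu <- se2 / su2
    if (include_pe) {
      lc <- se2 / sc2
      dc <- n_i + lc
      w <- lc / dc                              # q-vector
      Cbb <- XtX - XtZ %*% (t(XtZ) / dc)
      Cbu <- XtZ * rep(w, each = p)
      Cuu <- lu * Ainv
      diag(Cuu) <- diag(Cuu) + n_i * w
      rb <- Xty - XtZ %*% (Zty / dc)
      ru <- w * Zty
    } else {
      dc <- NULL; w <- NULL
      Cbb <- XtX; Cbu <- XtZ
      Cuu <- lu * Ainv
      diag(Cuu) <- diag(Cuu) + n_i
      rb <- Xty; ru <- Zty
    }
    Cred <- rbind(cbind(Cbb, Cbu), cbind(t(Cbu), Cuu))
    R <- tryCatch(chol(Cred), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    sol <- backsolve(R, backsolve(R, c(rb, ru), transpose = TRUE))
    beta <- sol[seq_len(p)]
    u <- sol[p + seq_len(q)]
    cc <- if (include_pe)
      drop(Zty - crossprod(XtZ, beta) - n_i * u) / dc else numeric(q)
    ype <- yty - sum(beta * Xty) - sum(u * Zty) - sum(cc * Zty)  # y' e-hat
    ype <- max(ype, 1e-12)
    logdetC <- 2 * sum(log(diag(R))) + if (include_pe) sum(log(dc)) else 0
    m2ll <- n * log(se2) + q * log(su2) + logdetA +
      (if (include_pe) q * log(sc2) else 0) +
      logdetC - (p + q + (if (include_pe) q else 0)) * log(se2) + ype / se2
    # traces of the relevant blocks of the full MME inverse (lambda form)
    Cinv <- chol2inv(R)
    Cuu_inv <- Cinv[p + seq_len(q), p + seq_len(q), drop = FALSE]
    tr_uu <- sum(Ainv * Cuu_inv)
    tr_cc <- if (include_pe) {
      G <- rbind(XtZ * rep(1 / dc, each = p), diag(n_i / dc, q))
      S <- backsolve(R, G, transpose = TRUE)
      sum(1 / dc) + sum(S * S)
    } else NA_real_
    list(beta = beta, u = u, cc = cc, ype = ype, m2ll = m2ll,
         tr_uu = tr_uu, tr_cc = tr_cc, R = R, dc = dc, w = w,
         su2 = su2, sc2 = sc2, se2 = se2)
  }

  # EM-REML updates from the current solution
  em_update <- function(ev) {
    se2n <- ev$ype / (n - p)
    su2n <- (sum(ev$u * (Ainv %*% ev$u)) + ev$tr_uu * ev$se2) / q
    sc2n <- if (include_pe) (sum(ev$cc^2) + ev$tr_cc * ev$se2) / q else 0
    pmax(c(su2n, sc2n, se2n), 1e-8)
  }

  # solve the absorbed MME for an arbitrary data vector f, return P f
  Pvec <- function(ev, f) {
    Xtf <- drop(crossprod(X, f)); Ztf <- as.numeric(Matrix::crossprod(Z, f))
    if (include_pe) {
      rb <- Xtf - XtZ %*% (Ztf / ev$dc); ru <- ev$w * Ztf
    } else { rb <- Xtf; ru <- Ztf }
    sol <- backsolve(ev$R, backsolve(ev$R, c(rb, ru), transpose = TRUE))
    bf <- sol[seq_len(p)]; uf <- sol[p + seq_len(q)]
    cf <- if (include_pe)
      drop(Ztf - crossprod(XtZ, bf) - n_i * uf) / ev$dc else numeric(q)
    as.numeric(f - X %*% bf - Z %*% (uf + cf)) / ev$se2
  }

  # AI-REML proposal; returns NULL if not usable
  ai_update <- function(ev) {
    su2 <- ev$su2; sc2 <- ev$sc2; se2 <- ev$se2
    ehat <- as.numeric(y - X %*% ev$beta - Z %*% (ev$u + ev$cc))
    Py <- ehat / se2
    fs <- list(u = as.numeric(Z %*% ev$u) / su2, e = Py)
    if (include_pe) fs$c <- as.numeric(Z %*% ev$cc) / sc2
    ord <- if (include_pe) c("u", "c", "e") else c("u", "e")
    Pf <- lapply(fs[ord], function(f) Pvec(ev, f))
    k <- length(ord)
    AI <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in a:k) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(fs[[ord[a]]] * Pf[[ord[b]]])
    }
    trPVu <- (q - (se2 / su2) * ev$tr_uu) / su2
    yPVuPy <- sum(ev$u * (Ainv %*% ev$u)) / su2^2
    sc_u <- -0.5 * (trPVu - yPVuPy)
    if (include_pe) {
      trPVc <- (q - (se2 / sc2) * ev$tr_cc) / sc2
      yPVcPy <- sum(ev$cc^2) / sc2^2
      sc_c <- -0.5 * (trPVc - yPVcPy)
      trP <- ((n - p) - su2 * trPVu - sc2 * trPVc) / se2
    } else {
      sc_c <- NULL
      trP <- ((n - p) - su2 * trPVu) / se2
    }
    sc_e <- -0.5 * (trP - sum(Py * Py))
    score <- if (include_pe) c(sc_u, sc_c, sc_e) else c(sc_u, sc_e)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    theta <- if (include_pe) c(su2, sc2, se2) else c(su2, se2)
    newt <- theta + step
    if (any(!is.finite(newt))) return(NULL)
    # a component pushed past zero is clamped toward the boundary
    newt[newt <= 0] <- pmax(theta[newt <= 0] / 10, 1e-8)
    if (include_pe) pmax(newt, 1e-8) else c(newt[1], 0, newt[2])
  }

  vy <- var(y)
  theta <- start %||% c(vy / 3, if (include_pe) vy / 3 else 0, vy / 3)
  theta <- pmax(theta, c(1e-8, 0, 1e-8))
  ev <- evaluate(theta[1], max(theta[2], 1e-8), theta[3])
  if (is.null(ev)) stop_famgp("mixed-model equations are singular at the start values")
  trace <- data.frame(iter = 0L, sigma_u2 = theta[1], sigma_c2 = theta[2],
                      sigma_e2 = theta[3], m2ll = ev$m2ll, step = "init")
  converged <- FALSE; it <- 0L; ll_flat <- 0L
  while (it < max_iter) {
    it <- it + 1L
    proposal <- NULL; kind <- "em"
    if (it > n_em) {
      cand <- ai_update(ev)
      if (!is.null(cand)) {
        # accept the AI step, halving it while it degrades the likelihood
        for (h in 0:3) {
          cand_h <- theta + (cand - theta) / 2^h
          cand_h <- pmax(cand_h, c(1e-8, if (include_pe) 1e-8 else 0, 1e-8))
          if (!include_pe) cand_h[2] <- 0
          evc <- evaluate(cand_h[1], max(cand_h[2], 1e-8), cand_h[3])
          if (!is.null(evc) && evc$m2ll <= ev$m2ll + 1e-10) {
            proposal <- cand_h; evn <- evc; kind <- "ai"
            break
          }
        }
      }
    }
    if (is.null(proposal)) {
      proposal <- em_update(ev)
      if (!include_pe) proposal[2] <- 0
      evn <- evaluate(proposal[1], max(proposal[2], 1e-8), proposal[3])
      if (is.null(evn)) stop_famgp("mixed-model equations became singular")
    }
    rel <- abs(proposal - theta) / pmax(abs(theta), 1e-8)
    dll <- abs(ev$m2ll - evn$m2ll)
    theta <- proposal; ev <- evn
    trace <- rbind(trace, data.frame(iter = it, sigma_u2 = theta[1],
                                     sigma_c2 = theta[2], sigma_e2 = theta[3],
                                     m2ll = ev$m2ll, step = kind))
    if (max(rel) < tol) { converged <- TRUE; break }
    # boundary components leave the likelihood flat while still moving:
    # accept likelihood stationarity as convergence
    ll_flat <- ll_flat + 1L
    if (dll >= 1e-7 * (1 + abs(ev$m2ll))) ll_flat <- 0L
    if (ll_flat >= 3L) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 0L)
    warning("REML did not converge in ", max_iter, " iterations; ",
            "returning the last iterate (converged = FALSE)")
  u_hat <- ev$u; names(u_hat) <- ids
  c_hat <- ev$cc; names(c_hat) <- ids
  beta <- ev$beta; names(beta) <- colnames(X)
  vc <- list(sigma_u2 = theta[1], sigma_c2 = theta[2], sigma_e2 = theta[3])
  structure(list(beta = beta, u_hat = u_hat, c_hat = c_hat, vc = vc,
                 h2 = heritability(vc), loglik_restricted = -0.5 * ev$m2ll,
                 converged = converged, n_iter = it, trace = trace,
                 n_records = n, n_individuals = q, include_pe = include_pe),
            class = "famgp_vc_fit")
}

#' Restricted log-likelihood of the repeatability model at given variances
#'
#' Evaluates the REML log-likelihood (up to the usual constant) at fixed
#' variance components, using the same absorbed mixed-model-equation route as
#' the fitter. Used for optimizer sanity checks.
#'
#' @inheritParams fit_repeatability_model
#' @param vc List with `sigma_u2`, `sigma_c2`, `sigma_e2` (all > 0).
#' @return Restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(records, A, vc,
                        covariates = c("year", "age", "sex", "meds", "smoking"),
                        intercept = TRUE) {
  fit <- fit_repeatability_model(records, A, covariates, intercept,
                                 start = c(vc$sigma_u2, vc$sigma_c2, vc$sigma_e2),
                                 max_iter = 0L)
  fit$loglik_restricted
}

#' @export
print.famgp_vc_fit <- function(x, ...) {
  cat("Repeatability animal model (REML)\n")
  cat(sprintf("  records: %d   individuals: %d\n", x$n_records, x$n_individuals))
  cat(sprintf("  sigma_u2 = %.3f  sigma_c2 = %.3f  sigma_e2 = %.3f\n",
              x$vc$sigma_u2, x$vc$sigma_c2, x$vc$sigma_e2))
  cat(sprintf("  h2 = %.3f   restricted logLik = %.3f   converged: %s (%d iter)\n",
              x$h2, x$loglik_restricted, x$converged, x$n_iter))
  invisible(x)
}
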
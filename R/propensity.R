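# Propensity-score estimation (main-effects logistic regression) and
# discrimination diagnostics.

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment status on the
#' baseline covariates, fitted by iteratively reweighted least squares with
#' step halving.  Upon a singular weighted Hessian a ridge of 1e-8 is added
#' to the Hessian only (never the score), and its use is flagged; this
#' keeps rare degenerate bootstrap resamples from crashing a simulation
#' run.  Non-convergence or degenerate fitted probabilities (perfect
#' separation) raise a classed condition \code{"pswvar_fit_failure"} so the
#' caller can record the replicate as failed.
#'
#' @param X Covariate matrix (no intercept column).
#' @param Z 0/1 treatment vector.
#' @param maxit Maximum IRLS iterations.
#' @param grad_tol Convergence tolerance on the maximum absolute component
#'   of the score vector.
#' @return An object of class \code{"propensity_fit"}: list with
#'   \code{coefficients} (intercept first), \code{fitted_ps},
#'   \code{converged}, \code{ridge_used}, \code{score_max}.
#' @export
fit_propensity <- function(X, Z, maxit = 100L, grad_tol = 1e-9) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n1 <- sum(Z == 1); n0 <- sum(Z == 0)
  if (n1 == 0L || n0 == 0L)
    .fit_failure("both treatment groups must be non-empty")
  Xd <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  ridge_used <- FALSE
  loglik <- function(eta) sum(Z * eta - log1p(exp(eta)))
  eta <- drop(Xd %*% beta)
  ll <- loglik(eta)
  for (it in seq_len(maxit)) {
    pr <- stats::plogis(eta)
    g <- crossprod(Xd, Z - pr)
    if (max(abs(g)) < grad_tol && it > 1L) break
    w <- pr * (1 - pr)
    H <- crossprod(Xd * w, Xd)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      ridge_used <- TRUE
      step <- tryCatch(solve(H + diag(1e-8, p), g), error = function(e) NULL)
      if (is.null(step)) .fit_failure("singular Hessian")
    }
    # step halving: insist the log-likelihood does not decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(Xd %*% beta_new)
      ll_new <- loglik(eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-10) .fit_failure("step halving failed")
    }
    beta <- beta_new; eta <- eta_new; ll <- ll_new
  }
  pr <- stats::plogis(eta)
  score_max <- max(abs(crossprod(Xd, Z - pr)))
  converged <- is.finite(score_max) && score_max < 1e-6
  if (!converged)
    .fit_failure(sprintf("no convergence (max |score| = %g)", score_max))
  if (any(pr <= 0) || any(pr >= 1))
    .fit_failure("fitted probabilities degenerate (separation)")
  structure(list(coefficients = drop(beta),
                 fitted_ps = pr,
                 converged = TRUE,
                 ridge_used = ridge_used,
                 score_max = score_max),
            class = "propensity_fit")
}

.fit_failure <- function(msg) {
  stop(structure(class = c("pswvar_fit_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Concordance (c-statistic) of a propensity score
#'
#' Rank-based concordance between a score and binary treatment status:
#' the probability that a randomly chosen treated subject has a higher
#' score than a randomly chosen control, with ties counting one half.
#' Computed via rank sums (Wilcoxon identity), so it is invariant to any
#' strictly increasing transform of the score.
#'
#' @param ps Numeric score vector.
#' @param Z 0/1 treatment vector.
#' @return Concordance in \[0, 1\].
#' @export
c_statistic <- function(ps, Z) {
  n1 <- as.numeric(sum(Z == 1)); n0 <- as.numeric(sum(Z == 0))
  if (n1 == 0 || n0 == 0)
    stop("c-statistic undefined: a treatment group is empty", call. = FALSE)
  r <- rank(ps)
  (sum(r[Z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
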
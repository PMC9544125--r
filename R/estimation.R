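# Point estimation of weighted treatment effects, the M-estimation
# (stacked estimating equation) sandwich variance that propagates
# propensity-score estimation, bootstrap standard errors, and
# normal-theory confidence intervals.

#' Hajek weighted group means
#'
#' Normalized (ratio) weighted means of the outcome in the treated and
#' control groups: the weight sums appear in the denominators, so
#' rescaling all weights within a group by a positive constant leaves the
#' means unchanged.
#'
#' @param y Outcome vector.
#' @param Z 0/1 treatment vector.
#' @param w Weight vector (see [compute_weights()]).
#' @return Named numeric vector \code{c(mu1, mu0)}.
#' @export
weighted_group_means <- function(y, Z, w) {
  s1 <- sum(w[Z == 1]); s0 <- sum(w[Z == 0])
  if (!(s1 > 0) || !(s0 > 0))
    stop("estimate undefined: a group has non-positive total weight",
         call. = FALSE)
  c(mu1 = sum(w[Z == 1] * y[Z == 1]) / s1,
    mu0 = sum(w[Z == 0] * y[Z == 0]) / s0)
}

#' Combine group means into effect estimates
#'
#' For a continuous outcome the mean difference mu1 - mu0; for a binary
#' outcome the risk difference mu1 - mu0 and the log relative risk
#' log(mu1/mu0).  The relative risk is carried on the log scale because
#' its sampling distribution is closer to normal.
#'
#' @param mu1,mu0 Weighted group means.
#' @param outcome_type \code{"continuous"} or \code{"binary"}.
#' @return Named list: \code{mean_diff}, or \code{risk_diff} and
#'   \code{log_rr}.
#' @export
point_estimates <- function(mu1, mu0,
                            outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  if (outcome_type == "continuous")
    return(list(mean_diff = mu1 - mu0))
  if (mu1 <= 0 || mu0 <= 0)
    stop("log relative risk undefined: a group proportion is zero",
         call. = FALSE)
  list(risk_diff = mu1 - mu0, log_rr = log(mu1 / mu0))
}

# Weight and derivative-of-weight functions with respect to the propensity
# score e, per family, in treated (w1) and control (w0) form.  MW is not
# differentiable at e = 0.5; the e < 0.5 branch is used there (measure-zero
# event for continuously distributed scores).
.weight_funs <- function(family) {
  switch(family,
    ATE = list(w1 = function(e) 1 / e,        d1 = function(e) -1 / e^2,
               w0 = function(e) 1 / (1 - e),  d0 = function(e) 1 / (1 - e)^2),
    ATT = list(w1 = function(e) rep(1, length(e)), d1 = function(e) rep(0, length(e)),
               w0 = function(e) e / (1 - e),  d0 = function(e) 1 / (1 - e)^2),
    MW  = list(w1 = function(e) pmin(e, 1 - e) / e,
               d1 = function(e) ifelse(e <= 0.5, 0, -1 / e^2),
               w0 = function(e) pmin(e, 1 - e) / (1 - e),
               d0 = function(e) ifelse(e <= 0.5, 1 / (1 - e)^2, 0)),
    OW  = list(w1 = function(e) 1 - e,        d1 = function(e) rep(-1, length(e)),
               w0 = function(e) e,            d0 = function(e) rep(1, length(e))),
    stop("unknown weight family", call. = FALSE))
}

#' Sandwich variance from stacked estimating equations
#'
#' Empirical sandwich (M-estimation) variance for the weighted group means
#' and the derived effect estimates.  The estimating equations stack the
#' logistic score equations for the propensity coefficients beta with the
#' two weighted-mean equations
#' \deqn{\sum_i w_1(x_i;\beta) Z_i (Y_i - \mu_1) = 0, \quad
#'       \sum_i w_0(x_i;\beta) (1-Z_i) (Y_i - \mu_0) = 0,}
#' so the variance propagates the uncertainty from estimating the
#' propensity score: the bread matrix A contains the analytic derivative
#' of the weights through e(x; beta).  With A = -mean of the Jacobian and
#' B = mean outer product of the stacked equations, Var = A^-1 B A^-T / n,
#' and the delta method maps the (mu1, mu0) block to each estimand
#' (gradient (1, -1) for differences, (1/mu1, -1/mu0) for the log relative
#' risk).
#'
#' Setting \code{propagate_ps = FALSE} treats the weights as fixed
#' constants (only the two mean equations are stacked), which reduces, at
#' unit weights, to the classical two-group sandwich with per-group
#' divisor n.
#'
#' @param X Covariate matrix used in the propensity model.
#' @param Z 0/1 treatment vector.
#' @param y Outcome vector.
#' @param fit A [fit_propensity()] object (ignored when
#'   \code{propagate_ps = FALSE} and \code{weights} are supplied).
#' @param family Weight family.
#' @param outcome_type \code{"continuous"} or \code{"binary"}.
#' @param propagate_ps Logical; account for propensity estimation.
#' @param weights Optional fixed weight vector (only with
#'   \code{propagate_ps = FALSE}).
#' @return List with \code{se} (named: \code{mean_diff} or
#'   \code{risk_diff}, \code{log_rr}), \code{mu} = c(mu1, mu0),
#'   \code{vcov_mu} (2 x 2), and the \code{A} and \code{B} matrices.
#' @export
sandwich_variance <- function(X, Z, y, fit, family,
                              outcome_type = c("continuous", "binary"),
                              propagate_ps = TRUE, weights = NULL) {
  outcome_type <- match.arg(outcome_type)
  n <- length(Z)
  if (propagate_ps) {
    e <- fit$fitted_ps
    wf <- .weight_funs(family)
    w <- ifelse(Z == 1, wf$w1(e), wf$w0(e))
  } else {
    if (is.null(weights)) {
      e <- fit$fitted_ps
      wf <- .weight_funs(family)
      w <- ifelse(Z == 1, wf$w1(e), wf$w0(e))
    } else w <- weights
  }
  mu <- weighted_group_means(y, Z, w)
  mu1 <- mu[["mu1"]]; mu0 <- mu[["mu0"]]
  psi1 <- w * (Z == 1) * (y - mu1)
  psi0 <- w * (Z == 0) * (y - mu0)
  if (propagate_ps) {
    Xd <- cbind(1, X)
    p <- ncol(Xd)
    v <- e * (1 - e)
    psi_beta <- Xd * (Z - e)
    A11 <- crossprod(Xd * v, Xd) / n
    a21 <- -colMeans(Xd * ((Z == 1) * (y - mu1) * wf$d1(e) * v))
    a20 <- -colMeans(Xd * ((Z == 0) * (y - mu0) * wf$d0(e) * v))
    A <- rbind(cbind(A11, matrix(0, p, 2)),
               c(a21, mean(w * (Z == 1)), 0),
               c(a20, 0, mean(w * (Z == 0))))
    Psi <- cbind(psi_beta, psi1, psi0)
  } else {
    p <- 0L
    A <- diag(c(mean(w * (Z == 1)), mean(w * (Z == 0))))
    Psi <- cbind(psi1, psi0)
  }
  B <- crossprod(Psi) / n
  Ainv <- tryCatch(solve(A), error = function(e)
    stop(structure(class = c("pswvar_variance_failure", "error", "condition"),
                   list(message = "singular bread matrix in sandwich variance",
                        call = NULL))))
  V <- Ainv %*% B %*% t(Ainv) / n
  k <- p + 1L
  Vmu <- V[k:(k + 1L), k:(k + 1L)]
  se <- if (outcome_type == "continuous") {
    c(mean_diff = sqrt(drop(t(c(1, -1)) %*% Vmu %*% c(1, -1))))
  } else {
    # a zero group proportion leaves the risk difference defined but not
    # the log relative risk: its SE is reported missing
    c(risk_diff = sqrt(drop(t(c(1, -1)) %*% Vmu %*% c(1, -1))),
      log_rr = if (mu1 > 0 && mu0 > 0)
        sqrt(drop(t(c(1 / mu1, -1 / mu0)) %*% Vmu %*%
                    c(1 / mu1, -1 / mu0))) else NA_real_)
  }
  list(se = se, mu = mu, vcov_mu = Vmu, A = A, B = B)
}

# One pass of the full estimation pipeline on a (re)sample: trimming
# workflow, propensity fit, and per-family point estimates for both
# outcomes.  Returns a named numeric vector over families x estimands.
# A failed propensity fit aborts (caller records the failure); a
# zero-event group only invalidates the log relative risk, which comes
# back NA.  Used by the bootstrap and the simulation engine.
.estimate_all <- function(smp, families,
                          trim_method = "none", trim_delta = 0) {
  wf <- apply_trimming_workflow(smp, trim_method, trim_delta)
  s <- wf$sample; fit <- wf$fit
  out <- c()
  for (fam in families) {
    w <- compute_weights(fit$fitted_ps, s$Z, fam)
    muc <- weighted_group_means(s$y_cont, s$Z, w)
    mub <- weighted_group_means(s$y_bin, s$Z, w)
    v <- c(muc[["mu1"]] - muc[["mu0"]],
           mub[["mu1"]] - mub[["mu0"]],
           if (mub[["mu1"]] > 0 && mub[["mu0"]] > 0)
             log(mub[["mu1"]] / mub[["mu0"]]) else NA_real_)
    names(v) <- paste(fam, c("mean_diff", "risk_diff", "log_rr"), sep = ".")
    out <- c(out, v)
  }
  out
}

# B bootstrap resamples of the full pipeline: rows are resamples, columns
# family.estimand point estimates; failed resamples give NA rows.
.bootstrap_matrix <- function(smp, B, families,
                              trim_method = "none", trim_delta = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(smp$Z)
  cols <- as.vector(outer(c("mean_diff", "risk_diff", "log_rr"), families,
                          function(e, f) paste(f, e, sep = ".")))
  res <- matrix(NA_real_, B, length(cols), dimnames = list(NULL, cols))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      .estimate_all(.subset_sample(smp, idx), families,
                    trim_method, trim_delta),
      error = function(e) NULL)
    if (!is.null(est)) res[b, names(est)] <- est
  }
  res
}

#' Bootstrap standard errors for weighted effect estimates
#'
#' Draws \code{B} simple (unstratified) resamples of n subjects with
#' replacement and re-runs the complete estimation pipeline on each:
#' propensity re-estimation, weight computation, point estimation, and the
#' trimming workflow when configured (Crump's threshold is recomputed per
#' resample).  The SE of each estimand is the sample standard deviation
#' (divisor B - 1) across successful resamples; degenerate resamples
#' (separation, an empty group, a zero-event group) are dropped and
#' counted, never imputed.
#'
#' @param smp A \code{"ps_sample"}.
#' @param family Weight family.
#' @param B Number of bootstrap resamples (study default 200).
#' @param seed Optional integer seed.
#' @param trim_method,trim_delta Trimming configuration applied inside
#'   each resample.
#' @return List with \code{se} (named vector over \code{mean_diff},
#'   \code{risk_diff}, \code{log_rr}), \code{n_used} (successful resamples
#'   per estimand), \code{n_failed}, and \code{high_failure} (flag set
#'   when more than 10% of resamples failed).
#' @export
bootstrap_se <- function(smp, family, B = 200L, seed = NULL,
                         trim_method = "none", trim_delta = 0) {
  if (B < 2L) stop("need at least 2 bootstrap resamples", call. = FALSE)
  m <- .bootstrap_matrix(smp, B, family, trim_method, trim_delta, seed)
  n_used <- colSums(!is.na(m))
  if (all(n_used == 0))
    stop("all bootstrap resamples failed", call. = FALSE)
  se <- apply(m, 2, stats::sd, na.rm = TRUE)
  names(se) <- sub(paste0("^", family, "\\."), "", names(se))
  names(n_used) <- names(se)
  list(se = se, n_used = n_used, n_failed = B - n_used,
       high_failure = any(n_used < 0.9 * B))
}

#' Normal-theory confidence interval
#'
#' \code{point +/- z * se} with z the standard-normal quantile at
#' \code{(1 + level)/2}.  For the relative risk the interval is built on
#' the log scale.
#'
#' @param point Point estimate.
#' @param se Standard error (>= 0).
#' @param level Confidence level in (0, 1).
#' @return Numeric vector \code{c(low, high)}.
#' @export
normal_ci <- function(point, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(low = point - z * se, high = point + z * se)
}
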
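# Data-generating process: calibrated synthetic super-population with ten
# correlated baseline covariates, a logistic treatment-selection model, a
# linear continuous-outcome model and a logistic binary-outcome model.

#' Model coefficients of the data-generating process
#'
#' The fixed slopes on covariates x1..x10: log odds ratios of the
#' treatment-selection model, main effects of the linear
#' continuous-outcome model, and log odds ratios of the logistic
#' binary-outcome model.
#'
#' @return Numeric vector of length 10.
#' @export
treatment_coefficients <- function() {
  log(c(1.1, 1.2, 1.5, 1.75, 2, 1.25, 1.5, 2, 0.8, 0.5))
}

#' @rdname treatment_coefficients
#' @export
continuous_outcome_coefficients <- function() {
  c(2.5, 2, 1.5, 1, 0.5, 2, 1, 5, 4, 3)
}

#' @rdname treatment_coefficients
#' @export
binary_outcome_coefficients <- function() {
  log(c(2, 1.75, 1.1, 1.5, 1.2, 2, 1.5, 1.1, 1.25, 2))
}

# Target prevalences of the five dichotomized covariates x6..x10.
.binary_covariate_prevalences <- c(0.10, 0.20, 0.30, 0.40, 0.50)

#' Generate the baseline covariate matrix
#'
#' Draws ten equicorrelated standard-normal covariates (pairwise correlation
#' 0.2).  The first five columns are kept continuous; columns 6--10 are
#' dichotomized at the 10th, 20th, 30th, 40th, and 50th percentiles of the
#' latent normal -- the indicator is 1 below the cut -- so their prevalences
#' are 10%, 20%, 30%, 40%, and 50%.  Thresholds are the exact quantiles
#' \code{qnorm(p)} rather than empirical sample quantiles, so the stated
#' prevalences hold in expectation for any n.
#'
#' @param n Number of subjects (positive integer).
#' @param seed Optional integer seed; when \code{NULL} the current RNG state
#'   is used.
#' @return An \code{n x 10} numeric matrix with columns \code{x1}..\code{x10};
#'   columns 6--10 contain only 0/1.
#' @export
#' @examples
#' X <- generate_covariates(1000, seed = 1)
#' colMeans(X[, 6:10])
generate_covariates <- function(n, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  p <- 10L
  rho <- 0.2
  Sigma <- matrix(rho, p, p)
  diag(Sigma) <- 1
  X <- matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma)
  for (j in seq_len(5L)) {
    thr <- stats::qnorm(.binary_covariate_prevalences[j])
    X[, 5L + j] <- as.numeric(X[, 5L + j] < thr)
  }
  colnames(X) <- paste0("x", 1:10)
  X
}

#' Linear predictor of the treatment-selection model
#'
#' Evaluates \code{alpha0 + sigma_scale * (beta . x)} with the fixed
#' treatment-model log odds ratios (log 1.1, log 1.2, log 1.5, log 1.75,
#' log 2 on the continuous covariates; log 1.25, log 1.5, log 2, log 0.8,
#' log 0.5 on the binary ones).  The propensity score is the inverse logit
#' of this value.  \code{sigma_scale} multiplies every slope and controls
#' the discrimination (c-statistic) of the treatment model; 1 gives the
#' main design.
#'
#' @param X Covariate matrix from [generate_covariates()].
#' @param alpha0 Intercept.
#' @param sigma_scale Positive scalar multiplying all slopes.
#' @return Numeric vector of linear predictors.
#' @export
treatment_linear_predictor <- function(X, alpha0 = 0, sigma_scale = 1) {
  stopifnot(is.matrix(X), ncol(X) == 10L, sigma_scale > 0)
  alpha0 + sigma_scale * drop(X %*% treatment_coefficients())
}

#' Calibrate the treatment-model intercept by bisection
#'
#' Finds the intercept for which the mean inverse-logit propensity over the
#' supplied population equals \code{target_prevalence}.  Calibration uses
#' expected probabilities, not realized treatment draws, which removes one
#' layer of Monte Carlo noise.
#'
#' @param X Covariate matrix.
#' @param target_prevalence Target treatment prevalence in (0, 1).
#' @param sigma_scale Slope multiplier of the treatment model.
#' @param tol Tolerance on the prevalence scale (default 1e-4).
#' @param bracket Numeric length-2 search interval for the intercept.
#' @param maxit Maximum bisection iterations.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_treatment_intercept <- function(X, target_prevalence,
                                          sigma_scale = 1, tol = 1e-4,
                                          bracket = c(-20, 20), maxit = 200L) {
  if (length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must lie in (0, 1)", call. = FALSE)
  eta <- sigma_scale * drop(X %*% treatment_coefficients())
  .bisect(function(a) mean(stats::plogis(a + eta)) - target_prevalence,
          bracket, tol, maxit, what = "treatment intercept")
}

#' Draw treatment assignments
#'
#' Independent Bernoulli draws with subject-specific probabilities.
#'
#' @param ps Vector of probabilities strictly inside (0, 1).
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector of the same length as `ps`.
#' @export
assign_treatment <- function(ps, seed = NULL) {
  if (any(ps <= 0 | ps >= 1))
    stop("propensities must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(length(ps), 1L, ps)
}

# Linear predictor of the continuous-outcome model, treatment effect excluded.
.continuous_outcome_lp <- function(X) {
  drop(X %*% continuous_outcome_coefficients())
}

#' Calibrate the continuous-outcome error variance
#'
#' Chooses the error variance so that the ten covariates explain 25% of the
#' outcome variance among untreated subjects: with linear predictor variance
#' v, the error variance is 3v, giving R-squared v / (v + 3v) = 0.25.
#'
#' @param X Covariate matrix with at least two rows.
#' @return The calibrated error variance (scalar, > 0).
#' @export
calibrate_error_variance <- function(X) {
  if (nrow(X) < 2L) stop("need at least two subjects", call. = FALSE)
  v <- stats::var(.continuous_outcome_lp(X))
  if (v <= 0)
    stop("degenerate outcome linear predictor: zero variance", call. = FALSE)
  3 * v
}

#' Generate continuous potential outcomes
#'
#' Potential outcomes under control and treatment from the linear model
#' Y = 2 Z + 2.5 x1 + 2 x2 + 1.5 x3 + x4 + 0.5 x5 + 2 x6 + x7 + 5 x8 +
#' 4 x9 + 3 x10 + e, with e ~ N(0, sigma2).  One noise draw per subject is
#' shared by both potential outcomes, so without interactions the
#' subject-level effect Y(1) - Y(0) is exactly 2.  With
#' \code{interactions = TRUE}, treatment-covariate interaction terms with
#' coefficients 0.25 times each main effect are added, making the effect
#' 2 + 0.25 * beta'x.
#'
#' @param X Covariate matrix.
#' @param sigma2 Error variance (> 0), typically from
#'   [calibrate_error_variance()].
#' @param interactions Logical; add treatment-covariate interactions.
#' @param seed Optional integer seed.
#' @return List with numeric vectors \code{y0} and \code{y1}.
#' @export
generate_continuous_potential_outcomes <- function(X, sigma2,
                                                   interactions = FALSE,
                                                   seed = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  lp <- .continuous_outcome_lp(X)
  eps <- stats::rnorm(nrow(X), 0, sqrt(sigma2))
  y0 <- lp + eps
  effect <- 2
  if (interactions)
    effect <- effect + 0.25 * lp
  list(y0 = y0, y1 = y0 + effect)
}

# Linear predictor of the binary-outcome model, intercept and treatment
# effect excluded.
.binary_outcome_lp <- function(X) {
  drop(X %*% binary_outcome_coefficients())
}

#' Calibrate the binary-outcome intercept by bisection
#'
#' Finds the intercept of the logistic outcome model so that the mean event
#' probability with every subject untreated equals \code{target_prev}.
#'
#' @param X Covariate matrix.
#' @param target_prev Target control-arm outcome prevalence in (0, 1).
#' @param tol Tolerance on the prevalence scale.
#' @param bracket Search interval for the intercept.
#' @param maxit Maximum bisection iterations.
#' @return The calibrated outcome intercept (scalar).
#' @export
calibrate_outcome_intercept <- function(X, target_prev = 0.2, tol = 1e-4,
                                        bracket = c(-20, 20), maxit = 200L) {
  if (target_prev <= 0 || target_prev >= 1)
    stop("`target_prev` must lie in (0, 1)", call. = FALSE)
  eta <- .binary_outcome_lp(X)
  .bisect(function(a) mean(stats::plogis(a + eta)) - target_prev,
          bracket, tol, maxit, what = "outcome intercept")
}

#' Calibrate the treatment log odds ratio of the binary-outcome model
#'
#' Given a calibrated outcome intercept, bisects the treatment log odds
#' ratio until the population mean of p(1) - p(0) (event probabilities with
#' Z = 1 versus Z = 0) equals \code{target_rd}.  Expected probabilities are
#' used rather than realized potential outcomes for numerical stability.
#'
#' @param X Covariate matrix.
#' @param alpha0_outcome Calibrated outcome intercept.
#' @param target_rd Target average risk difference (default -0.02).
#' @param interactions Logical; include treatment-covariate interactions
#'   (coefficients 0.25 times each main effect) in the treated-arm linear
#'   predictor.
#' @param tol Tolerance on the risk-difference scale.
#' @param bracket Search interval for the log odds ratio.
#' @param maxit Maximum bisection iterations.
#' @return The calibrated treatment log odds ratio (scalar).
#' @export
calibrate_treatment_log_odds <- function(X, alpha0_outcome,
                                         target_rd = -0.02,
                                         interactions = FALSE,
                                         tol = 1e-4,
                                         bracket = c(-20, 20), maxit = 200L) {
  eta0 <- alpha0_outcome + .binary_outcome_lp(X)
  inter <- if (interactions) 0.25 * .binary_outcome_lp(X) else 0
  p0 <- mean(stats::plogis(eta0))
  .bisect(function(a) mean(stats::plogis(eta0 + a + inter)) - p0 - target_rd,
          bracket, tol, maxit, what = "treatment log odds ratio")
}

#' Generate binary potential outcomes
#'
#' Event probabilities under control and treatment come from the logistic
#' outcome model; both potential outcomes are realized from one shared
#' uniform draw per subject (comonotone coupling).  The coupling leaves all
#' marginal means and hence all estimands untouched, but makes the null
#' case alpha_treat = 0 produce identical potential outcomes subject-wise.
#'
#' @param X Covariate matrix.
#' @param alpha0_outcome Calibrated outcome intercept.
#' @param alpha_treat Treatment log odds ratio.
#' @param interactions Logical; include treatment-covariate interactions.
#' @param seed Optional integer seed.
#' @return List with 0/1 vectors \code{y0}, \code{y1} and probability
#'   vectors \code{p0}, \code{p1}.
#' @export
generate_binary_potential_outcomes <- function(X, alpha0_outcome, alpha_treat,
                                               interactions = FALSE,
                                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta0 <- alpha0_outcome + .binary_outcome_lp(X)
  inter <- if (interactions) 0.25 * .binary_outcome_lp(X) else 0
  p0 <- stats::plogis(eta0)
  p1 <- stats::plogis(eta0 + alpha_treat + inter)
  u <- stats::runif(nrow(X))
  list(y0 = as.integer(u < p0), y1 = as.integer(u < p1), p0 = p0, p1 = p1)
}

#' Build a calibrated super-population
#'
#' Generates the full synthetic super-population for one scenario:
#' covariates, calibrated treatment model and true propensity scores,
#' realized treatment, and both continuous and binary potential outcomes
#' with all four calibration constants (treatment intercept, error
#' variance, outcome intercept, treatment log odds ratio).
#'
#' @param n Population size (the study design uses 1e6).
#' @param target_prevalence Treatment prevalence in (0, 1).
#' @param sigma_scale Treatment-model slope multiplier.
#' @param interactions Logical; treatment-covariate interactions in both
#'   outcome models.
#' @param seed Integer seed; the population is a deterministic function of
#'   the arguments.
#' @param target_control_prev Control-arm binary-outcome prevalence.
#' @param target_rd Average risk difference for the binary outcome.
#' @return An object of class \code{"super_population"}: a list with
#'   \code{covariates}, \code{true_ps}, \code{treatment}, potential
#'   outcomes (\code{y_cont_0}, \code{y_cont_1}, \code{y_bin_0},
#'   \code{y_bin_1}), observed outcomes (\code{y_cont}, \code{y_bin}), and
#'   a \code{calibration} list.
#' @export
#' @examples
#' pop <- make_super_population(5000, target_prevalence = 0.5, seed = 7)
#' mean(pop$treatment)
make_super_population <- function(n = 1e6, target_prevalence = 0.5,
                                  sigma_scale = 1, interactions = FALSE,
                                  seed = 1L,
                                  target_control_prev = 0.2,
                                  target_rd = -0.02) {
  set.seed(seed)
  X <- generate_covariates(n)
  a0t <- calibrate_treatment_intercept(X, target_prevalence, sigma_scale)
  ps <- stats::plogis(treatment_linear_predictor(X, a0t, sigma_scale))
  Z <- assign_treatment(ps)
  sigma2 <- calibrate_error_variance(X)
  yc <- generate_continuous_potential_outcomes(X, sigma2, interactions)
  a0o <- calibrate_outcome_intercept(X, target_control_prev)
  at <- calibrate_treatment_log_odds(X, a0o, target_rd, interactions)
  yb <- generate_binary_potential_outcomes(X, a0o, at, interactions)
  structure(list(
    covariates = X,
    true_ps = ps,
    treatment = Z,
    y_cont_0 = yc$y0, y_cont_1 = yc$y1,
    y_bin_0 = yb$y0, y_bin_1 = yb$y1,
    y_cont = ifelse(Z == 1L, yc$y1, yc$y0),
    y_bin = ifelse(Z == 1L, yb$y1, yb$y0),
    calibration = list(alpha0_treat = a0t,
                       alpha0_outcome = a0o,
                       alpha_treat = at,
                       sigma2_error = sigma2),
    target_prevalence = target_prevalence,
    sigma_scale = sigma_scale,
    interactions = interactions,
    seed = seed
  ), class = "super_population")
}

#' @export
print.super_population <- function(x, ...) {
  cat("Super-population:", length(x$true_ps), "subjects\n")
  cat("  treatment prevalence:", signif(mean(x$treatment), 4),
      "(target", x$target_prevalence, ")\n")
  cat("  sigma_scale:", x$sigma_scale,
      " interactions:", x$interactions, "\n")
  cal <- x$calibration
  cat(sprintf("  alpha0_treat = %.4f, alpha0_outcome = %.4f,\n",
              cal$alpha0_treat, cal$alpha0_outcome))
  cat(sprintf("  alpha_treat = %.4f, sigma2_error = %.4f\n",
              cal$alpha_treat, cal$sigma2_error))
  invisible(x)
}

#' True estimands for a weight family
#'
#' Computes the population value targeted by each weight family as a
#' tilting-function average of the potential-outcome contrast: with
#' h(x) = 1 (ATE), e(x) (ATT), min(e, 1-e) (MW) or e(1-e) (OW), the
#' weighted means are sum(h * Y(z)) / sum(h), combined as a difference
#' (mean difference and risk difference) and a log ratio of proportions
#' (log relative risk).  True propensity scores are used.
#'
#' @param pop A [make_super_population()] object.
#' @param family One of \code{"ATE"}, \code{"ATT"}, \code{"MW"},
#'   \code{"OW"}.
#' @return List with \code{mean_diff}, \code{risk_diff}, \code{log_rr}.
#' @export
true_estimands <- function(pop, family = c("ATE", "ATT", "MW", "OW")) {
  family <- match.arg(family)
  e <- pop$true_ps
  h <- switch(family,
              ATE = rep(1, length(e)),
              ATT = e,
              MW  = pmin(e, 1 - e),
              OW  = e * (1 - e))
  sh <- sum(h)
  if (!is.finite(sh) || sh <= .Machine$double.eps * length(e))
    stop("degenerate tilting function: estimand undefined", call. = FALSE)
  mu <- function(y) sum(h * y) / sh
  m1c <- mu(pop$y_cont_1); m0c <- mu(pop$y_cont_0)
  m1b <- mu(pop$y_bin_1);  m0b <- mu(pop$y_bin_0)
  list(mean_diff = m1c - m0c,
       risk_diff = m1b - m0b,
       log_rr = log(m1b / m0b))
}

#' Draw a study sample from a super-population
#'
#' Samples \code{n} subjects without replacement, mirroring the study's
#' repeated drawing of random samples from a fixed super-population.
#'
#' @param pop A super-population.
#' @param n Sample size (at most the population size).
#' @param seed Optional integer seed.
#' @return An object of class \code{"ps_sample"}: list with \code{X},
#'   \code{Z}, \code{y_cont}, \code{y_bin}, \code{true_ps}, \code{idx}.
#' @export
draw_sample <- function(pop, n, seed = NULL) {
  N <- length(pop$true_ps)
  if (n > N) stop("sample size exceeds population size", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(N, n)
  structure(list(X = pop$covariates[idx, , drop = FALSE],
                 Z = pop$treatment[idx],
                 y_cont = pop$y_cont[idx],
                 y_bin = pop$y_bin[idx],
                 true_ps = pop$true_ps[idx],
                 idx = idx), class = "ps_sample")
}

# Subset a ps_sample by row indices (used by trimming and the bootstrap).
.subset_sample <- function(smp, idx) {
  structure(list(X = smp$X[idx, , drop = FALSE],
                 Z = smp$Z[idx],
                 y_cont = smp$y_cont[idx],
                 y_bin = smp$y_bin[idx],
                 true_ps = smp$true_ps[idx],
                 idx = smp$idx[idx]), class = "ps_sample")
}

# Bisection on a monotone-in-expectation criterion f with f(lo) and f(hi)
# of opposite sign; returns the midpoint once |f| < tol.
.bisect <- function(f, bracket, tol, maxit, what = "parameter") {
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop(sprintf(
      "calibration failure for %s: criterion not bracketed on [%g, %g] (f = %g, %g)",
      what, lo, hi, flo, fhi), call. = FALSE)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm * flo < 0) {
      hi <- mid
    } else {
      lo <- mid; flo <- fm
    }
  }
  stop(sprintf("calibration failure for %s: no convergence in %d iterations",
               what, maxit), call. = FALSE)
}
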
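# Covariate balance (weighted standardized mean differences), Kish
# effective sample size, and distributional-overlap diagnostics.

# Weighted mean and weighted variance with the reliability-weight
# correction sum(w (x - m)^2) / (sum(w) - sum(w^2)/sum(w)); reduces to the
# usual n - 1 divisor at unit weights.
.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) return(0)
  sum(w * (x - m)^2) / denom
}

#' Weighted standardized mean difference
#'
#' (weighted treated mean - weighted control mean) divided by the square
#' root of the average of the two weighted group variances.  With unit
#' weights this is the classical two-group standardized difference.  A
#' zero pooled variance returns 0 when the means agree and Inf (signed)
#' otherwise.
#'
#' @param x Covariate vector.
#' @param Z 0/1 treatment vector.
#' @param w Weight vector.
#' @return The standardized difference (not absolute).
#' @export
weighted_smd <- function(x, Z, w) {
  i1 <- Z == 1; i0 <- Z == 0
  if (!(sum(w[i1]) > 0) || !(sum(w[i0]) > 0))
    stop("a group has non-positive total weight", call. = FALSE)
  m1 <- .wmean(x[i1], w[i1]); m0 <- .wmean(x[i0], w[i0])
  v1 <- .wvar(x[i1], w[i1]); v0 <- .wvar(x[i0], w[i0])
  pooled <- sqrt((v1 + v0) / 2)
  if (pooled == 0) {
    if (m1 == m0) return(0)
    return(sign(m1 - m0) * Inf)
  }
  (m1 - m0) / pooled
}

#' Kish effective sample size
#'
#' Per treatment group, (sum w)^2 / sum(w^2): the size of an equally
#' weighted sample with the same variance.  Equals the group size exactly
#' when weights are constant within the group.
#'
#' @param w Weight vector.
#' @param Z 0/1 treatment vector.
#' @return Named vector \code{c(ess1, ess0, ess_total)}.
#' @export
effective_sample_size <- function(w, Z) {
  ess <- function(wg) sum(wg)^2 / sum(wg^2)
  e1 <- ess(w[Z == 1]); e0 <- ess(w[Z == 0])
  c(ess1 = e1, ess0 = e0, ess_total = e1 + e0)
}

#' Balance report for a weighted sample
#'
#' Weighted standardized mean difference per covariate, their maximum
#' absolute value, and the effective sample sizes.
#'
#' @param X Covariate matrix.
#' @param Z 0/1 treatment vector.
#' @param w Weight vector.
#' @return Object of class \code{"balance_report"}: list with
#'   \code{smd_per_covariate}, \code{max_abs_smd}, \code{ess}.
#' @export
balance_report <- function(X, Z, w) {
  smd <- apply(X, 2, weighted_smd, Z = Z, w = w)
  structure(list(smd_per_covariate = smd,
                 max_abs_smd = max(abs(smd)),
                 ess = effective_sample_size(w, Z)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("max |weighted SMD|:", format(x$max_abs_smd, digits = 4), "\n")
  cat("effective sample size: treated", format(x$ess[["ess1"]], digits = 5),
      "control", format(x$ess[["ess0"]], digits = 5),
      "total", format(x$ess[["ess_total"]], digits = 5), "\n")
  invisible(x)
}

#' @export
format.balance_report <- function(x, ...) {
  paste(c(sprintf("%s\t%.6g", names(x$smd_per_covariate), x$smd_per_covariate),
          sprintf("max_abs_smd\t%.6g", x$max_abs_smd),
          sprintf("%s\t%.6g", names(x$ess), x$ess)), collapse = "\n")
}

#' Overlapping coefficient of two propensity-score distributions
#'
#' One minus the integrated minimum of two Gaussian kernel density
#' estimates (Silverman bandwidth per group) evaluated on a common
#' 512-point grid over \[0, 1\], integrated by the trapezoid rule.  Under
#' this convention 0 denotes perfect overlap and 1 denotes none.
#'
#' @param ps_treated Propensity scores of treated subjects (length >= 2).
#' @param ps_control Propensity scores of control subjects (length >= 2).
#' @return A value in \[0, 1\].
#' @export
overlapping_coefficient <- function(ps_treated, ps_control) {
  if (length(ps_treated) < 2L || length(ps_control) < 2L)
    stop("each group needs at least two subjects", call. = FALSE)
  if (stats::var(ps_treated) == 0 || stats::var(ps_control) == 0)
    stop("degenerate (zero-variance) group", call. = FALSE)
  d1 <- stats::density(ps_treated, bw = "nrd0", kernel = "gaussian",
                       from = 0, to = 1, n = 512)
  d0 <- stats::density(ps_control, bw = "nrd0", kernel = "gaussian",
                       from = 0, to = 1, n = 512)
  y <- pmin(d1$y, d0$y)
  dx <- diff(d1$x)
  ovl <- sum((y[-1] + y[-length(y)]) / 2 * dx)
  1 - min(max(ovl, 0), 1)
}
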
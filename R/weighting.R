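# Weight families derived from the propensity score, and propensity-score
# trimming (fixed thresholds and Crump's sample-optimal threshold).

#' Compute propensity-score weights
#'
#' Four weight families, with e the propensity score:
#' \describe{
#'   \item{ATE}{treated 1/e, control 1/(1-e) (inverse probability of
#'     treatment weights).}
#'   \item{ATT}{treated 1, control e/(1-e).}
#'   \item{MW}{matching weights min(e, 1-e)/e (treated) and
#'     min(e, 1-e)/(1-e) (control).}
#'   \item{OW}{overlap weights 1-e (treated) and e (control).}
#' }
#'
#' @param ps Propensity scores strictly inside (0, 1).
#' @param Z 0/1 treatment vector.
#' @param family One of \code{"ATE"}, \code{"ATT"}, \code{"MW"},
#'   \code{"OW"}.
#' @return Numeric weight vector with attribute \code{family}.
#' @export
#' @examples
#' compute_weights(c(0.25, 0.25), c(1, 0), "ATE")
compute_weights <- function(ps, Z, family = c("ATE", "ATT", "MW", "OW")) {
  family <- match.arg(family)
  if (any(ps <= 0 | ps >= 1))
    stop("propensity scores must lie strictly in (0, 1)", call. = FALSE)
  w <- switch(family,
              ATE = ifelse(Z == 1, 1 / ps, 1 / (1 - ps)),
              ATT = ifelse(Z == 1, 1, ps / (1 - ps)),
              MW  = pmin(ps, 1 - ps) / ifelse(Z == 1, ps, 1 - ps),
              OW  = ifelse(Z == 1, 1 - ps, ps))
  attr(w, "family") <- family
  w
}

#' Fixed-threshold propensity-score trimming
#'
#' Keeps subjects whose propensity score lies in the closed interval
#' \[delta, 1 - delta\]; subjects strictly below delta or strictly above
#' 1 - delta are excluded.  \code{delta = 0} keeps everyone.
#'
#' @param ps Propensity-score vector.
#' @param delta Trimming threshold in \[0, 0.5).
#' @return List with \code{kept_indices}, \code{threshold},
#'   \code{method} (\code{"none"} when delta = 0, else \code{"fixed"}).
#' @export
trim_fixed <- function(ps, delta) {
  if (length(delta) != 1L || delta < 0 || delta >= 0.5)
    stop("`delta` must lie in [0, 0.5)", call. = FALSE)
  kept <- which(ps >= delta & ps <= 1 - delta)
  list(kept_indices = kept,
       threshold = delta,
       method = if (delta == 0) "none" else "fixed")
}

#' Crump's optimal trimming threshold
#'
#' The smallest alpha in \[0, 0.5\] satisfying
#' \deqn{1/(\alpha(1-\alpha)) = 2\,\mathrm{mean}\{1/(e_i(1-e_i)) :
#'   e_i(1-e_i) \ge \alpha(1-\alpha)\},}
#' solved exactly by scanning the sorted sample values of e(1-e) as
#' candidate cut levels: with the retained set fixed to the k largest
#' values of e(1-e), the candidate level is the reciprocal of twice their
#' mean reciprocal, and it is a solution when it falls inside the interval
#' of levels for which exactly those k subjects are retained.  Ties in
#' e(1-e) are included in the retained set together.
#'
#' @param ps Propensity scores strictly in (0, 1), length >= 2.
#' @return The threshold alpha (scalar in \[0, 0.5\]).
#' @export
#' @examples
#' crump_threshold(rep(0.5, 10))  # (1 - sqrt(0.5)) / 2
crump_threshold <- function(ps) {
  if (length(ps) < 2L || any(ps <= 0 | ps >= 1))
    stop("need >= 2 propensity scores strictly in (0, 1)", call. = FALSE)
  g <- sort(ps * (1 - ps), decreasing = TRUE)
  m <- cumsum(1 / g) / seq_along(g)   # mean of 1/g over the k largest g
  lam <- 1 / (2 * m)                  # candidate cut level per retained set
  lo <- c(g[-1L], 0)                  # retained set is top-k for level in (g[k+1], g[k]]
  ok <- lam > lo & lam <= g
  if (!any(ok))
    stop("Crump threshold failure: no self-consistent cut level", call. = FALSE)
  lam_star <- min(lam[ok])
  lam_star <- min(lam_star, 0.25)
  (1 - sqrt(max(0, 1 - 4 * lam_star))) / 2
}

#' Trim a sample and re-estimate the propensity score
#'
#' The full trimming workflow: fit the propensity model on the whole
#' sample, trim on the fitted scores (fixed delta or Crump's threshold
#' estimated from those scores), then re-fit the propensity model on the
#' retained subjects.  All downstream weights should use the re-fitted
#' scores.  With \code{method = "none"} the sample is untouched and the
#' single fit is returned.
#'
#' @param smp A \code{"ps_sample"} (see [draw_sample()]).
#' @param method \code{"none"}, \code{"fixed"}, or \code{"crump"}.
#' @param delta Threshold for \code{method = "fixed"}.
#' @return List with \code{sample} (possibly trimmed), \code{fit} (the
#'   propensity fit to use downstream), \code{threshold},
#'   \code{kept_indices}, \code{method}.
#' @export
apply_trimming_workflow <- function(smp,
                                    method = c("none", "fixed", "crump"),
                                    delta = 0) {
  method <- match.arg(method)
  fit0 <- fit_propensity(smp$X, smp$Z)
  if (method == "none" || (method == "fixed" && delta == 0)) {
    return(list(sample = smp, fit = fit0, threshold = 0,
                kept_indices = seq_along(smp$Z), method = method))
  }
  thr <- if (method == "crump") crump_threshold(fit0$fitted_ps) else delta
  tr <- trim_fixed(fit0$fitted_ps, thr)
  kept <- tr$kept_indices
  sub <- .subset_sample(smp, kept)
  if (sum(sub$Z == 1) == 0L || sum(sub$Z == 0) == 0L)
    stop(structure(class = c("pswvar_fit_failure", "error", "condition"),
                   list(message = "trimming removed an entire treatment group",
                        call = NULL)))
  fit1 <- fit_propensity(sub$X, sub$Z)
  list(sample = sub, fit = fit1, threshold = thr,
       kept_indices = kept, method = method)
}
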
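# Shared fixtures (built lazily, cached across test files) and the
# independent oracles used to cross-check the implementation.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# Moderate super-population for unit tests.
small_pop <- function() {
  cached("small_pop", function()
    make_super_population(20000, 0.5, seed = 5))
}

# Full-size covariate matrix for the calibration checks.
big_X <- function() {
  cached("big_X", function() generate_covariates(1e6, seed = 42))
}

# A sample on which the propensity fit is clean and no fitted score sits
# near 0.5 (so matching-weight derivatives are finite-differencable).
fd_sample <- function() {
  cached("fd_sample", function() draw_sample(small_pop(), 120, seed = 2))
}

# Stacked estimating equations averaged over subjects, as an explicit
# function of theta = (beta, mu1, mu0); the finite-difference oracle for
# the sandwich bread matrix differentiates this numerically.
psi_bar <- function(theta, X, Z, y, family) {
  p <- ncol(X) + 1L
  beta <- theta[1:p]; mu1 <- theta[p + 1L]; mu0 <- theta[p + 2L]
  Xd <- cbind(1, X)
  e <- stats::plogis(drop(Xd %*% beta))
  wf <- pswvar:::.weight_funs(family)
  w <- ifelse(Z == 1, wf$w1(e), wf$w0(e))
  c(colMeans(Xd * (Z - e)),
    mean(w * (Z == 1) * (y - mu1)),
    mean(w * (Z == 0) * (y - mu0)))
}

fd_bread <- function(theta, X, Z, y, family, h = 1e-6) {
  k <- length(theta)
  A <- matrix(0, k, k)
  for (j in seq_len(k)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    A[, j] <- -(psi_bar(tp, X, Z, y, family) -
                  psi_bar(tm, X, Z, y, family)) / (2 * h)
  }
  A
}

# All-pairs concordance count (quadratic; fixture scale only).
c_statistic_bruteforce <- function(ps, Z) {
  p1 <- ps[Z == 1]; p0 <- ps[Z == 0]
  tot <- 0
  for (a in p1) tot <- tot + sum(a > p0) + 0.5 * sum(a == p0)
  tot / (length(p1) * length(p0))
}

# Grid search for the Crump cut level: smallest alpha on a fine grid at
# which the retained-set condition 1/(a(1-a)) <= 2 mean{1/g : g >= a(1-a)}
# first holds.
crump_grid_oracle <- function(ps, n_grid = 10000L) {
  g <- ps * (1 - ps)
  for (a in seq(1e-5, 0.4999, length.out = n_grid)) {
    lam <- a * (1 - a)
    keep <- g >= lam
    if (!any(keep)) next
    if (1 / lam <= 2 * mean(1 / g[keep])) return(a)
  }
  NA_real_
}

# Histogram-based overlapping coefficient on a common set of breaks.
ovl_histogram_oracle <- function(x1, x0, breaks = seq(0, 1, by = 0.02)) {
  h1 <- hist(x1, breaks = breaks, plot = FALSE)$density
  h0 <- hist(x0, breaks = breaks, plot = FALSE)$density
  1 - sum(pmin(h1, h0) * diff(breaks))
}
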
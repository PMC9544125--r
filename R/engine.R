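# Simulation engine: per-replicate orchestration, scenario grids, and the
# study's performance metrics (SE ratio, empirical coverage, significance
# bands).

.families <- c("ATE", "ATT", "MW", "OW")
.estimands <- c("mean_diff", "risk_diff", "log_rr")

#' Scenario configuration
#'
#' Bundles and validates the knobs of one simulation scenario.
#'
#' @param n_sample Sample size drawn per replicate.
#' @param target_prevalence Treatment prevalence in (0, 1).
#' @param sigma_scale Treatment-model slope multiplier (1 = main design).
#' @param interactions Logical; treatment-covariate interactions in the
#'   outcome models.
#' @param trim_method \code{"none"}, \code{"fixed"}, or \code{"crump"}.
#' @param trim_delta Fixed trimming threshold in \[0, 0.5).
#' @param n_replicates Monte Carlo replicates (study default 1000).
#' @param n_bootstrap Bootstrap resamples per replicate (study default
#'   200).
#' @param seed Master seed for the scenario.
#' @param pop_size Super-population size (study default 1e6).
#' @param level Confidence level.
#' @return Object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_sample, target_prevalence,
                            sigma_scale = 1, interactions = FALSE,
                            trim_method = c("none", "fixed", "crump"),
                            trim_delta = 0,
                            n_replicates = 1000L, n_bootstrap = 200L,
                            seed = 1L, pop_size = 1e6, level = 0.95) {
  trim_method <- match.arg(trim_method)
  stopifnot(n_sample >= 1, n_sample <= pop_size,
            target_prevalence > 0, target_prevalence < 1,
            sigma_scale > 0, trim_delta >= 0, trim_delta < 0.5,
            n_replicates >= 1, n_bootstrap >= 0,
            level > 0, level < 1)
  structure(list(n_sample = as.integer(n_sample),
                 target_prevalence = target_prevalence,
                 sigma_scale = sigma_scale,
                 interactions = isTRUE(interactions),
                 trim_method = trim_method,
                 trim_delta = trim_delta,
                 n_replicates = as.integer(n_replicates),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed),
                 pop_size = pop_size,
                 level = level),
            class = "scenario_config")
}

# Deterministic seed derivation decoupling scenarios and replicates.
# Lehmer-style mixing mod 2^31 - 1, exact in double arithmetic.
.mix_seed <- function(master, scenario, replicate) {
  M <- 2147483647
  x <- (abs(master) %% M)
  x <- (x * 48271 + 1) %% M
  x <- ((x + scenario) * 48271 + 1) %% M
  x <- ((x + replicate) * 48271 + 1) %% M
  as.integer(x)
}

#' Run one simulation replicate
#'
#' Draws a sample of the configured size without replacement from the
#' super-population, applies the trimming workflow, fits the propensity
#' model, and for each of the four weight families computes the three
#' point estimates, the asymptotic (sandwich) and bootstrap SEs,
#' normal-theory confidence intervals and their coverage of the true
#' estimands, plus balance and effective-sample-size diagnostics.
#' Estimation failures do not abort: the record carries a failure flag.
#'
#' @param pop Super-population matching the scenario.
#' @param config A [scenario_config()].
#' @param replicate_seed Integer seed for this replicate.
#' @param truths Named list of [true_estimands()] results per family;
#'   computed from \code{pop} when missing.
#' @return One-row data.frame (a \code{ReplicateRecord}).
#' @export
run_replicate <- function(pop, config, replicate_seed, truths = NULL) {
  if (is.null(truths))
    truths <- sapply(.families, function(f) true_estimands(pop, f),
                     simplify = FALSE)
  set.seed(replicate_seed)
  smp <- draw_sample(pop, config$n_sample)
  rec <- list(replicate_seed = replicate_seed, failed = FALSE,
              failure_message = NA_character_, trim_threshold = NA_real_)
  z <- stats::qnorm((1 + config$level) / 2)
  res <- tryCatch({
    wf <- apply_trimming_workflow(smp, config$trim_method, config$trim_delta)
    s <- wf$sample; fit <- wf$fit
    rec$trim_threshold <- wf$threshold
    boot <- NULL
    if (config$n_bootstrap >= 2L)
      boot <- .bootstrap_matrix(smp, config$n_bootstrap, .families,
                                config$trim_method, config$trim_delta)
    for (fam in .families) {
      w <- compute_weights(fit$fitted_ps, s$Z, fam)
      bal <- balance_report(s$X, s$Z, w)
      rec[[paste0("max_abs_smd.", fam)]] <- bal$max_abs_smd
      rec[[paste0("ess_total.", fam)]] <- bal$ess[["ess_total"]]
      muc <- weighted_group_means(s$y_cont, s$Z, w)
      mub <- weighted_group_means(s$y_bin, s$Z, w)
      # NA-tolerant per estimand: a zero-event group invalidates only the
      # log relative risk for this replicate, not the whole record
      pts <- list(mean_diff = muc[["mu1"]] - muc[["mu0"]],
                  risk_diff = mub[["mu1"]] - mub[["mu0"]],
                  log_rr = if (mub[["mu1"]] > 0 && mub[["mu0"]] > 0)
                    log(mub[["mu1"]] / mub[["mu0"]]) else NA_real_)
      sea <- c(sandwich_variance(s$X, s$Z, s$y_cont, fit, fam,
                                 "continuous")$se,
               sandwich_variance(s$X, s$Z, s$y_bin, fit, fam,
                                 "binary")$se)
      for (est in .estimands) {
        key <- paste(fam, est, sep = ".")
        pt <- pts[[est]]
        tv <- truths[[fam]][[est]]
        rec[[paste0("point.", key)]] <- pt
        rec[[paste0("se_asym.", key)]] <- sea[[est]]
        rec[[paste0("cover_asym.", key)]] <-
          as.integer(abs(pt - tv) <= z * sea[[est]])
        if (!is.null(boot)) {
          bvals <- boot[, key]
          nb <- sum(!is.na(bvals))
          seb <- if (nb >= 2L) stats::sd(bvals, na.rm = TRUE) else NA_real_
          rec[[paste0("se_boot.", key)]] <- seb
          rec[[paste0("cover_boot.", key)]] <-
            if (is.na(seb)) NA_integer_ else
              as.integer(abs(pt - tv) <= z * seb)
          rec[[paste0("n_boot.", key)]] <- nb
        }
      }
    }
    rec
  }, error = function(e) {
    rec$failed <- TRUE
    rec$failure_message <- conditionMessage(e)
    rec
  })
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Ratio of mean estimated SE to empirical SD
#'
#' The study's accuracy metric for a variance estimator: the mean of the
#' estimated SEs across replicates divided by the standard deviation
#' (divisor R - 1) of the point estimates across the same replicates.
#' A value of 1 means the SE correctly estimates the sampling SD.
#'
#' @param se_values Estimated SEs across replicates.
#' @param points Point estimates across the same replicates.
#' @return The ratio (scalar).
#' @export
se_ratio <- function(se_values, points) {
  keep <- !is.na(se_values) & !is.na(points)
  if (sum(keep) < 2L)
    stop("need at least 2 successful replicates", call. = FALSE)
  s <- stats::sd(points[keep])
  if (s == 0) stop("zero empirical SD: ratio undefined", call. = FALSE)
  mean(se_values[keep]) / s
}

#' Empirical coverage rate
#'
#' Proportion of replicates whose confidence interval contained the true
#' value, over successful replicates.
#'
#' @param covered 0/1 (or logical) coverage indicators; NA entries are
#'   dropped.
#' @return Coverage in \[0, 1\].
#' @export
coverage_rate <- function(covered) {
  covered <- covered[!is.na(covered)]
  if (length(covered) < 1L) stop("no successful replicates", call. = FALSE)
  mean(covered)
}

#' Significance band around the nominal coverage rate
#'
#' Normal-theory band outside which an empirical coverage rate over R
#' replicates differs significantly (5% level) from the nominal rate:
#' nominal +/- z_0.975 sqrt(nominal (1 - nominal) / R).  At R = 1000 and
#' nominal 0.95 this is (0.9365, 0.9635).
#'
#' @param R Number of simulation replicates.
#' @param nominal Nominal coverage rate.
#' @return Numeric vector \code{c(low, high)}.
#' @export
coverage_significance_band <- function(R, nominal = 0.95) {
  stopifnot(R >= 1, nominal > 0, nominal < 1)
  half <- stats::qnorm(0.975) * sqrt(nominal * (1 - nominal) / R)
  c(low = nominal - half, high = nominal + half)
}

#' Summarize replicate records into scenario metrics
#'
#' Per (family, estimand, SE method): the SE ratio and empirical coverage.
#' Per family: mean maximum absolute weighted SMD and mean effective
#' sample size.  Failed replicates are excluded pairwise, with counts
#' reported.
#'
#' @param records data.frame of stacked [run_replicate()] rows.
#' @param config The scenario's [scenario_config()].
#' @return Object of class \code{"scenario_summary"}: list with
#'   \code{metrics} (data.frame: family, estimand, method, se_ratio,
#'   coverage, n), \code{balance} (data.frame per family), \code{n_failed},
#'   \code{n_replicates}, \code{config}.
#' @export
summarize_replicates <- function(records, config = NULL) {
  ok <- !records$failed
  n_failed <- sum(!ok)
  rec <- records[ok, , drop = FALSE]
  methods <- c("asym", "boot")
  rows <- list()
  for (fam in .families) for (est in .estimands) {
    key <- paste(fam, est, sep = ".")
    pts <- rec[[paste0("point.", key)]]
    for (m in methods) {
      secol <- paste0("se_", m, ".", key)
      if (is.null(rec[[secol]])) next
      ses <- rec[[secol]]
      cov <- rec[[paste0("cover_", m, ".", key)]]
      keep <- !is.na(ses) & !is.na(pts)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, estimand = est,
        method = if (m == "asym") "asymptotic" else "bootstrap",
        se_ratio = if (sum(keep) >= 2L) se_ratio(ses, pts) else NA_real_,
        coverage = coverage_rate(cov),
        n = sum(keep), stringsAsFactors = FALSE)
    }
  }
  balance <- do.call(rbind, lapply(.families, function(fam) data.frame(
    family = fam,
    mean_max_abs_smd = mean(rec[[paste0("max_abs_smd.", fam)]]),
    mean_ess_total = mean(rec[[paste0("ess_total.", fam)]]),
    stringsAsFactors = FALSE)))
  structure(list(metrics = do.call(rbind, rows),
                 balance = balance,
                 n_failed = n_failed,
                 n_replicates = nrow(records),
                 config = config),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("Scenario summary over", x$n_replicates, "replicates (",
      x$n_failed, "failed )\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Run a full scenario
#'
#' Builds (or reuses) the calibrated super-population, computes the true
#' estimands for every weight family, runs all replicates with
#' deterministically derived seeds, and summarizes them.
#'
#' @param config A [scenario_config()].
#' @param pop Optional pre-built super-population (reused across sample
#'   sizes within a prevalence/sigma combination); built from the config
#'   when missing.
#' @param scenario_id Integer used in seed derivation.
#' @return List with \code{summary}, \code{records}, \code{truths},
#'   \code{config}.
#' @export
run_scenario <- function(config, pop = NULL, scenario_id = 1L) {
  if (is.null(pop))
    pop <- make_super_population(config$pop_size, config$target_prevalence,
                                 config$sigma_scale, config$interactions,
                                 seed = .mix_seed(config$seed, scenario_id, 0L))
  truths <- sapply(.families, function(f) true_estimands(pop, f),
                   simplify = FALSE)
  records <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r)
    run_replicate(pop, config, .mix_seed(config$seed, scenario_id, r),
                  truths)))
  list(summary = summarize_replicates(records, config),
       records = records, truths = truths, config = config)
}

#' Scenario grids of the study designs
#'
#' \describe{
#'   \item{main}{5 sample sizes (250, 500, 1000, 5000, 10000) x 9
#'     treatment prevalences (0.1..0.9) = 45 scenarios.}
#'   \item{interactions}{the main grid with treatment-covariate
#'     interactions in the outcome models.}
#'   \item{overlap}{n = 1000, prevalence 0.5, slope multiplier sigma in
#'     (0.4, 0.5, 0.6, 0.7, 0.8, 1, 1.2, 1.4, 1.6) = 9 scenarios.}
#'   \item{trimming}{the overlap grid crossed with trimming delta in
#'     (0, 0.01, 0.02, 0.05, 0.10) plus Crump's threshold = 54 scenarios.}
#' }
#'
#' @param name Grid name.
#' @return data.frame with one row per scenario: \code{n_sample},
#'   \code{target_prevalence}, \code{sigma_scale}, \code{interactions},
#'   \code{trim_method}, \code{trim_delta}.
#' @export
scenario_grid <- function(name = c("main", "interactions", "overlap",
                                   "trimming")) {
  name <- match.arg(name)
  sizes <- c(250L, 500L, 1000L, 5000L, 10000L)
  prevs <- seq(0.1, 0.9, by = 0.1)
  sigmas <- c(0.4, 0.5, 0.6, 0.7, 0.8, 1, 1.2, 1.4, 1.6)
  g <- switch(name,
    main = ,
    interactions = expand.grid(n_sample = sizes, target_prevalence = prevs,
                               sigma_scale = 1, trim_method = "none",
                               trim_delta = 0, stringsAsFactors = FALSE),
    overlap = expand.grid(n_sample = 1000L, target_prevalence = 0.5,
                          sigma_scale = sigmas, trim_method = "none",
                          trim_delta = 0, stringsAsFactors = FALSE),
    trimming = {
      fixed <- expand.grid(n_sample = 1000L, target_prevalence = 0.5,
                           sigma_scale = sigmas, trim_method = "fixed",
                           trim_delta = c(0, 0.01, 0.02, 0.05, 0.10),
                           stringsAsFactors = FALSE)
      fixed$trim_method[fixed$trim_delta == 0] <- "none"
      crump <- expand.grid(n_sample = 1000L, target_prevalence = 0.5,
                           sigma_scale = sigmas, trim_method = "crump",
                           trim_delta = 0, stringsAsFactors = FALSE)
      rbind(fixed, crump)
    })
  g$interactions <- name == "interactions"
  g$scenario_id <- seq_len(nrow(g))
  g
}

#' Run a grid of scenarios
#'
#' Runs every scenario of a named grid (or a custom data.frame in the
#' [scenario_grid()] format) and returns a tidy table of metrics: one row
#' per scenario x family x estimand x SE method.  The super-population is
#' generated once per (prevalence, sigma_scale, interactions) combination
#' and shared across sample sizes.  Summaries can be written incrementally
#' so long runs are resumable.
#'
#' @param grid Grid name or data.frame.
#' @param n_replicates,n_bootstrap Per-scenario Monte Carlo sizes (study
#'   defaults 1000 and 200; reduce for exploratory runs).
#' @param seed Master seed.
#' @param pop_size Super-population size.
#' @param out Optional path to a TSV written incrementally; scenarios
#'   already present in the file are skipped on re-run.
#' @return data.frame of stacked metric rows, with scenario columns.
#' @export
run_grid <- function(grid = "main", n_replicates = 1000L,
                     n_bootstrap = 200L, seed = 1L, pop_size = 1e6,
                     out = NULL) {
  g <- if (is.character(grid)) scenario_grid(grid) else grid
  done <- integer(0)
  if (!is.null(out) && file.exists(out)) {
    prev <- utils::read.delim(out)
    done <- unique(prev$scenario_id)
  }
  pops <- new.env(parent = emptyenv())
  results <- if (length(done)) list(prev) else list()
  for (i in seq_len(nrow(g))) {
    if (g$scenario_id[i] %in% done) next
    cfg <- scenario_config(g$n_sample[i], g$target_prevalence[i],
                           g$sigma_scale[i], g$interactions[i],
                           g$trim_method[i], g$trim_delta[i],
                           n_replicates, n_bootstrap, seed,
                           pop_size = pop_size)
    pop_key <- paste(g$target_prevalence[i], g$sigma_scale[i],
                     g$interactions[i], sep = "_")
    if (is.null(pops[[pop_key]])) {
      # pop seed derives from the scenario parameters, not visit order
      pop_tag <- round(g$target_prevalence[i] * 100 +
                         g$sigma_scale[i] * 10000 +
                         1e6 * g$interactions[i])
      pops[[pop_key]] <- make_super_population(
        pop_size, g$target_prevalence[i], g$sigma_scale[i],
        g$interactions[i], seed = .mix_seed(seed, pop_tag, 0L))
    }
    res <- run_scenario(cfg, pops[[pop_key]],
                        scenario_id = g$scenario_id[i])
    tab <- res$summary$metrics
    tab <- cbind(g[rep(i, nrow(tab)), , drop = FALSE], tab,
                 row.names = NULL)
    results[[length(results) + 1L]] <- tab
    if (!is.null(out))
      utils::write.table(do.call(rbind, results), out, sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  do.call(rbind, results)
}

#' Read a scenario grid from a plain-text key-value file
#'
#' The file is YAML: top-level keys matching the [scenario_grid()]
#' columns, scalar or list-valued; list values are fully crossed.
#'
#' @param path Path to the YAML file.
#' @return Scenario data.frame as from [scenario_grid()].
#' @export
read_scenario_grid <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read grid files", call. = FALSE)
  spec <- yaml::read_yaml(path)
  defaults <- list(n_sample = 1000L, target_prevalence = 0.5,
                   sigma_scale = 1, trim_method = "none", trim_delta = 0,
                   interactions = FALSE)
  for (k in names(defaults))
    if (is.null(spec[[k]])) spec[[k]] <- defaults[[k]]
  g <- expand.grid(spec[names(defaults)], stringsAsFactors = FALSE)
  g$scenario_id <- seq_len(nrow(g))
  g
}
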
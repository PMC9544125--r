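# Simulation engine: metrics, significance bands, scenario grids,
# replicate orchestration and seed discipline.

test_that("SE ratio: closed cases and a 5-replicate hand computation", {
  points <- c(1, 2, 3, 4, 5)
  expect_equal(se_ratio(rep(sd(points), 5), points), 1)
  # doubling every deviation doubles the SD, halving the ratio
  expect_equal(se_ratio(rep(sd(points), 5), 3 + 2 * (points - 3)), 0.5)
  ses <- c(1, 1, 2, 2, 4)
  expect_equal(se_ratio(ses, points), 2 / sqrt(2.5))
  expect_error(se_ratio(1, 1), "at least 2")
  expect_error(se_ratio(c(1, 1), c(3, 3)), "zero")
})

test_that("coverage rate over successful replicates", {
  expect_equal(coverage_rate(rep(1, 10)), 1)
  expect_equal(coverage_rate(rep(0, 10)), 0)
  expect_equal(coverage_rate(c(1, 0, 1, NA)), 2 / 3)
  expect_error(coverage_rate(NA), "no successful")
})

test_that("coverage significance band", {
  band <- coverage_significance_band(1000, 0.95)
  expect_equal(round(unname(band), 4), c(0.9365, 0.9635))
  # width scales as 1/sqrt(R)
  w250 <- diff(coverage_significance_band(250))
  w1000 <- diff(coverage_significance_band(1000))
  expect_equal(unname(w250 / w1000), 2)
  wide <- coverage_significance_band(1e8)
  expect_equal(unname(wide), c(0.95, 0.95), tolerance = 1e-3)
})

test_that("scenario grids have the designed dimensions", {
  main <- scenario_grid("main")
  expect_equal(nrow(main), 45)
  expect_equal(sort(unique(main$n_sample)),
               c(250, 500, 1000, 5000, 10000))
  expect_equal(sort(unique(main$target_prevalence)), seq(0.1, 0.9, 0.1))
  expect_false(any(main$interactions))
  expect_true(all(scenario_grid("interactions")$interactions))
  overlap <- scenario_grid("overlap")
  expect_equal(nrow(overlap), 9)
  expect_equal(overlap$sigma_scale,
               c(0.4, 0.5, 0.6, 0.7, 0.8, 1, 1.2, 1.4, 1.6))
  expect_true(all(overlap$n_sample == 1000))
  trimming <- scenario_grid("trimming")
  expect_equal(nrow(trimming), 54)
  expect_equal(sum(trimming$trim_method == "crump"), 9)
})

test_that("scenario config validates its arguments", {
  cfg <- scenario_config(250, 0.1, n_replicates = 3, n_bootstrap = 0)
  expect_s3_class(cfg, "scenario_config")
  expect_error(scenario_config(250, 1.5), "target_prevalence")
  expect_error(scenario_config(250, 0.5, trim_delta = 0.7), "trim_delta")
  expect_error(scenario_config(2e6, 0.5), "n_sample")
})

test_that("replicates are bit-identical under a fixed seed", {
  pop <- small_pop()
  cfg <- scenario_config(400, 0.5, n_replicates = 2, n_bootstrap = 30,
                         seed = 3, pop_size = 20000)
  truths <- sapply(c("ATE", "ATT", "MW", "OW"),
                   function(f) true_estimands(pop, f), simplify = FALSE)
  r1 <- run_replicate(pop, cfg, 777L, truths)
  r2 <- run_replicate(pop, cfg, 777L, truths)
  expect_identical(r1, r2)
  expect_false(r1$failed)
  expect_identical(r1$cover_asym.ATE.mean_diff,
                   as.integer(abs(r1$point.ATE.mean_diff - 2) <=
                                qnorm(0.975) * r1$se_asym.ATE.mean_diff))
})

test_that("run_scenario summarizes all families, estimands and methods", {
  cfg <- scenario_config(400, 0.5, n_replicates = 6, n_bootstrap = 30,
                         seed = 11, pop_size = 20000)
  res <- run_scenario(cfg, small_pop())
  m <- res$summary$metrics
  expect_equal(nrow(m), 4 * 3 * 2)
  expect_true(all(m$coverage >= 0 & m$coverage <= 1))
  expect_true(all(m$se_ratio > 0, na.rm = TRUE))
  expect_equal(res$summary$n_replicates, 6)
  expect_equal(nrow(res$summary$balance), 4)
  # OW exact balance shows up in the balance summary
  expect_lt(res$summary$balance$mean_max_abs_smd[
    res$summary$balance$family == "OW"], 1e-8)
  # summaries are a pure function of the configuration
  res2 <- run_scenario(cfg, small_pop())
  expect_identical(res$summary$metrics, res2$summary$metrics)
})

test_that("failed replicates are flagged and excluded from metrics", {
  pop <- small_pop()
  cfg <- scenario_config(24, 0.5, n_replicates = 1, n_bootstrap = 0,
                         seed = 5, pop_size = 20000)
  truths <- sapply(c("ATE", "ATT", "MW", "OW"),
                   function(f) true_estimands(pop, f), simplify = FALSE)
  # n = 24 with 10 covariates: separation is certain
  rec <- run_replicate(pop, cfg, 1L, truths)
  expect_true(rec$failed)
  ok <- run_replicate(pop, scenario_config(500, 0.5, n_replicates = 1,
                                           n_bootstrap = 0, seed = 5,
                                           pop_size = 20000), 1L, truths)
  summ <- summarize_replicates(merge(rec, ok, all = TRUE), cfg)
  expect_equal(summ$n_failed, 1)
})

test_that("grid runner stacks tidy metric rows and writes incrementally", {
  g <- data.frame(n_sample = c(300, 300), target_prevalence = c(0.4, 0.6),
                  sigma_scale = 1, trim_method = "none", trim_delta = 0,
                  interactions = FALSE, scenario_id = 1:2)
  out <- tempfile(fileext = ".tsv")
  tab <- run_grid(g, n_replicates = 3, n_bootstrap = 0, seed = 2,
                  pop_size = 20000, out = out)
  expect_equal(nrow(tab), 2 * 4 * 3)  # asymptotic only (no bootstrap)
  expect_true(file.exists(out))
  again <- run_grid(g, n_replicates = 3, n_bootstrap = 0, seed = 2,
                    pop_size = 20000, out = out)
  expect_equal(nrow(again), nrow(tab))  # resumed, not recomputed
  unlink(out)
})

test_that("scenario grids can be read from a YAML file", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yml")
  writeLines(c("n_sample: [250, 1000]",
               "target_prevalence: [0.2, 0.5]",
               "sigma_scale: 1"), path)
  g <- read_scenario_grid(path)
  expect_equal(nrow(g), 4)
  expect_equal(sort(unique(g$n_sample)), c(250, 1000))
  expect_equal(g$trim_method, rep("none", 4))
  unlink(path)
})
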
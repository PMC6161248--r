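mk_history <- function(conc, lots, ids = "M1") {
  tibble::tibble(qc_lot = lots, batch_id = paste0("B", seq_along(conc)),
                 run_date = as.Date("2024-01-01"), hmdb_id = ids,
                 conc_umol_l = conc)
}

test_that("a degenerate constant history collapses onto its value", {
  h <- mk_history(rep(50, 40), rep(c("L1", "L2"), each = 20))
  f <- fit_reference(h, n_draws = 3000, burn_in = 500, seed = 2)
  est <- f$estimates
  expect_equal(est$posterior_median, 50, tolerance = 0.01)
  # residual interval width is prior-driven; it collapses onto [v, v] as the
  # variance priors vanish
  width <- est$cri_upper / est$cri_lower
  f2 <- fit_reference(h, n_draws = 3000, burn_in = 500, seed = 2,
                      prior_shape = 1e-9, prior_rate = 1e-9)
  width2 <- f2$estimates$cri_upper / f2$estimates$cri_lower
  expect_lt(width2, width)
  expect_lt(width2, 1.001)
  expect_equal(f2$estimates$posterior_median, 50, tolerance = 1e-3)
})

test_that("the sampler recovers a known lot-structured truth", {
  cfg <- sim_config(seed = 12, n_metabolites = 1, lot_sd_log = 0.1,
                    qc_noise_sd_log = 0.2)
  h <- simulate_qc_history(cfg, n_batches = 54, n_lots = 6, reps_per_batch = 10,
                           true_median = 100)
  expect_identical(nrow(h$history), 540L)
  f <- fit_reference(h$history, n_draws = 8000, burn_in = 2000, seed = 5)
  est <- f$estimates
  expect_equal(est$posterior_median, 100, tolerance = 0.12)
  expect_lt(est$cri_lower, est$posterior_median)
  expect_gt(est$cri_upper, est$posterior_median)
  expect_equal(est$sigma_resid, 0.2, tolerance = 0.25)
  # lot-effect identifiability: posterior deviations centered near zero
  expect_lt(abs(est$lot_sum_posterior_mean), 6 * 0.1)
  # agrees with an independent mixed-model point estimate
  m <- lme4::lmer(log(conc_umol_l) ~ 1 + (1 | qc_lot), data = h$history)
  expect_equal(est$posterior_median, exp(unname(lme4::fixef(m)[1])),
               tolerance = 0.02)
})

test_that("independent seeds agree within Monte-Carlo error", {
  cfg <- sim_config(seed = 3, n_metabolites = 1)
  h <- simulate_qc_history(cfg, n_batches = 54, n_lots = 6)$history
  f1 <- fit_reference(h, n_draws = 20000, burn_in = 5000, seed = 101)
  f2 <- fit_reference(h, n_draws = 20000, burn_in = 5000, seed = 202)
  expect_equal(f1$estimates$posterior_median, f2$estimates$posterior_median,
               tolerance = 0.01)
  # and the same seed reproduces exactly
  f3 <- fit_reference(h, n_draws = 20000, burn_in = 5000, seed = 101)
  expect_identical(f1$estimates, f3$estimates)
})

test_that("estimates are scale-equivariant", {
  cfg <- sim_config(seed = 8, n_metabolites = 1)
  h <- simulate_qc_history(cfg, n_batches = 12, n_lots = 3)$history
  k <- 7.3
  h2 <- dplyr::mutate(h, conc_umol_l = conc_umol_l * k)
  f1 <- fit_reference(h, n_draws = 5000, burn_in = 1000, seed = 9)
  f2 <- fit_reference(h2, n_draws = 5000, burn_in = 1000, seed = 9)
  expect_equal(f2$estimates$posterior_median, k * f1$estimates$posterior_median,
               tolerance = 1e-9)
  expect_equal(f2$estimates$cri_lower, k * f1$estimates$cri_lower, tolerance = 1e-9)
  expect_equal(f2$estimates$cri_upper, k * f1$estimates$cri_upper, tolerance = 1e-9)
})

test_that("single-lot histories fall back with a warning; bad rows counted", {
  h <- mk_history(exp(rnorm(30, log(20), 0.1)), rep("L1", 30))
  expect_warning(f <- fit_reference(h, n_draws = 2000, burn_in = 500, seed = 1),
                 "single-lot")
  expect_equal(f$estimates$posterior_median, 20, tolerance = 0.1)

  h2 <- mk_history(c(exp(rnorm(20, log(10), 0.1)), -1, 0),
                   rep(c("L1", "L2"), 11))
  f2 <- suppressWarnings(fit_reference(h2, n_draws = 2000, burn_in = 500, seed = 1))
  expect_identical(f2$estimates$n_dropped, 2L)
  expect_error(fit_reference(mk_history(c(1, 2), c("L1", "L2")),
                             n_draws = 100, burn_in = 10, seed = 1),
               class = "semiquantr_domain_error")
})

test_that("reference tables follow panel order and re-emit packaged values", {
  p <- default_panel()
  tbl <- reference_table(p, p)
  expect_identical(nrow(tbl), 102L)
  expect_identical(tbl$hmdb_id, p$entries$hmdb_id)  # panel row order
  expect_identical(tbl$estimate,
                   p$references$median_umol_l[match(tbl$hmdb_id,
                                                    p$references$hmdb_id)])
  # byte-identical re-emission through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  reference_table(p, p, path = path)
  tbl2 <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(tbl2$estimate, tbl$estimate)

  cfg <- sim_config(seed = 4, n_metabolites = 5)
  h <- simulate_qc_history(cfg, n_batches = 8, n_lots = 2)$history
  f <- fit_reference(h, n_draws = 1500, burn_in = 300, seed = 3)
  sp <- simulate_panel(cfg)
  t2 <- reference_table(f, sp)
  expect_identical(nrow(t2), 5L)
  expect_identical(names(t2), c("class", "name", "hmdb_id", "estimate",
                                "lower", "upper"))
  expect_s3_class(tidy(f), "tbl_df")
  expect_identical(glance(f)$n_draws, 1500)
})

test_that("cross-platform comparison reports OLS R², slope and intercept", {
  a <- tibble::tibble(hmdb_id = sprintf("M%d", 1:10), conc = c(1:10))
  r <- cross_platform_compare(a, a)
  expect_equal(r$glance$r_squared, 1)
  expect_equal(r$glance$slope, 1)
  expect_equal(r$glance$intercept, 0, tolerance = 1e-12)

  set.seed(44)
  b <- dplyr::mutate(a, conc = 2 * conc + rnorm(10))
  r2 <- cross_platform_compare(a, b)
  expect_equal(r2$glance$r_squared, cor(a$conc, b$conc)^2)
  expect_identical(nrow(r2$residuals), 10L)

  disjoint <- dplyr::mutate(a, hmdb_id = paste0("X", hmdb_id))
  expect_error(cross_platform_compare(a, disjoint),
               class = "semiquantr_validation_error")
  expect_error(cross_platform_compare(a[1:2, ], a[1:2, ]),
               class = "semiquantr_validation_error")
})
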
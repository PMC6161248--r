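test_that("double randomization is seeded, reproducible, and non-trivial", {
  ids <- sprintf("S%02d", 1:20)
  groups <- setNames(rep(c("A", "B"), each = 10), ids)
  r1 <- double_randomize(ids, groups, seed = 42)
  r2 <- double_randomize(ids, groups, seed = 42)
  expect_identical(r1, r2)
  expect_setequal(r1$extraction_order, ids)
  expect_setequal(r1$injection_order, ids)
  # the two permutations are independent draws, not copies
  r3 <- double_randomize(ids, groups, seed = 43)
  expect_false(identical(r1$injection_order, r3$injection_order))

  single <- double_randomize("only-one", seed = 1)
  expect_identical(single$extraction_order, "only-one")
  expect_identical(single$injection_order, "only-one")
})

test_that("the blocking guard is never violated across seeds", {
  ids <- sprintf("S%02d", 1:20)
  groups <- setNames(rep(c("A", "B"), each = 10), ids)
  limit <- ceiling(2 * 10 / 2)
  violations <- sum(vapply(1:1000, function(s) {
    ord <- double_randomize(ids, groups, seed = s)$injection_order
    max(rle(unname(groups[ord]))$lengths) > limit
  }, logical(1)))
  expect_identical(violations, 0L)
})

test_that("batch layouts interleave QCs and blanks by the stated cadence", {
  l10 <- build_layout(sprintf("S%02d", 1:10))
  expect_identical(sum(l10$role == "qc"), 1L)
  expect_identical(sum(l10$role == "sample"), 10L)
  expect_identical(l10$role[1:11], rep("standard", 11))

  l0 <- build_layout(character(0))
  expect_identical(unique(l0$role), "standard")

  l25 <- build_layout(sprintf("S%02d", 1:25))
  expect_identical(sum(l25$role == "qc"), 2L)
  post <- l25[l25$position > 11, ]
  post$pos_post <- seq_len(nrow(post))
  blank_pos <- post$pos_post[post$role == "blank"]
  expect_identical(blank_pos, as.integer(seq(5, max(blank_pos), by = 5)))
  expect_identical(sum(post$role == "blank"), length(blank_pos))

  # pure function: identical output on re-run
  expect_identical(build_layout(sprintf("S%02d", 1:25)), l25)
})

test_that("a QC due on a blank slot defers to the next position", {
  # with 40 samples the third QC falls due on a blank multiple-of-5 slot
  l <- build_layout(sprintf("S%02d", 1:40))
  post <- l[l$position > 11, ]
  post$pos_post <- seq_len(nrow(post))
  expect_identical(sum(post$role == "sample"), 40L)
  expect_identical(sum(post$role == "qc"), 4L)
  # blanks own every fifth slot; QCs never sit on one
  expect_true(all(post$role[post$pos_post %% 5 == 0] == "blank"))
  qc_pos <- post$pos_post[post$role == "qc"]
  expect_false(any(qc_pos %% 5 == 0))
  # the deferred QC sits immediately after its blank
  expect_true(41 %in% qc_pos)
})

test_that("per-batch QC statistics match direct recomputation", {
  r <- qc_batch_stats(tibble::tibble(hmdb_id = "M1", conc = c(9, 10, 11)))
  expect_equal(r$mean_conc, 10)
  expect_equal(r$cv_pct, 10)
  expect_equal(qc_batch_stats(tibble::tibble(hmdb_id = "M1",
                                             conc = c(4, 4, 4)))$cv_pct, 0)
  # single replicate leaves CV missing
  expect_true(is.na(qc_batch_stats(tibble::tibble(hmdb_id = "M1", conc = 5))$cv_pct))

  set.seed(9)
  d <- tibble::tibble(hmdb_id = rep(c("A", "B"), each = 6),
                      conc = rnorm(12, 20, 2))
  r2 <- qc_batch_stats(d)
  expect_equal(r2$cv_pct[r2$hmdb_id == "B"],
               100 * sd(d$conc[7:12]) / mean(d$conc[7:12]))
})

test_that("drift checks compare batch RSD to the history inter-day RSD", {
  mk_history <- function(rsd_target) {
    # batches whose means have the requested spread
    set.seed(4)
    means <- 100 * (1 + rnorm(20, 0, rsd_target / 100))
    purrr::map_dfr(seq_along(means), function(k) tibble::tibble(
      qc_lot = "L1", batch_id = sprintf("B%02d", k),
      run_date = as.Date("2024-01-01") + k, hmdb_id = "M1",
      conc_umol_l = means[k]))
  }
  h <- mk_history(10)
  ref <- history_interday_rsd(h)
  expect_identical(ref$n_batches, 20L)

  stats_of <- function(rsd) tibble::tibble(hmdb_id = "M1", n = 6L,
                                           mean_conc = 100, cv_pct = rsd)
  expect_identical(compare_to_history(stats_of(ref$interday_rsd_pct * 0.8),
                                      h, tolerance_pct = 0)$status, "pass")
  expect_identical(compare_to_history(stats_of(ref$interday_rsd_pct * 1.3),
                                      h, tolerance_pct = 20)$status, "warn")
  expect_identical(compare_to_history(
    tibble::tibble(hmdb_id = "UNSEEN", n = 6L, mean_conc = 1, cv_pct = 5),
    h)$status, "unknown")
})

test_that("history inter-day RSD matches a from-scratch oracle after appends", {
  cfg <- sim_config(seed = 17, n_metabolites = 3)
  h1 <- simulate_qc_history(cfg, n_batches = 10, n_lots = 2)$history
  h2 <- simulate_qc_history(cfg, n_batches = 4, n_lots = 2, seed_offset = 50)$history
  h2$batch_id <- sub("BATCH-0", "BATCH-9", h2$batch_id)
  path <- withr::local_tempfile(fileext = ".csv")
  write_qc_history(h1, path)
  write_qc_history(h2, path, append = TRUE)
  h <- read_qc_history(path)
  # append never alters earlier records
  expect_equal(nrow(h), nrow(h1) + nrow(h2))
  expect_equal(h$conc_umol_l[seq_len(nrow(h1))], h1$conc_umol_l)

  r <- history_interday_rsd(h)
  oracle <- sapply(unique(h$hmdb_id), function(id) {
    bm <- tapply(h$conc_umol_l[h$hmdb_id == id], h$batch_id[h$hmdb_id == id], mean)
    100 * sd(bm) / mean(bm)
  })
  expect_equal(r$interday_rsd_pct, unname(oracle[r$hmdb_id]))
})

test_that("reproducibility summaries hit the configured tiers", {
  set.seed(23)
  n_b <- 25; mets <- sprintf("M%02d", 1:20)
  summaries <- tidyr::expand_grid(batch_id = sprintf("B%02d", seq_len(n_b)),
                                  hmdb_id = mets) |>
    dplyr::mutate(qc_conc = 50 * (1 + rnorm(dplyr::n(), 0, 0.03)),
                  rt = 6 * (1 + rnorm(dplyr::n(), 0, 0.005)),
                  r_squared = pmin(1, 0.995 * (1 + rnorm(dplyr::n(), 0, 0.002))))
  s <- reproducibility_summary(summaries)
  expect_gte(s$tiers$frac_conc_cv_below_tier, 0.95)
  expect_gte(s$tiers$frac_rt_cv_below_tier, 0.95)
  expect_gte(s$tiers$frac_r2_cv_below_tier, 0.95)

  const <- tibble::tibble(batch_id = c("B1", "B2"), hmdb_id = "M1",
                          qc_conc = c(10, 10), rt = c(5, 5),
                          r_squared = c(0.99, 0.99))
  s2 <- reproducibility_summary(const)
  expect_equal(s2$per_metabolite$rt_cv_pct, 0)
  expect_equal(s2$per_metabolite$r2_cv_pct, 0)
  expect_error(reproducibility_summary(const[1, ]),
               class = "semiquantr_domain_error")
})

test_that("synthetic lot drift is flagged exactly when it exceeds tolerance", {
  # stable history; a clean batch passes, an inflated-noise batch warns
  set.seed(6)
  h <- purrr::map_dfr(1:15, function(k) tibble::tibble(
    qc_lot = "L1", batch_id = sprintf("B%02d", k),
    run_date = as.Date("2024-01-01") + k, hmdb_id = "M1",
    conc_umol_l = rnorm(6, 100, 5)))
  ref_rsd <- history_interday_rsd(h)$interday_rsd_pct
  good <- tibble::tibble(hmdb_id = "M1", n = 6L, mean_conc = 100,
                         cv_pct = ref_rsd * 0.5)
  bad <- tibble::tibble(hmdb_id = "M1", n = 6L, mean_conc = 100,
                        cv_pct = ref_rsd * 1.5)
  expect_identical(compare_to_history(good, h, 20)$status, "pass")
  expect_identical(compare_to_history(bad, h, 20)$status, "warn")
})
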
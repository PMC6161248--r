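#' Hierarchical log-normal estimation of population reference medians
#'
#' Pooled-serum QC concentrations accumulated over years arrive in distinct
#' serum *lots*; lot-to-lot differences inflate the spread of the raw values
#' and must not contaminate a population reference estimate. The model, per
#' metabolite, is a lot-corrected log-normal mixed model:
#'
#' \deqn{\log y_{ij} = \mu + b_j + \varepsilon_{ij}, \quad
#'       b_j \sim N(0, \sigma_b^2), \quad
#'       \varepsilon_{ij} \sim N(0, \sigma_e^2)}
#'
#' with a flat prior on \eqn{\mu} and inverse-gamma(0.001, 0.001) priors on
#' both variances. A Gibbs sampler draws from the full conditionals (all
#' conjugate); the population median concentration is summarized as the
#' median of the `exp(mu)` draws — transformation-consistent with the
#' log-normal median — and the 95% credibility interval as the 2.5/97.5
#' percentiles of the same draws.
#'
#' Non-positive concentrations cannot enter a log-normal likelihood; such
#' rows are dropped and counted. A single-lot history falls back, with a
#' warning, to a no-lot model (\eqn{b} fixed at zero).
#'
#' @param history QC history tibble with `hmdb_id`, `qc_lot`, `conc_umol_l`
#'   (see [read_qc_history()]).
#' @param n_draws Retained posterior draws (default 20000).
#' @param burn_in Discarded initial draws (default 5000).
#' @param seed Integer seed (mandatory).
#' @param keep_draws Keep the `exp(mu)` draws per metabolite (for
#'   diagnostics; default `FALSE`).
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters shared by
#'   both variance priors (default 0.001 and 0.001, a standard
#'   weakly-informative choice). As they shrink toward zero the posterior
#'   for noiseless data collapses onto the observed value.
#' @return An `sq_reffit`: list with `estimates` (tibble per metabolite:
#'   `posterior_median`, `cri_lower`, `cri_upper`, `sigma_lot`,
#'   `sigma_resid`, `n_obs`, `n_lots`, `n_dropped`), `lot_effects` (posterior
#'   mean multiplicative deviation per lot), `n_draws`, `burn_in`, `seed`.
#' @examples
#' \donttest{
#' h <- simulate_qc_history(sim_config(seed = 1, n_metabolites = 2),
#'                          n_batches = 10, n_lots = 3)
#' fit_reference(h$history, n_draws = 2000, burn_in = 500, seed = 1)
#' }
#' @export
fit_reference <- function(history, n_draws = 20000, burn_in = 5000, seed,
                          keep_draws = FALSE,
                          prior_shape = 0.001, prior_rate = 0.001) {
  stopifnot(!missing(seed), n_draws >= 1, burn_in >= 0,
            all(c("hmdb_id", "qc_lot", "conc_umol_l") %in% names(history)))
  ids <- unique(history$hmdb_id)
  with_seed(as.integer(seed), {
    per <- lapply(ids, function(id) {
      d <- history[history$hmdb_id == id, ]
      n_dropped <- sum(!is.finite(d$conc_umol_l) | d$conc_umol_l <= 0)
      d <- d[is.finite(d$conc_umol_l) & d$conc_umol_l > 0, ]
      if (nrow(d) < 3)
        stop_domain(paste0("need >= 3 positive observations for ", id))
      gibbs_lognormal(log(d$conc_umol_l), factor(d$qc_lot),
                      n_draws = n_draws, burn_in = burn_in,
                      id = id, n_dropped = n_dropped, keep_draws = keep_draws,
                      a0 = prior_shape, b0 = prior_rate)
    })
  })
  structure(list(
    estimates = dplyr::bind_rows(lapply(per, `[[`, "estimate")),
    lot_effects = dplyr::bind_rows(lapply(per, `[[`, "lot_effects")),
    draws = if (keep_draws) setNames(lapply(per, `[[`, "draws"), ids),
    n_draws = n_draws, burn_in = burn_in, seed = seed),
    class = "sq_reffit")
}

# Gibbs sampler for log(y) = mu + b_lot + e; flat prior on mu,
# IG(a0, b0) on both variances. All conditionals are conjugate.
gibbs_lognormal <- function(logy, lot, n_draws, burn_in, id = "analyte",
                            n_dropped = 0, keep_draws = FALSE,
                            a0 = 0.001, b0 = 0.001) {
  n <- length(logy)
  lot <- droplevels(lot)
  J <- nlevels(lot)
  if (J < 2) {
    warn(paste0(id, ": single-lot history; fitting a no-lot model"))
  }
  lot_i <- as.integer(lot)
  n_j <- tabulate(lot_i, J)
  sum_j <- vapply(seq_len(J), function(j) sum(logy[lot_i == j]), numeric(1))
  ss_j <- vapply(seq_len(J), function(j) sum(logy[lot_i == j]^2), numeric(1))
  sum_y <- sum(logy)

  mu <- mean(logy)
  b <- rep(0, J)
  s2e <- stats::var(logy)
  if (!is.finite(s2e) || s2e <= 0) s2e <- 1e-6
  s2b <- if (J >= 2) max(stats::var(sum_j / n_j), 1e-6) else 0

  total <- burn_in + n_draws
  mu_draws <- numeric(n_draws)
  b_sum_draws <- numeric(n_draws)
  s2b_draws <- numeric(n_draws)
  s2e_draws <- numeric(n_draws)
  b_mean <- rep(0, J)

  m_j <- sum_j / n_j
  for (t in seq_len(total)) {
    if (J >= 2) {
      # mu | s2e, s2b with the lot effects integrated out (blocked draw):
      # lot means are independent N(mu, s2b + s2e/n_j)
      w_j <- 1 / (s2b + s2e / n_j)
      mu <- rnorm(1, sum(w_j * m_j) / sum(w_j), sqrt(1 / sum(w_j)))
      # b_j | mu, s2e, s2b
      prec <- n_j / s2e + 1 / s2b
      bmean <- (sum_j - n_j * mu) / s2e / prec
      b <- rnorm(J, bmean, sqrt(1 / prec))
      # s2b | b
      s2b <- 1 / stats::rgamma(1, a0 + J / 2, b0 + sum(b^2) / 2)
    } else {
      mu <- rnorm(1, sum_y / n, sqrt(s2e / n))
    }
    # s2e | mu, b — residual SS from per-lot sufficient statistics
    mb <- mu + b
    rss <- sum(ss_j - 2 * mb * sum_j + n_j * mb^2)
    s2e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + rss / 2)
    if (t > burn_in) {
      k <- t - burn_in
      mu_draws[k] <- mu
      b_sum_draws[k] <- sum(b)
      s2b_draws[k] <- s2b
      s2e_draws[k] <- s2e
      b_mean <- b_mean + b / n_draws
    }
  }

  med_draws <- exp(mu_draws)
  qs <- unname(quantile(med_draws, c(0.025, 0.5, 0.975)))
  list(
    estimate = tibble::tibble(
      hmdb_id = id,
      posterior_median = qs[2], cri_lower = qs[1], cri_upper = qs[3],
      sigma_lot = sqrt(stats::median(s2b_draws)),
      sigma_resid = sqrt(stats::median(s2e_draws)),
      lot_sum_posterior_mean = mean(b_sum_draws),
      n_obs = n, n_lots = J, n_dropped = n_dropped),
    lot_effects = tibble::tibble(hmdb_id = id, qc_lot = levels(lot),
                                 multiplier = exp(b_mean)),
    draws = if (keep_draws) med_draws)
}

#' Emit a reference table (class-grouped medians with 95% CrI)
#'
#' Formats fitted reference medians — or the packaged reference database
#' itself when `fit` is an `sq_panel` — as a class-grouped table with
#' columns `class`, `name`, `hmdb_id`, `estimate`, `lower`, `upper`, row
#' order following the panel.
#'
#' @param fit An `sq_reffit`, or an `sq_panel` to re-emit its packaged
#'   reference values.
#' @param panel An `sq_panel` supplying names, classes and row order.
#' @param path Optional CSV output path.
#' @return The reference tibble (written to `path` when given).
#' @export
reference_table <- function(fit, panel, path = NULL) {
  stopifnot(inherits(panel, "sq_panel"))
  est <- if (inherits(fit, "sq_reffit")) {
    dplyr::select(fit$estimates, "hmdb_id", estimate = "posterior_median",
                  lower = "cri_lower", upper = "cri_upper")
  } else if (inherits(fit, "sq_panel")) {
    dplyr::select(fit$references, "hmdb_id", estimate = "median_umol_l",
                  lower = "ci_lower", upper = "ci_upper")
  } else stop_domain("fit must be an sq_reffit or an sq_panel")
  out <- panel$entries |>
    dplyr::select("class", "name", "hmdb_id") |>
    dplyr::inner_join(est, by = "hmdb_id")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Cross-platform concentration comparison
#'
#' Ordinary least-squares regression of platform B concentrations on
#' platform A for the metabolites matched by HMDB id, reporting the
#' coefficient of determination, slope, intercept and per-point residuals.
#'
#' @param values_a,values_b Data frames with `hmdb_id` and `conc` columns.
#' @return A list with `glance` (one-row tibble: `r_squared`, `slope`,
#'   `intercept`, `n_matched`) and `residuals` (per-metabolite tibble).
#' @export
cross_platform_compare <- function(values_a, values_b) {
  stopifnot(all(c("hmdb_id", "conc") %in% names(values_a)),
            all(c("hmdb_id", "conc") %in% names(values_b)))
  m <- dplyr::inner_join(values_a, values_b, by = "hmdb_id",
                         suffix = c("_a", "_b")) |>
    dplyr::filter(!is.na(.data$conc_a), !is.na(.data$conc_b))
  if (nrow(m) < 3)
    stop_validation(sprintf("need >= 3 matched metabolites, found %d", nrow(m)))
  fit <- stats::lm(conc_b ~ conc_a, data = m)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((m$conc_b - mean(m$conc_b))^2)
  list(glance = tibble::tibble(r_squared = r2,
                               slope = unname(coef(fit)[2]),
                               intercept = unname(coef(fit)[1]),
                               n_matched = nrow(m)),
       residuals = tibble::tibble(hmdb_id = m$hmdb_id,
                                  conc_a = m$conc_a, conc_b = m$conc_b,
                                  residual = unname(stats::residuals(fit))))
}

#' @export
print.sq_reffit <- function(x, ...) {
  cat(sprintf("<sq_reffit> %d metabolites; %d draws after %d burn-in (seed %d)\n",
              nrow(x$estimates), x$n_draws, x$burn_in, as.integer(x$seed)))
  print(x$estimates, n = 5)
  invisible(x)
}
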
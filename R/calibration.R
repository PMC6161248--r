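#' Build a serial-dilution calibration design
#'
#' Standards are prepared by repeated dilution of the top standard by a fixed
#' factor; with the defaults (11 levels, factor 2) the design spans a
#' 1024-fold (> 1000-fold) dynamic concentration range.
#'
#' @param top_conc Concentration of the highest standard (> 0, any unit).
#' @param n_levels Number of calibration levels (>= 2; default 11).
#' @param factor Dilution factor between adjacent levels (> 1; default 2).
#' @return A tibble with `level` (1 = lowest) and ascending `nominal_conc`;
#'   the attribute `dynamic_range` equals `factor^(n_levels - 1)`.
#' @examples
#' make_serial_dilution(1000, 11, 2)
#' @export
make_serial_dilution <- function(top_conc, n_levels = 11, factor = 2) {
  if (!is.finite(top_conc) || top_conc <= 0) stop_domain("top_conc must be positive")
  if (n_levels < 2) stop_domain("n_levels must be >= 2")
  if (factor <= 1) stop_domain("dilution factor must be > 1")
  conc <- top_conc / factor^((n_levels - 1):0)
  structure(tibble::tibble(level = seq_len(n_levels), nominal_conc = conc),
            dynamic_range = factor^(n_levels - 1))
}

#' Fit a calibration curve on a configured scale
#'
#' Targeted assays over 1000-fold concentration ranges yield heteroscedastic
#' responses: variance grows with concentration. Two standard remedies are
#' supported and are mutually exclusive: `1/x` weighting of an untransformed
#' linear or quadratic least-squares fit, or a log-log transform (natural
#' logs of both response and concentration), which already stabilizes
#' proportional variance — so `transform = "loglog"` forces
#' `weighting = "none"`.
#'
#' The response is the analyte/internal-standard peak-area ratio (raw peak
#' area for metabolites without an assigned IS). R-squared is
#' `1 - SS_res/SS_tot` on the *fitted* scale (weighted when weighting is
#' active), and is labeled as such.
#'
#' After fitting, each level's response is back-calculated and accuracy
#' (measured/nominal, percent) is evaluated against the acceptance bands
#' (within 15%, or 20% at the lowest level); [determine_loq()] derives the
#' LLOQ/ULOQ from the contiguous run of passing levels.
#'
#' @param series A data frame with columns `nominal_conc` and `response`
#'   (e.g. from [make_serial_dilution()] joined with measured responses, or
#'   [simulate_calibration()]).
#' @param model `"linear"` or `"quadratic"`.
#' @param transform `"none"` or `"loglog"`.
#' @param weighting `"none"` or `"inv_x"` (weight `1/nominal_conc` on the
#'   untransformed scale).
#' @return An `sq_curvefit` object; see [tidy.sq_curvefit()] and
#'   [glance.sq_curvefit()].
#' @examples
#' s <- tibble::tibble(nominal_conc = 1:6, response = 2 * (1:6))
#' fit_curve(s, "linear")
#' @export
fit_curve <- function(series,
                      model = c("linear", "quadratic"),
                      transform = c("none", "loglog"),
                      weighting = c("none", "inv_x")) {
  model <- match.arg(model)
  transform <- match.arg(transform)
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(series),
            all(c("nominal_conc", "response") %in% names(series)))
  ok <- stats::complete.cases(series[, c("nominal_conc", "response")])
  series <- series[ok, , drop = FALSE]
  order_i <- order(series$nominal_conc)
  series <- series[order_i, , drop = FALSE]

  p <- if (model == "linear") 2L else 3L
  if (nrow(series) < p + 1L)
    stop_domain(sprintf("need at least %d non-missing levels for a %s fit",
                        p + 1L, model))
  if (transform == "loglog") {
    if (any(series$nominal_conc <= 0) || any(series$response <= 0))
      stop_domain("log-log fitting requires strictly positive concentrations and responses")
    weighting <- "none"
  }
  if (weighting == "inv_x" && any(series$nominal_conc <= 0))
    stop_domain("1/x weighting requires strictly positive concentrations")

  x <- if (transform == "loglog") log(series$nominal_conc) else series$nominal_conc
  y <- if (transform == "loglog") log(series$response) else series$response
  w <- if (weighting == "inv_x") 1 / series$nominal_conc else rep(1, length(x))

  fml <- if (model == "linear") y ~ x else y ~ x + I(x^2)
  fit <- stats::lm(fml, data = data.frame(x = x, y = y), weights = w)
  cf <- unname(coef(fit))
  yhat <- unname(fitted(fit))
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - wmean)^2)

  out <- structure(
    list(model = model, transform = transform, weighting = weighting,
         coefficients = setNames(cf, c("intercept", "slope",
                                       if (model == "quadratic") "quadratic")),
         r_squared = r2,
         series = tibble::as_tibble(series),
         lloq = NA_real_, uloq = NA_real_, rejected = FALSE,
         backcalc = NULL),
    class = "sq_curvefit")

  measured <- back_calculate(out, series$response)
  acc <- 100 * measured / series$nominal_conc
  out$backcalc <- tibble::tibble(
    level = seq_len(nrow(series)),
    nominal_conc = series$nominal_conc,
    response = series$response,
    back_calculated = measured,
    accuracy_pct = acc)
  loq <- determine_loq(out)
  out$lloq <- loq$lloq
  out$uloq <- loq$uloq
  out$rejected <- loq$rejected
  out
}

predict_response <- function(fit, conc) {
  cf <- fit$coefficients
  x <- if (fit$transform == "loglog") log(conc) else conc
  eta <- cf[["intercept"]] + cf[["slope"]] * x +
    if (fit$model == "quadratic") cf[["quadratic"]] * x^2 else 0
  if (fit$transform == "loglog") exp(eta) else eta
}

#' Back-calculate concentration from an instrument response
#'
#' Inverse prediction on the original concentration scale. For quadratic
#' fits the root lying inside the calibrated concentration range is chosen;
#' when both or neither root falls inside, the root nearest the range
#' midpoint wins (deterministic tie-break). Responses outside the invertible
#' region return `NA` (non-quantifiable) rather than an error.
#'
#' @param fit An `sq_curvefit`.
#' @param response Numeric vector of responses (area ratios).
#' @return Numeric vector of concentrations.
#' @export
back_calculate <- function(fit, response) {
  stopifnot(inherits(fit, "sq_curvefit"))
  cf <- fit$coefficients
  y <- if (fit$transform == "loglog") {
    out <- rep(NA_real_, length(response))
    pos <- !is.na(response) & response > 0
    out[pos] <- log(response[pos])
    out
  } else response

  if (fit$model == "linear") {
    conc_t <- (y - cf[["intercept"]]) / cf[["slope"]]
  } else {
    a <- cf[["quadratic"]]; b <- cf[["slope"]]; c0 <- cf[["intercept"]]
    rng <- range(if (fit$transform == "loglog") log(fit$series$nominal_conc)
                 else fit$series$nominal_conc)
    mid <- mean(rng)
    conc_t <- vapply(y, function(yi) {
      if (is.na(yi)) return(NA_real_)
      disc <- b^2 - 4 * a * (c0 - yi)
      if (disc < 0) return(NA_real_)
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      inside <- roots >= rng[1] & roots <= rng[2]
      cand <- if (sum(inside) == 1) roots[inside] else roots[which.min(abs(roots - mid))]
      cand
    }, numeric(1))
  }
  if (fit$transform == "loglog") exp(conc_t) else conc_t
}

#' Determine LLOQ and ULOQ from back-calculated accuracy
#'
#' A level passes when its back-calculated accuracy is within 15% of nominal
#' (20% at the lowest level of the series, the standard relaxation at the
#' quantification limit). The LLOQ is the lowest and the ULOQ the highest
#' nominal concentration of the longest contiguous run of passing levels;
#' a curve with no passing level is flagged rejected (not an error).
#'
#' @param fit An `sq_curvefit`.
#' @param tol_pct Accuracy half-band in percent (default 15).
#' @param tol_lloq_pct Relaxed half-band at the lowest level (default 20).
#' @return A list with `lloq`, `uloq`, `rejected` and the logical `pass`
#'   vector per level.
#' @export
determine_loq <- function(fit, tol_pct = 15, tol_lloq_pct = 20) {
  stopifnot(inherits(fit, "sq_curvefit"))
  bc <- fit$backcalc
  if (is.null(bc)) stop_domain("fit carries no back-calculation table")
  tol <- c(tol_lloq_pct, rep(tol_pct, nrow(bc) - 1L))
  pass <- !is.na(bc$accuracy_pct) & abs(bc$accuracy_pct - 100) <= tol
  if (!any(pass))
    return(list(lloq = NA_real_, uloq = NA_real_, rejected = TRUE, pass = pass))
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pass_runs <- which(runs$values)
  best <- pass_runs[which.max(runs$lengths[pass_runs])]
  list(lloq = bc$nominal_conc[starts[best]],
       uloq = bc$nominal_conc[ends[best]],
       rejected = FALSE, pass = pass)
}

#' Select the best regression configuration for a calibration series
#'
#' Fits every candidate `(model, transform, weighting)` combination and keeps
#' the one maximizing the number of levels whose back-calculated accuracy
#' passes the acceptance bands; ties break by higher fitted-scale R-squared,
#' then by simplicity (linear before quadratic, untransformed before
#' log-log, unweighted before 1/x).
#'
#' @param series Calibration series data frame (`nominal_conc`, `response`).
#' @param candidates List of character vectors `c(model, transform,
#'   weighting)`; defaults to the three workhorse configurations.
#' @return The winning `sq_curvefit`.
#' @export
select_model <- function(series,
                         candidates = list(c("linear", "none", "inv_x"),
                                           c("linear", "loglog", "none"),
                                           c("quadratic", "none", "inv_x"))) {
  stopifnot(length(candidates) >= 1)
  fits <- lapply(candidates, function(cand) {
    tryCatch(fit_curve(series, cand[1], cand[2], cand[3]),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop_domain("no candidate model could be fitted")
  score <- vapply(fits, function(f) {
    sum(determine_loq(f)$pass)
  }, numeric(1))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  complexity <- vapply(fits, function(f) {
    (f$model == "quadratic") * 4 + (f$transform == "loglog") * 2 +
      (f$weighting == "inv_x") * 1
  }, numeric(1))
  ord <- order(-score, -r2, complexity)
  fits[[ord[1]]]
}

#' Load a per-metabolite calibration configuration
#'
#' YAML mapping each HMDB id to any of `model`, `transform`, `weighting`,
#' `top_conc`, `n_levels`, `factor`; ids not listed fall back to automatic
#' model selection ([select_model()]).
#'
#' @param path YAML path.
#' @return A named list of per-metabolite settings.
#' @export
load_calibration_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "transform", "weighting", "top_conc", "n_levels", "factor")
  for (id in names(cfg)) {
    extra <- setdiff(names(cfg[[id]]), allowed)
    if (length(extra) > 0)
      stop_validation(paste0("unknown calibration setting(s) for ", id, ": ",
                             paste(extra, collapse = ", ")))
  }
  cfg
}

#' Carryover check against the LLOQ-level peak area
#'
#' Residual signal in a blank injection after a high-concentration standard,
#' expressed as a percentage of the LLOQ-level peak area. The default
#' acceptance threshold is 20% of the LLOQ peak area.
#'
#' @param blank_area Peak area observed in the blank (>= 0).
#' @param lloq_area Peak area at the LLOQ level (> 0).
#' @param threshold_pct Acceptance threshold in percent (default 20).
#' @return A one-row tibble with `carryover_pct` and logical `pass`.
#' @examples
#' check_carryover(10, 100)   # 10%, pass
#' check_carryover(25, 100)   # 25%, fail
#' @export
check_carryover <- function(blank_area, lloq_area, threshold_pct = 20) {
  if (any(!is.finite(lloq_area)) || any(lloq_area <= 0))
    stop_domain("lloq_area must be positive")
  pct <- 100 * blank_area / lloq_area
  tibble::tibble(carryover_pct = pct, pass = pct <= threshold_pct)
}

#' @export
print.sq_curvefit <- function(x, ...) {
  cat(sprintf("<sq_curvefit> %s / %s / %s over %d levels\n",
              x$model, x$transform, x$weighting, nrow(x$series)))
  cat(sprintf("  R^2 (fitted scale) = %.5f; LLOQ = %s, ULOQ = %s%s\n",
              x$r_squared, format(x$lloq), format(x$uloq),
              if (x$rejected) " [REJECTED: no passing level]" else ""))
  invisible(x)
}
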
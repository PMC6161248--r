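#' Bioanalytical accuracy
#'
#' Accuracy of a back-calculated or measured concentration against its
#' nominal value, as a percentage: `100 * measured / nominal`.
#'
#' @param measured Measured concentration(s).
#' @param nominal Nominal concentration(s) (> 0).
#' @return Percent accuracy, vectorized.
#' @examples
#' accuracy_pct(9.5, 10)  # 95
#' @export
accuracy_pct <- function(measured, nominal) {
  if (any(nominal <= 0, na.rm = TRUE)) stop_domain("nominal must be positive")
  100 * measured / nominal
}

#' Intra- and inter-batch precision (%CV)
#'
#' The coefficient of variation, `100 * sd / mean` with the sample (n - 1)
#' standard deviation. With a `batch` grouping, per-batch CVs are returned
#' together with a `pooled` row computed over all values across batches.
#' A zero mean (or fewer than two values) yields `NA`.
#'
#' @param replicates Numeric vector of replicate concentrations.
#' @param batch Optional vector of batch labels, same length as
#'   `replicates`; switches from intra- to inter-batch mode.
#' @return Intra mode: a single percent CV. Inter mode: a tibble of
#'   per-batch CVs plus a `"pooled"` row.
#' @examples
#' precision_cv(c(9, 10, 11))  # 10
#' @export
precision_cv <- function(replicates, batch = NULL) {
  if (is.null(batch)) {
    if (length(replicates) < 2) stop_domain("need >= 2 replicates for a CV")
    return(cv_pct(replicates))
  }
  stopifnot(length(batch) == length(replicates))
  per_batch <- tibble::tibble(batch = as.character(batch), x = replicates) |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(n = sum(!is.na(.data$x)), cv_pct = cv_pct(.data$x),
                     .groups = "drop")
  dplyr::bind_rows(per_batch,
                   tibble::tibble(batch = "pooled",
                                  n = sum(!is.na(replicates)),
                                  cv_pct = cv_pct(replicates)))
}

#' Construct a spike design
#'
#' A recovery / matrix-effect experiment at one concentration level: QC
#' matrix spiked *before* extraction, matrix spiked *after* extraction,
#' pure-solvent (aqueous) spikes, and unspiked matrix measuring the
#' endogenous background.
#'
#' @param before,after,aqueous,endogenous Numeric replicate response vectors
#'   (endogenous defaults to 0 background).
#' @param hmdb_id,level Optional identifiers carried into reports.
#' @param nominal_spike Optional nominal spiked concentration (> 0).
#' @return A long tibble (`hmdb_id`, `level`, `arm`, `replicate`,
#'   `response`) of class `sq_spike_design`.
#' @export
spike_design <- function(before, after, aqueous = numeric(),
                         endogenous = 0, hmdb_id = "analyte",
                         level = "medium", nominal_spike = NA_real_) {
  arms <- list(spiked_before_extraction = before,
               spiked_after_extraction = after,
               aqueous_spiked = aqueous,
               unspiked_endogenous = endogenous)
  out <- purrr::imap(arms, function(v, arm) {
    if (length(v) == 0) return(NULL)
    tibble::tibble(hmdb_id = hmdb_id, level = level, arm = arm,
                   replicate = seq_along(v), response = as.numeric(v))
  }) |> dplyr::bind_rows()
  attr(out, "nominal_spike") <- nominal_spike
  class(out) <- c("sq_spike_design", class(out))
  out
}

arm_means <- function(design) {
  stopifnot(is.data.frame(design), all(c("arm", "response") %in% names(design)))
  design |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("hmdb_id", "level"))), .data$arm) |>
    dplyr::summarise(mean = mean(.data$response, na.rm = TRUE),
                     cv = cv_pct(.data$response), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("mean", "cv"))
}

grab <- function(df, col, default = NA_real_) {
  if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
}

#' Extraction recovery from a spike design
#'
#' `100 * (mean(before) - mean(endogenous)) / (mean(after) -
#' mean(endogenous))`: the endogenous background present in the matrix is
#' subtracted from both spiked arms before forming the ratio. Recovery is
#' undefined (flagged, `NA`) when the after-extraction arm does not exceed
#' the endogenous background.
#'
#' @param design An `sq_spike_design` or a long data frame with columns
#'   `arm`, `response` (plus optional `hmdb_id`, `level`).
#' @return A tibble per (hmdb_id, level): `recovery_pct`, `cv_pct`
#'   (before-arm replicate CV) and `undefined`.
#' @examples
#' recovery_pct(spike_design(before = 80, after = 100))         # 80%
#' recovery_pct(spike_design(before = 90, after = 110, endogenous = 10))  # 80%
#' @export
recovery_pct <- function(design) {
  m <- arm_means(design)
  endo <- dplyr::coalesce(grab(m, "mean_unspiked_endogenous"), 0)
  num <- grab(m, "mean_spiked_before_extraction") - endo
  den <- grab(m, "mean_spiked_after_extraction") - endo
  undefined <- is.na(den) | den <= 0
  dplyr::bind_cols(
    dplyr::select(m, dplyr::any_of(c("hmdb_id", "level"))),
    tibble::tibble(recovery_pct = ifelse(undefined, NA_real_, 100 * num / den),
                   cv_pct = grab(m, "cv_spiked_before_extraction"),
                   undefined = undefined))
}

#' Matrix effect from a spike design
#'
#' Ratio of the endogenous-subtracted post-extraction spiked response to the
#' aqueous (pure solvent) spiked response. Below 1 indicates ion
#' suppression, above 1 ion enhancement; only the matrix arm is
#' endogenous-subtracted since solvent carries no endogenous analyte.
#'
#' @inheritParams recovery_pct
#' @return A tibble per (hmdb_id, level): `matrix_effect`, `cv_pct`
#'   (after-arm CV) and `interpretation` (`suppression` / `neutral` /
#'   `enhancement`).
#' @examples
#' matrix_effect(spike_design(before = 1, after = 120, aqueous = 100))  # 1.2
#' @export
matrix_effect <- function(design) {
  m <- arm_means(design)
  aq <- grab(m, "mean_aqueous_spiked")
  if (any(is.na(aq)) || any(aq <= 0))
    stop_domain("aqueous arm mean must be positive")
  endo <- dplyr::coalesce(grab(m, "mean_unspiked_endogenous"), 0)
  me <- (grab(m, "mean_spiked_after_extraction") - endo) / aq
  dplyr::bind_cols(
    dplyr::select(m, dplyr::any_of(c("hmdb_id", "level"))),
    tibble::tibble(matrix_effect = me,
                   cv_pct = grab(m, "cv_spiked_after_extraction"),
                   interpretation = dplyr::case_when(me < 1 ~ "suppression",
                                                     me > 1 ~ "enhancement",
                                                     TRUE ~ "neutral")))
}

#' Process efficiency from recovery and matrix effect
#'
#' The total signal attenuation a metabolite suffers between the biological
#' sample and the detector: extraction recovery (fraction) times the matrix
#' effect ratio. Final concentrations of metabolites without their own
#' labeled internal standard are divided by this factor
#' ([apply_process_efficiency()]), and the panel file's
#' `process_efficiency` column is where these values live.
#'
#' @param recovery Extraction recovery as a fraction (> 0), e.g. 0.8.
#' @param me Matrix-effect ratio (> 0).
#' @return Process-efficiency fraction, vectorized.
#' @examples
#' process_efficiency(0.5, 1.2)  # 0.6
#' @export
process_efficiency <- function(recovery, me) {
  if (any(recovery <= 0, na.rm = TRUE) || any(me <= 0, na.rm = TRUE))
    stop_domain("recovery and matrix effect must be positive")
  recovery * me
}

#' Stability of stored versus freshly prepared samples
#'
#' `100 * mean(stored) / mean(fresh)` per condition (wet extract in the
#' autosampler, freeze-thaw cycles, stock or intermediate solutions), with a
#' pass band of 85-115% by default.
#'
#' @param design A data frame with columns `arm` (`stored` / `fresh`),
#'   `response`, plus optional `hmdb_id`, `condition`.
#' @param band Two-sided acceptance band in percent (default `c(85, 115)`).
#' @return A tibble per (hmdb_id, condition): `stability_pct` and `pass`.
#' @examples
#' d <- tibble::tibble(arm = c("stored", "fresh"), response = c(95, 100))
#' stability_pct(d)  # 95%, pass
#' @export
stability_pct <- function(design, band = c(85, 115)) {
  stopifnot(all(c("arm", "response") %in% names(design)),
            length(band) == 2, band[1] < band[2])
  m <- design |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("hmdb_id", "condition"))),
                    .data$arm) |>
    dplyr::summarise(mean = mean(.data$response, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "mean")
  if (!all(c("stored", "fresh") %in% names(m)))
    stop_domain("stability design needs paired 'stored' and 'fresh' arms")
  pct <- ifelse(m$fresh > 0, 100 * m$stored / m$fresh, NA_real_)
  dplyr::bind_cols(
    dplyr::select(m, dplyr::any_of(c("hmdb_id", "condition"))),
    tibble::tibble(stability_pct = pct,
                   pass = !is.na(pct) & pct >= band[1] & pct <= band[2]))
}

#' Assemble a method-validation report
#'
#' Per-metabolite, per-level validation tables with pass/fail calls against
#' the configured acceptance bands, plus summary counts: the fraction of
#' metabolites with recovery in the reliable 50-120% band, the unreliable
#' (< 30%) list, and stability/precision pass fractions. Sections whose
#' designs are absent are omitted with a notice.
#'
#' @param panel An `sq_panel` (used for naming; metabolites without designs
#'   simply do not appear).
#' @param spike_designs Long spike-design data frame (see [spike_design()];
#'   multiple metabolites/levels may be row-bound) or `NULL`.
#' @param stability_designs Long stability data frame or `NULL`.
#' @param precision_data Data frame with `hmdb_id`, `level`, `batch`,
#'   `response` or `NULL`.
#' @param recovery_band,me_band,stability_band,cv_max Acceptance bands.
#' @return An `sq_validation_report` list with one tibble per available
#'   section, `summary`, and `notices`.
#' @export
validation_report <- function(panel, spike_designs = NULL,
                              stability_designs = NULL,
                              precision_data = NULL,
                              recovery_band = c(50, 120),
                              me_band = c(0.6, 1.8),
                              stability_band = c(85, 115),
                              cv_max = 15) {
  sections <- list()
  notices <- character()
  summary_rows <- list()

  if (!is.null(spike_designs) && nrow(spike_designs) > 0) {
    rec <- recovery_pct(spike_designs) |>
      dplyr::mutate(pass = !.data$undefined &
                      .data$recovery_pct >= recovery_band[1] &
                      .data$recovery_pct <= recovery_band[2],
                    unreliable = !is.na(.data$recovery_pct) & .data$recovery_pct < 30)
    me <- matrix_effect(spike_designs) |>
      dplyr::mutate(pass = .data$matrix_effect >= me_band[1] &
                      .data$matrix_effect <= me_band[2])
    sections$recovery <- rec
    sections$matrix_effect <- me
    summary_rows$recovery <- tibble::tibble(
      section = "recovery",
      n = dplyr::n_distinct(rec$hmdb_id),
      pass_fraction = mean(rec$pass, na.rm = TRUE))
    summary_rows$unreliable <- tibble::tibble(
      section = "recovery_below_30pct",
      n = dplyr::n_distinct(rec$hmdb_id[rec$unreliable]),
      pass_fraction = NA_real_)
  } else notices <- c(notices, "no spike designs supplied; recovery/matrix-effect sections omitted")

  if (!is.null(stability_designs) && nrow(stability_designs) > 0) {
    st <- stability_pct(stability_designs, band = stability_band)
    sections$stability <- st
    summary_rows$stability <- tibble::tibble(
      section = "stability", n = nrow(st), pass_fraction = mean(st$pass))
  } else notices <- c(notices, "no stability designs supplied; stability section omitted")

  if (!is.null(precision_data) && nrow(precision_data) > 0) {
    pr <- precision_data |>
      dplyr::group_by(dplyr::across(dplyr::any_of(c("hmdb_id", "level")))) |>
      dplyr::summarise(cv_pct = cv_pct(.data$response), .groups = "drop") |>
      dplyr::mutate(pass = !is.na(.data$cv_pct) & .data$cv_pct <= cv_max)
    sections$precision <- pr
    summary_rows$precision <- tibble::tibble(
      section = "precision", n = nrow(pr), pass_fraction = mean(pr$pass))
  } else notices <- c(notices, "no precision data supplied; precision section omitted")

  structure(list(sections = sections,
                 summary = dplyr::bind_rows(summary_rows),
                 notices = notices),
            class = "sq_validation_report")
}

#' @export
print.sq_validation_report <- function(x, ...) {
  cat("<sq_validation_report>\n")
  if (nrow(x$summary) > 0) print(x$summary)
  for (n in x$notices) cat(" note:", n, "\n")
  invisible(x)
}
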
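#' Double randomization of sample processing order
#'
#' Samples are randomized twice — once before extraction and once before
#' injection — so that neither bench position nor acquisition order tracks
#' the phenotype. Both permutations come from one seeded generator and are
#' reproducible. A blocking guard rejects (and redraws) injection orders in
#' which any phenotype group occupies a contiguous block longer than
#' `ceiling(2 * max(group size) / n_groups)`, protecting against accidental
#' group blocking in small batches.
#'
#' @param sample_ids Character vector of sample ids.
#' @param groups Optional named vector mapping sample id to phenotype group.
#' @param seed Integer seed (mandatory).
#' @param max_tries Redraws allowed against the blocking guard.
#' @return A list with `extraction_order` and `injection_order`.
#' @export
double_randomize <- function(sample_ids, groups = NULL, seed, max_tries = 100) {
  stopifnot(length(sample_ids) >= 1, !missing(seed))
  with_seed(as.integer(seed), {
    extraction <- sample(sample_ids)
    guard <- function(ord) {
      if (is.null(groups) || dplyr::n_distinct(groups) < 2) return(TRUE)
      g <- unname(groups[ord])
      limit <- ceiling(2 * max(table(groups)) / dplyr::n_distinct(groups))
      max(rle(g)$lengths) <= limit
    }
    injection <- sample(sample_ids)
    tries <- 1
    while (!guard(injection) && tries < max_tries) {
      injection <- sample(sample_ids)
      tries <- tries + 1
    }
    list(extraction_order = extraction, injection_order = injection)
  })
}

#' Build a batch injection layout
#'
#' Calibration standards are injected first. In the post-standard segment,
#' every fifth position is a blank, and a pooled-serum QC follows every run
#' of ten experimental samples. When a due QC would land on a blank
#' position, the blank keeps the slot and the QC shifts to the next
#' position (deterministic collision rule).
#'
#' @param samples Character vector of experimental sample ids in injection
#'   order (may be empty).
#' @param n_standards Number of calibration standards injected first
#'   (default 11).
#' @return A `BatchLayout` tibble: `position` (1-based overall), `role`
#'   (`standard` / `blank` / `qc` / `sample`), `sample_id`.
#' @examples
#' build_layout(paste0("S", 1:10))  # exactly one interspersed QC
#' @export
build_layout <- function(samples, n_standards = 11) {
  rows <- list()
  for (i in seq_len(n_standards)) {
    rows[[length(rows) + 1]] <- list(role = "standard",
                                     sample_id = sprintf("STD-%02d", i))
  }
  qc_i <- 0L
  blank_i <- 0L
  since_qc <- 0L
  pending_qc <- FALSE
  next_sample <- 1L
  pos_post <- 0L
  while (next_sample <= length(samples) || pending_qc) {
    pos_post <- pos_post + 1L
    if (pos_post %% 5L == 0L) {
      blank_i <- blank_i + 1L
      rows[[length(rows) + 1]] <- list(role = "blank",
                                       sample_id = sprintf("BLANK-%02d", blank_i))
    } else if (pending_qc) {
      qc_i <- qc_i + 1L
      rows[[length(rows) + 1]] <- list(role = "qc",
                                       sample_id = sprintf("QC-%02d", qc_i))
      pending_qc <- FALSE
    } else {
      rows[[length(rows) + 1]] <- list(role = "sample",
                                       sample_id = samples[next_sample])
      next_sample <- next_sample + 1L
      since_qc <- since_qc + 1L
      if (since_qc == 10L) {
        pending_qc <- TRUE
        since_qc <- 0L
      }
    }
  }
  tibble::tibble(position = seq_along(rows),
                 role = vapply(rows, `[[`, "", "role"),
                 sample_id = vapply(rows, `[[`, "", "sample_id"))
}

#' Per-batch QC statistics
#'
#' Mean concentration and sample-SD-based %CV of the QC replicates in one
#' batch, per metabolite. Fewer than two replicates leaves the CV missing.
#'
#' @param qc_conc Data frame with `hmdb_id` and `conc` columns (one row per
#'   QC replicate measurement).
#' @return A tibble per metabolite: `n`, `mean_conc`, `cv_pct`.
#' @export
qc_batch_stats <- function(qc_conc) {
  stopifnot(all(c("hmdb_id", "conc") %in% names(qc_conc)))
  qc_conc |>
    dplyr::group_by(.data$hmdb_id) |>
    dplyr::summarise(n = sum(!is.na(.data$conc)),
                     mean_conc = mean(.data$conc, na.rm = TRUE),
                     cv_pct = cv_pct(.data$conc), .groups = "drop")
}

#' Read / write a QC history database
#'
#' The QC history is an append-only CSV with schema
#' `qc_lot, batch_id, run_date, hmdb_id, conc_umol_l`, one row per QC
#' replicate measurement accumulated across batches and years.
#'
#' @param path CSV path.
#' @param history A QC history tibble.
#' @param append Append to an existing file instead of overwriting.
#' @return `read_qc_history()` returns the history tibble.
#' @name qc_history_io
NULL

#' @rdname qc_history_io
#' @export
read_qc_history <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(qc_lot = "c", batch_id = "c",
                                          run_date = "D", hmdb_id = "c",
                                          conc_umol_l = "d"))
}

#' @rdname qc_history_io
#' @export
write_qc_history <- function(history, path, append = FALSE) {
  readr::write_csv(history, path, append = append && file.exists(path))
  invisible(path)
}

#' Inter-day RSD of a QC history
#'
#' The drift reference: per metabolite, the CV (percent) of per-batch mean
#' QC concentrations across all batches in the history.
#'
#' @param history QC history tibble (see [read_qc_history()]).
#' @return A tibble per metabolite: `n_batches`, `interday_rsd_pct`.
#' @export
history_interday_rsd <- function(history) {
  stopifnot(all(c("batch_id", "hmdb_id", "conc_umol_l") %in% names(history)))
  history |>
    dplyr::group_by(.data$hmdb_id, .data$batch_id) |>
    dplyr::summarise(batch_mean = mean(.data$conc_umol_l, na.rm = TRUE),
                     .groups = "drop_last") |>
    dplyr::summarise(n_batches = dplyr::n(),
                     interday_rsd_pct = cv_pct(.data$batch_mean),
                     .groups = "drop")
}

#' Compare current-batch QC spread against the history database
#'
#' A batch passes for a metabolite when its QC RSD does not exceed the
#' historical inter-day RSD inflated by the relative tolerance:
#' `batch RSD <= history RSD * (1 + tolerance_pct / 100)`. Metabolites
#' absent from the history get status `unknown`.
#'
#' @param batch_stats Output of [qc_batch_stats()] for the current batch.
#' @param history QC history tibble.
#' @param tolerance_pct Allowed relative excess over the historical RSD
#'   (default 20).
#' @return A tibble per metabolite: `batch_rsd`, `history_rsd`, `status`
#'   (`pass` / `warn` / `unknown`).
#' @export
compare_to_history <- function(batch_stats, history, tolerance_pct = 20) {
  ref <- history_interday_rsd(history)
  batch_stats |>
    dplyr::left_join(ref, by = "hmdb_id") |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$interday_rsd_pct) ~ "unknown",
        is.na(.data$cv_pct) ~ "unknown",
        .data$cv_pct <= .data$interday_rsd_pct * (1 + tolerance_pct / 100) ~ "pass",
        TRUE ~ "warn")) |>
    dplyr::select("hmdb_id", batch_rsd = "cv_pct",
                  history_rsd = "interday_rsd_pct", "status")
}

#' Long-term reproducibility summary across batches
#'
#' Per-metabolite CVs of QC concentration, retention time and calibration
#' R-squared across batches, with the fraction of metabolites under the
#' configured tiers: concentration CV < 25%, RT CV < 4%, R-squared CV < 3%.
#'
#' @param batch_summaries Data frame with one row per (batch, metabolite):
#'   columns `batch_id`, `hmdb_id`, and any of `qc_conc`, `rt`, `r_squared`.
#' @param conc_tier,rt_tier,r2_tier CV tier thresholds in percent.
#' @return A list with `per_metabolite` (CV table) and `tiers` (one-row
#'   tibble of fractions below each tier).
#' @export
reproducibility_summary <- function(batch_summaries, conc_tier = 25,
                                    rt_tier = 4, r2_tier = 3) {
  stopifnot(all(c("batch_id", "hmdb_id") %in% names(batch_summaries)))
  if (dplyr::n_distinct(batch_summaries$batch_id) < 2)
    stop_domain("need >= 2 batches for a reproducibility summary")
  per <- batch_summaries |>
    dplyr::group_by(.data$hmdb_id) |>
    dplyr::summarise(
      n_batches = dplyr::n_distinct(.data$batch_id),
      conc_cv_pct = if ("qc_conc" %in% names(batch_summaries)) cv_pct(.data$qc_conc) else NA_real_,
      rt_cv_pct = if ("rt" %in% names(batch_summaries)) cv_pct(.data$rt) else NA_real_,
      r2_cv_pct = if ("r_squared" %in% names(batch_summaries)) cv_pct(.data$r_squared) else NA_real_,
      .groups = "drop")
  tiers <- tibble::tibble(
    frac_conc_cv_below_tier = mean(per$conc_cv_pct < conc_tier, na.rm = TRUE),
    frac_rt_cv_below_tier = mean(per$rt_cv_pct < rt_tier, na.rm = TRUE),
    frac_r2_cv_below_tier = mean(per$r2_cv_pct < r2_tier, na.rm = TRUE),
    conc_tier = conc_tier, rt_tier = rt_tier, r2_tier = r2_tier)
  list(per_metabolite = per, tiers = tiers)
}
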
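#' Unit-conversion and correction primitives
#'
#' The correction chain converting raw instrument readings into final
#' concentrations is purely multiplicative; each primitive validates its
#' domain and is vectorized.
#'
#' * `mw_normalize()` — ppb (ug/L) divided by molecular weight (g/mol)
#'   gives umol/L.
#' * `apply_process_efficiency()` — divides by the process-efficiency
#'   fraction (recovery x matrix effect) to undo signal attenuation for
#'   metabolites quantified without their own labeled internal standard.
#' * `apply_dilution()` — multiplies by the dilution factor (>= 1).
#' * `normalize_per_cells()` — converts umol/L of extract to umol per
#'   million cells: `conc * extract_volume_l * 1e6 / cell_count`.
#' * `normalize_per_tissue()` — converts umol/L of extract to umol/g:
#'   `conc * extract_volume_l / tissue_weight_g`. Tissue weight must be in
#'   grams; values >= 1000 are rejected as a unit-mismatch guard (a
#'   milligram figure passed as grams).
#'
#' @param conc_ppb,conc Concentration values (>= 0).
#' @param molecular_weight Average molecular weight, g/mol (> 0).
#' @param pe Process-efficiency fraction (> 0).
#' @param dilution_factor Dilution factor (>= 1).
#' @param extract_volume_l Extraction volume in litres (> 0).
#' @param cell_count Number of cells (> 0).
#' @param tissue_weight_g Tissue weight in grams (> 0, < 1000).
#' @return Numeric vector of corrected concentrations.
#' @examples
#' mw_normalize(180.16, 180.16)          # 1 umol/L
#' apply_process_efficiency(5, 0.5)      # 10
#' normalize_per_tissue(1, 1e-4, 0.02)   # 5e-3 umol/g
#' @name corrections
NULL

#' @rdname corrections
#' @export
mw_normalize <- function(conc_ppb, molecular_weight) {
  if (any(molecular_weight <= 0, na.rm = TRUE))
    stop_domain("molecular_weight must be positive")
  if (any(conc_ppb < 0, na.rm = TRUE)) stop_domain("concentration must be >= 0")
  conc_ppb / molecular_weight
}

#' @rdname corrections
#' @export
apply_process_efficiency <- function(conc, pe) {
  if (any(pe <= 0, na.rm = TRUE)) stop_domain("process efficiency must be positive")
  conc / pe
}

#' @rdname corrections
#' @export
apply_dilution <- function(conc, dilution_factor) {
  if (any(dilution_factor < 1, na.rm = TRUE))
    stop_domain("dilution_factor must be >= 1")
  conc * dilution_factor
}

#' @rdname corrections
#' @export
normalize_per_cells <- function(conc, extract_volume_l, cell_count) {
  if (any(extract_volume_l <= 0, na.rm = TRUE))
    stop_domain("extract_volume_l must be positive")
  if (any(cell_count <= 0, na.rm = TRUE)) stop_domain("cell_count must be positive")
  conc * extract_volume_l * 1e6 / cell_count
}

#' @rdname corrections
#' @export
normalize_per_tissue <- function(conc, extract_volume_l, tissue_weight_g) {
  if (any(extract_volume_l <= 0, na.rm = TRUE))
    stop_domain("extract_volume_l must be positive")
  if (any(tissue_weight_g <= 0, na.rm = TRUE))
    stop_domain("tissue_weight_g must be positive")
  if (any(tissue_weight_g >= 1000, na.rm = TRUE))
    stop_domain("tissue_weight_g >= 1000: weight must be given in grams, not milligrams")
  conc * extract_volume_l / tissue_weight_g
}

#' Quantify a parsed batch through the full correction chain
#'
#' Applies, in a fixed order, to every QC and experimental-sample injection:
#' concentration intake (reported ppb, or back-calculation through the
#' per-metabolite calibration fit when starting from peak areas) ->
#' molecular-weight normalization -> process-efficiency correction ->
#' dilution correction -> matrix-specific normalization (per gram of tissue
#' or per million cells; biofluids stay volumetric). The steps are all
#' multiplicative, so the order does not change the value; it is fixed for
#' provenance reproducibility. Every factor is recorded in a `factor_*`
#' column and `value == raw * factor_mw * factor_pe * factor_dilution *
#' factor_matrix` holds exactly for every row.
#'
#' Values falling outside a metabolite's calibrated `[lloq, uloq]` (in ppb,
#' pre-correction scale) are flagged `below_lloq` / `above_uloq` but the
#' value is always retained, never imputed, zeroed or dropped.
#'
#' @param batch An `sq_batch` with attached metadata.
#' @param panel An `sq_panel`.
#' @param fits Optional named list of `sq_curvefit` objects (by HMDB id).
#'   Required (per metabolite) when `from = "peak_area"`; when quantifying
#'   from reported ppb they only supply LLOQ/ULOQ flags.
#' @param from `"conc_ppb"` (default) or `"peak_area"`.
#' @param extract_volume_l Extraction volume used for per-tissue / per-cell
#'   normalization (default 1e-4 L = 100 uL).
#' @return An `sq_quant` tibble, one row per (injection, metabolite), with
#'   `value`, its `unit`, flag columns and the provenance `factor_*` columns.
#' @export
quantify_batch <- function(batch, panel, fits = NULL,
                           from = c("conc_ppb", "peak_area"),
                           extract_volume_l = 1e-4) {
  stopifnot(inherits(batch, "sq_batch"), inherits(panel, "sq_panel"))
  from <- match.arg(from)
  if (is.null(batch$metadata))
    stop_validation("batch has no metadata; every sample needs matrix_type and dilution_factor")
  meta <- batch$metadata

  rec <- batch$records |>
    dplyr::filter(.data$sample_type %in% c("sample", "qc")) |>
    dplyr::left_join(meta, by = "sample_id", suffix = c("", ".meta")) |>
    dplyr::left_join(dplyr::select(panel$entries, "hmdb_id", "molecular_weight",
                                   "process_efficiency", "default_dilution"),
                     by = "hmdb_id")

  in_panel <- !is.na(rec$molecular_weight)
  if (any(!in_panel)) {
    warn(paste0("skipping metabolite(s) not in panel: ",
                paste(unique(rec$hmdb_id[!in_panel]), collapse = ", ")))
    rec <- rec[in_panel, , drop = FALSE]
  }
  if (nrow(rec) == 0)
    stop_validation("no quantifiable records: no batch metabolite matches the panel")

  if (from == "peak_area") {
    if (is.null(fits)) stop_validation("fits are required when quantifying from peak areas")
    have_fit <- rec$hmdb_id %in% names(fits)
    if (any(!have_fit)) {
      warn(paste0("no calibration fit; metabolite(s) skipped: ",
                  paste(unique(rec$hmdb_id[!have_fit]), collapse = ", ")))
      rec <- rec[have_fit, , drop = FALSE]
    }
    ratio <- ifelse(is.na(rec$is_area) | rec$is_area == 0,
                    rec$peak_area, rec$peak_area / rec$is_area)
    raw <- rep(NA_real_, nrow(rec))
    for (id in unique(rec$hmdb_id)) {
      i <- rec$hmdb_id == id
      raw[i] <- back_calculate(fits[[id]], ratio[i])
    }
  } else {
    raw <- rec$conc_ppb
  }

  dil <- dplyr::coalesce(rec$dilution_factor, rec$default_dilution, 1)
  matrix_type <- dplyr::coalesce(rec$matrix_type, "biofluid")
  factor_matrix <- dplyr::case_when(
    matrix_type == "tissue" ~ extract_volume_l / (rec$tissue_weight_mg / 1000),
    matrix_type == "cells" ~ extract_volume_l * 1e6 / rec$cell_count,
    TRUE ~ 1)
  bad_tissue <- matrix_type == "tissue" &
    (is.na(rec$tissue_weight_mg) | rec$tissue_weight_mg <= 0)
  bad_cells <- matrix_type == "cells" &
    (is.na(rec$cell_count) | rec$cell_count <= 0)
  if (any(bad_tissue | bad_cells))
    stop_validation(paste0("missing/non-positive tissue weight or cell count for sample(s): ",
                           paste(unique(rec$sample_id[bad_tissue | bad_cells]),
                                 collapse = ", ")))

  out <- tibble::tibble(
    sample_id = rec$sample_id,
    injection_index = rec$injection_index,
    sample_type = rec$sample_type,
    phenotype_group = rec$phenotype_group,
    qc_lot = if ("qc_lot" %in% names(rec)) rec$qc_lot else NA_character_,
    hmdb_id = rec$hmdb_id,
    compound = rec$compound,
    raw = raw,
    factor_mw = 1 / rec$molecular_weight,
    factor_pe = 1 / rec$process_efficiency,
    factor_dilution = dil,
    factor_matrix = factor_matrix,
    unit = dplyr::case_when(matrix_type == "tissue" ~ "umol/g",
                            matrix_type == "cells" ~ "umol/1e6 cells",
                            TRUE ~ "umol/L"))
  out$value <- out$raw * out$factor_mw * out$factor_pe *
    out$factor_dilution * out$factor_matrix
  out$missing <- is.na(out$value)

  out$below_lloq <- FALSE
  out$above_uloq <- FALSE
  if (!is.null(fits)) {
    for (id in intersect(unique(out$hmdb_id), names(fits))) {
      f <- fits[[id]]
      if (is.na(f$lloq)) next
      i <- out$hmdb_id == id & !is.na(out$raw)
      out$below_lloq[i] <- out$raw[i] < f$lloq
      out$above_uloq[i] <- out$raw[i] > f$uloq
    }
  }
  class(out) <- c("sq_quant", class(out))
  out
}

#' Phenotype-group statistics and outlier marking
#'
#' For each (phenotype group, metabolite) cell population the mean, sample
#' standard deviation (n - 1) and RSD (100 * SD / mean) are computed over
#' non-missing values, and each value is marked `outlier_1sd` when it lies
#' more than one SD from its group mean, plus `outlier_2sd` beyond two SDs.
#' The candidate point stays in the mean/SD it is judged against (marking,
#' not trimming), and groups of size one get no statistics and no flags.
#'
#' @param table An `sq_quant` from [quantify_batch()].
#' @param groups Optional named character vector mapping `sample_id` to
#'   group; defaults to the `phenotype_group` metadata column.
#' @param sd_thresholds Two increasing thresholds in SD units (default 1, 2).
#' @return The input with `group_mean`, `group_sd`, `group_rsd`,
#'   `outlier_1sd` and `outlier_2sd` columns added (experimental samples
#'   only; QC rows keep `NA` statistics).
#' @export
group_stats <- function(table, groups = NULL, sd_thresholds = c(1, 2)) {
  stopifnot(inherits(table, "sq_quant"), length(sd_thresholds) == 2,
            sd_thresholds[1] < sd_thresholds[2])
  if (!is.null(groups)) table$phenotype_group <- unname(groups[table$sample_id])
  out <- table |>
    dplyr::group_by(.data$hmdb_id, .data$phenotype_group) |>
    dplyr::mutate(
      .n_obs = sum(!is.na(.data$value) & .data$sample_type == "sample"),
      group_mean = ifelse(.data$sample_type == "sample" & .data$.n_obs >= 2,
                          mean(.data$value[.data$sample_type == "sample"], na.rm = TRUE),
                          NA_real_),
      group_sd = ifelse(.data$sample_type == "sample" & .data$.n_obs >= 2,
                        stats::sd(.data$value[.data$sample_type == "sample"], na.rm = TRUE),
                        NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      group_rsd = 100 * .data$group_sd / .data$group_mean,
      outlier_1sd = !is.na(.data$group_sd) & !is.na(.data$value) &
        abs(.data$value - .data$group_mean) > sd_thresholds[1] * .data$group_sd,
      outlier_2sd = !is.na(.data$group_sd) & !is.na(.data$value) &
        abs(.data$value - .data$group_mean) > sd_thresholds[2] * .data$group_sd) |>
    dplyr::select(-".n_obs")
  class(out) <- c("sq_quant", setdiff(class(out), "sq_quant"))
  out
}
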
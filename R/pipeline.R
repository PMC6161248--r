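#' Configure an end-to-end processing run
#'
#' Bundles the file paths and thresholds one batch run needs. A YAML file
#' with the same field names can be loaded with [load_run_config()]; every
#' threshold defaults to the package's standard value and is echoed into
#' the run log for provenance.
#'
#' @param flatfile Flat-text export path.
#' @param metadata Batch metadata CSV path.
#' @param panel Panel file path, or `NULL` for the packaged serum panel.
#' @param history Optional QC history CSV path (enables the drift check).
#' @param out_dir Output directory.
#' @param sd_thresholds Outlier thresholds in SD units (default `c(1, 2)`).
#' @param carryover_pct Carryover acceptance threshold (default 20).
#' @param qc_tolerance_pct Drift-check relative tolerance (default 20).
#' @param stability_band Stability acceptance band (default `c(85, 115)`).
#' @param seed Integer seed for any stochastic step (default 1).
#' @return An `sq_run_config` list.
#' @export
run_config <- function(flatfile, metadata, panel = NULL, history = NULL,
                       out_dir = "semiquantr_out",
                       sd_thresholds = c(1, 2), carryover_pct = 20,
                       qc_tolerance_pct = 20, stability_band = c(85, 115),
                       seed = 1) {
  for (p in c(flatfile, metadata, panel, history))
    if (!is.null(p) && !file.exists(p))
      stop_validation(paste0("path does not exist: ", p))
  stopifnot(carryover_pct > 0, qc_tolerance_pct >= 0)
  structure(list(flatfile = flatfile, metadata = metadata, panel = panel,
                 history = history, out_dir = out_dir,
                 sd_thresholds = sd_thresholds,
                 carryover_pct = carryover_pct,
                 qc_tolerance_pct = qc_tolerance_pct,
                 stability_band = stability_band, seed = as.integer(seed)),
            class = "sq_run_config")
}

#' @rdname run_config
#' @param path YAML config path.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full processing workflow on one batch
#'
#' parse -> calibrate (from the in-batch standards, model selection per
#' metabolite) -> quantify through the correction chain -> phenotype-group
#' statistics and outlier marking -> QC drift check against the history
#' database (when supplied) -> workbook output. Every decision (flags,
#' fallbacks, thresholds) is appended to a structured log file, partial
#' artifacts are preserved on failure, and a QC hard-fail (any metabolite
#' whose batch RSD exceeds the history tolerance) yields a nonzero status.
#'
#' @param config An `sq_run_config`.
#' @return Invisibly, a list with `status` (0 ok, 3 QC fail), `workbook`,
#'   `fits_csv`, `qc_check`, `log` and the in-memory `quant` table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sq_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("run started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  log_line("thresholds: sd=%s carryover<=%.1f%% qc_tolerance=%.1f%% seed=%d",
           paste(config$sd_thresholds, collapse = "/"),
           config$carryover_pct, config$qc_tolerance_pct, config$seed)

  panel <- if (is.null(config$panel)) default_panel() else load_panel(config$panel)
  log_line("panel: %d metabolites, %d classes",
           nrow(panel$entries), dplyr::n_distinct(panel$entries$class))

  batch <- parse_flatfile(config$flatfile, panel = panel,
                          metadata = read_batch_metadata(config$metadata))
  log_line("parsed '%s': %d injections x %d metabolites", batch$batch_id,
           dplyr::n_distinct(batch$records$injection_index),
           dplyr::n_distinct(batch$records$hmdb_id))

  # calibration from the in-batch standards (response = area / IS area)
  std <- dplyr::filter(batch$records, .data$sample_type == "standard")
  fits <- list()
  if (nrow(std) > 0) {
    for (id in unique(std$hmdb_id)) {
      s <- std[std$hmdb_id == id, ]
      series <- tibble::tibble(
        nominal_conc = s$std_conc,
        response = ifelse(is.na(s$is_area) | s$is_area == 0,
                          s$peak_area, s$peak_area / s$is_area))
      f <- tryCatch(select_model(series), error = function(e) NULL)
      if (is.null(f)) {
        log_line("calibration failed for %s; metabolite not flagged for LOQ", id)
      } else {
        fits[[id]] <- f
        if (f$rejected) log_line("calibration rejected (no passing level): %s", id)
      }
    }
    fit_tbl <- purrr::imap_dfr(fits, function(f, id)
      dplyr::bind_cols(tibble::tibble(hmdb_id = id), glance(f)))
    fits_csv <- file.path(config$out_dir, "calibration_fits.csv")
    readr::write_csv(fit_tbl, fits_csv)
    log_line("calibration: %d curves fitted, median R²=%.4f", nrow(fit_tbl),
             stats::median(fit_tbl$r.squared))
  } else {
    fits_csv <- NULL
    log_line("no standards in batch; LOQ flags unavailable")
  }

  quant <- quantify_batch(batch, panel, fits = if (length(fits)) fits) |>
    group_stats(sd_thresholds = config$sd_thresholds)
  log_line("quantified %d sample x metabolite cells; %d below LLOQ, %d above ULOQ, %d outliers",
           nrow(quant), sum(quant$below_lloq), sum(quant$above_uloq),
           sum(quant$outlier_1sd, na.rm = TRUE))

  workbook <- write_workbook(quant, file.path(config$out_dir, "results"))
  log_line("workbook written: %s", workbook)

  status <- 0L
  qc_check_csv <- NULL
  qc_rows <- dplyr::filter(quant, .data$sample_type == "qc")
  if (!is.null(config$history) && nrow(qc_rows) > 0) {
    stats_tbl <- qc_batch_stats(dplyr::select(qc_rows, "hmdb_id", conc = "value"))
    check <- compare_to_history(stats_tbl, read_qc_history(config$history),
                                tolerance_pct = config$qc_tolerance_pct)
    qc_check_csv <- file.path(config$out_dir, "qc_check.csv")
    readr::write_csv(check, qc_check_csv)
    n_warn <- sum(check$status == "warn")
    log_line("QC drift check: %d pass, %d warn, %d unknown",
             sum(check$status == "pass"), n_warn,
             sum(check$status == "unknown"))
    if (n_warn > 0) {
      status <- 3L
      log_line("QC HARD FAIL: batch RSD exceeds history tolerance for %d metabolite(s)",
               n_warn)
    }
  }
  log_line("run finished with status %d", status)
  invisible(list(status = status, workbook = workbook, fits_csv = fits_csv,
                 qc_check = qc_check_csv, log = log_path, quant = quant))
}
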
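#' Configure a synthetic targeted-metabolomics study
#'
#' Defines the ground truth a simulated study is generated from: panel size,
#' per-group true concentrations, proportional measurement noise, QC-lot
#' log-scale spread, extraction efficiency and matrix effect, retention
#' times and drift, carryover, and the calibration design. Every generator
#' in the package is a pure function of `(config, seed)`.
#'
#' Defaults emulate a well-behaved serum assay: 5% proportional
#' concentration noise, QC lot SD 0.1 and residual SD 0.2 on the log scale,
#' extraction efficiency 0.7, matrix-effect ratio 1.2 (mild ion
#' enhancement), retention-time jitter at 1% CV, no carryover, and an
#' 11-level two-fold serial dilution (1024-fold dynamic range).
#'
#' @param seed Integer seed (mandatory).
#' @param n_metabolites Number of synthetic metabolites (default 10, spread
#'   over 3 classes; the `"paper_scale"` preset of [simulate_batch()] uses
#'   the packaged 102-metabolite panel).
#' @param n_samples Experimental samples per batch (default 20).
#' @param n_groups Phenotype groups (default 2).
#' @param group_truth Optional matrix (`n_metabolites` x `n_groups`) of true
#'   concentrations in umol/L; drawn log-uniformly from 0.5-200 umol/L when
#'   omitted.
#' @param noise_cv Proportional measurement noise, percent (default 5).
#' @param lot_sd_log QC lot random-effect SD on the log scale (default 0.1).
#' @param qc_noise_sd_log QC residual SD on the log scale (default 0.2).
#' @param extraction_efficiency True extraction recovery fraction (default 0.7).
#' @param matrix_factor True matrix-effect ratio (default 1.2).
#' @param rt_drift_cv Retention-time jitter CV, percent (default 1; kept
#'   small so simulated assays stay within the ~4% long-term drift a
#'   stable platform exhibits).
#' @param carryover_frac Fraction of the preceding injection's peak area
#'   leaking into a blank (default 0).
#' @param top_conc,n_levels,dilution_factor Calibration design (defaults
#'   1000, 11, 2).
#' @return An `sq_sim_config` list.
#' @export
sim_config <- function(seed,
                       n_metabolites = 10,
                       n_samples = 20,
                       n_groups = 2,
                       group_truth = NULL,
                       noise_cv = 5,
                       lot_sd_log = 0.1,
                       qc_noise_sd_log = 0.2,
                       extraction_efficiency = 0.7,
                       matrix_factor = 1.2,
                       rt_drift_cv = 1,
                       carryover_frac = 0,
                       top_conc = 1000,
                       n_levels = 11,
                       dilution_factor = 2) {
  if (missing(seed)) stop_domain("seed is mandatory")
  stopifnot(n_metabolites >= 1, n_samples >= 0, n_groups >= 1,
            noise_cv >= 0, lot_sd_log >= 0, qc_noise_sd_log >= 0,
            extraction_efficiency > 0, extraction_efficiency <= 2,
            matrix_factor > 0, matrix_factor <= 2,
            carryover_frac >= 0, carryover_frac <= 1)
  cfg <- list(seed = as.integer(seed), n_metabolites = n_metabolites,
              n_samples = n_samples, n_groups = n_groups,
              group_truth = group_truth, noise_cv = noise_cv,
              lot_sd_log = lot_sd_log, qc_noise_sd_log = qc_noise_sd_log,
              extraction_efficiency = extraction_efficiency,
              matrix_factor = matrix_factor, rt_drift_cv = rt_drift_cv,
              carryover_frac = carryover_frac,
              top_conc = top_conc, n_levels = n_levels,
              dilution_factor = dilution_factor)
  class(cfg) <- "sq_sim_config"
  cfg
}

# multiplicative Gaussian noise truncated at -1 so values stay positive
prop_noise <- function(n, cv_pct) {
  eps <- rnorm(n, 0, cv_pct / 100)
  1 + pmax(eps, -0.999)
}

#' Simulate a synthetic metabolite panel
#'
#' `n_metabolites` synthetic entries (`SYN000001`, ...) across three
#' classes, with molecular weights drawn uniformly in 75-500 g/mol and the
#' configured true process efficiency
#' (`extraction_efficiency * matrix_factor`) written into the
#' `process_efficiency` column — so quantification through the panel undoes
#' exactly the attenuation the generator applies.
#'
#' @param config An `sq_sim_config`.
#' @return An `sq_panel` with a `truth` attribute (per-metabolite tibble:
#'   molecular weight, RT, process efficiency).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sq_sim_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_metabolites
    classes <- rep(c("Synthetic Class A", "Synthetic Class B",
                     "Synthetic Class C"), length.out = n)
    entries <- tibble::tibble(
      name = sprintf("SynMet%03d", seq_len(n)),
      hmdb_id = sprintf("SYN%06d", seq_len(n)),
      class = sort(classes),
      molecular_weight = round(runif(n, 75, 500), 2),
      internal_standard = rep(c("IS-A", "IS-B", "IS-C"), length.out = n),
      process_efficiency = config$extraction_efficiency * config$matrix_factor,
      default_dilution = 1)
    rt_true <- round(runif(n, 1, 16), 3)
    p <- new_panel(entries)
    attr(p, "truth") <- tibble::tibble(hmdb_id = entries$hmdb_id,
                                       molecular_weight = entries$molecular_weight,
                                       rt_true = rt_true,
                                       process_efficiency = entries$process_efficiency)
    p
  })
}

#' Simulate heteroscedastic calibration series
#'
#' For each metabolite an 11-level (by default) serial-dilution series is
#' generated from a known true line through the origin with proportional
#' noise: `response = slope * conc * (1 + N(0, noise_cv))`. Proportional
#' noise is exactly the heteroscedasticity that motivates `1/x` weighting
#' and log-log fitting.
#'
#' @param config An `sq_sim_config`.
#' @param seed_offset Added to `config$seed`, letting callers draw many
#'   independent series from one config.
#' @return A list: `series` (tibble with `hmdb_id`, `level`,
#'   `nominal_conc`, `response`) and `truth` (per-metabolite true slope).
#' @export
simulate_calibration <- function(config, seed_offset = 0L) {
  stopifnot(inherits(config, "sq_sim_config"))
  design <- make_serial_dilution(config$top_conc, config$n_levels,
                                 config$dilution_factor)
  with_seed(config$seed + 2L + as.integer(seed_offset), {
    n <- config$n_metabolites
    slope <- runif(n, 0.5, 5)
    series <- purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(hmdb_id = sprintf("SYN%06d", i),
                     level = design$level,
                     nominal_conc = design$nominal_conc,
                     response = slope[i] * design$nominal_conc *
                       prop_noise(nrow(design), config$noise_cv))
    })
    list(series = series,
         truth = tibble::tibble(hmdb_id = sprintf("SYN%06d", seq_len(n)),
                                slope = slope, intercept = 0))
  })
}

#' Simulate a full batch as a flat-file export
#'
#' Generates a complete acquisition in the exact flat-file dialect
#' [parse_flatfile()] reads: calibration standards first, then experimental
#' samples interleaved with blanks (every fifth post-standard position) and
#' pooled-serum QCs (after every tenth experimental sample), per
#' [build_layout()]. Reported ppb concentrations encode the generator
#' truth: `ppb = true_umol_L * MW * PE_true * noise / dilution`, so the
#' quantification chain (MW, process-efficiency and dilution corrections)
#' recovers the group truths. Blank injections carry `carryover_frac` of
#' the highest (ULOQ) calibration standard's peak area.
#'
#' @param config An `sq_sim_config`.
#' @param dir Output directory (created).
#' @param preset `"small"` uses the synthetic panel from
#'   [simulate_panel()]; `"paper_scale"` uses the packaged 102-metabolite
#'   serum panel with reference medians as group truth.
#' @return A list with `flatfile`, `metadata` (paths), `panel`, `truth`
#'   (per (group, metabolite) true concentration) and `layout`.
#' @export
simulate_batch <- function(config, dir = tempfile("sqbatch"),
                           preset = c("small", "paper_scale")) {
  stopifnot(inherits(config, "sq_sim_config"))
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  if (preset == "paper_scale") {
    panel <- default_panel()
    pe_true <- config$extraction_efficiency * config$matrix_factor
    panel$entries$process_efficiency <- pe_true
    truth_panel <- tibble::tibble(
      hmdb_id = panel$entries$hmdb_id,
      molecular_weight = panel$entries$molecular_weight,
      rt_true = with_seed(config$seed + 1L,
                          round(runif(nrow(panel$entries), 1, 16), 3)),
      process_efficiency = pe_true)
    ref_med <- panel$references$median_umol_l[
      match(panel$entries$hmdb_id, panel$references$hmdb_id)]
  } else {
    panel <- simulate_panel(config)
    truth_panel <- attr(panel, "truth")
    ref_med <- NULL
  }
  n_met <- nrow(panel$entries)

  with_seed(config$seed + 3L, {
    groups <- paste0("G", seq_len(config$n_groups))
    truth <- if (!is.null(config$group_truth)) {
      stopifnot(identical(dim(config$group_truth),
                          c(n_met, as.integer(config$n_groups))))
      config$group_truth
    } else if (!is.null(ref_med)) {
      matrix(rep(ref_med, config$n_groups), ncol = config$n_groups)
    } else {
      matrix(exp(runif(n_met * config$n_groups, log(0.5), log(200))),
             ncol = config$n_groups)
    }
    qc_truth <- if (!is.null(ref_med)) ref_med else exp(rowMeans(log(truth)))

    sample_ids <- sprintf("SAMPLE-%03d", seq_len(config$n_samples))
    group_of <- setNames(rep(groups, length.out = config$n_samples), sample_ids)
    injection_order <- if (config$n_samples > 0) {
      double_randomize(sample_ids, group_of, seed = config$seed + 4L)$injection_order
    } else character(0)
    layout <- build_layout(injection_order, n_standards = config$n_levels)

    design <- make_serial_dilution(config$top_conc, config$n_levels,
                                   config$dilution_factor)
    slope <- runif(n_met, 0.5, 5)
    mw <- truth_panel$molecular_weight
    pe <- truth_panel$process_efficiency

    n_inj <- nrow(layout)
    # per (injection, metabolite) matrices
    area <- matrix(NA_real_, n_inj, n_met)
    ppb <- matrix(NA_real_, n_inj, n_met)
    rt <- matrix(rep(truth_panel$rt_true, each = n_inj), n_inj, n_met) *
      matrix(prop_noise(n_inj * n_met, config$rt_drift_cv), n_inj, n_met)
    std_conc <- rep(NA_real_, n_inj)

    for (i in seq_len(n_inj)) {
      role <- layout$role[i]
      if (role == "standard") {
        lev <- as.integer(sub("STD-0*", "", layout$sample_id[i]))
        conc <- design$nominal_conc[design$level == lev]
        std_conc[i] <- conc
        area[i, ] <- slope * conc * prop_noise(n_met, config$noise_cv)
        ppb[i, ] <- conc * prop_noise(n_met, config$noise_cv)
      } else if (role == "blank") {
        # residue from the highest (ULOQ) standard, the classic
        # ULOQ-then-blank carryover design
        uloq_i <- which(layout$role == "standard" &
                          layout$sample_id == sprintf("STD-%02d", config$n_levels))
        prev <- if (length(uloq_i) == 1 && uloq_i < i) area[uloq_i, ]
                else rep(0, n_met)
        area[i, ] <- config$carryover_frac * prev
        ppb[i, ] <- 0
      } else {
        true_umol <- if (role == "qc") {
          qc_truth
        } else {
          truth[, match(group_of[layout$sample_id[i]], groups)]
        }
        observed_umol <- true_umol * pe * prop_noise(n_met, config$noise_cv)
        ppb[i, ] <- observed_umol * mw
        area[i, ] <- slope * ppb[i, ]
      }
    }
    is_area <- matrix(10000 * prop_noise(n_inj * n_met, config$noise_cv / 2),
                      n_inj, n_met)

    type_str <- c(standard = "Standard", blank = "Blank", qc = "QC",
                  sample = "Analyte")[layout$role]
    fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 10,
                                                    format = "g"))
    blocks <- vapply(seq_len(n_met), function(m) {
      lines <- c(
        sprintf("Compound %d:  %s", m, panel$entries$name[m]),
        paste(c("#", "Name", "Sample Text", "Type", "Std. Conc", "RT",
                "Area", "IS Area", "Conc."), collapse = "\t"),
        sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                seq_len(n_inj),
                sprintf("file%04d", seq_len(n_inj)),
                layout$sample_id, type_str,
                fmt(std_conc), fmt(rt[, m]), fmt(area[, m]),
                fmt(is_area[, m]), fmt(ppb[, m])))
      paste(lines, collapse = "\n")
    }, character(1))
    flatfile <- file.path(dir, "batch_export.txt")
    writeLines(paste(blocks, collapse = "\n"), flatfile)

    meta <- tibble::tibble(
      sample_id = layout$sample_id,
      sample_type = layout$role,
      phenotype_group = ifelse(layout$role == "sample",
                               unname(group_of[layout$sample_id]), NA),
      matrix_type = ifelse(layout$role %in% c("sample", "qc"), "biofluid", NA),
      dilution_factor = ifelse(layout$role %in% c("sample", "qc"), 1, NA),
      tissue_weight_mg = NA_real_, cell_count = NA_real_,
      qc_lot = ifelse(layout$role == "qc", "LOT-1", NA),
      calibration_level = suppressWarnings(
        ifelse(layout$role == "standard",
               as.integer(sub("STD-0*", "", layout$sample_id)),
               NA_integer_)))
    meta <- meta[!duplicated(meta$sample_id), ]
    metadata_path <- file.path(dir, "batch_metadata.csv")
    readr::write_csv(meta, metadata_path)

    truth_tbl <- tidyr::expand_grid(hmdb_id = panel$entries$hmdb_id,
                                    group = groups) |>
      dplyr::mutate(true_umol_l = as.vector(t(truth)))

    list(flatfile = flatfile, metadata = metadata_path, panel = panel,
         truth = truth_tbl, qc_truth = tibble::tibble(
           hmdb_id = panel$entries$hmdb_id, true_umol_l = qc_truth),
         layout = layout,
         calibration_truth = tibble::tibble(
           hmdb_id = panel$entries$hmdb_id, slope = slope))
  })
}

#' Simulate a lot-structured QC concentration history
#'
#' Log-normal QC concentrations with lot-level random shifts:
#' `log conc = log(median) + b_lot + e`, `b_lot ~ N(0, lot_sd_log^2)`,
#' `e ~ N(0, qc_noise_sd_log^2)`. The default design mirrors a long-term QC
#' database: 6 lots x 90 replicates spread over batches (~540 records).
#'
#' @param config An `sq_sim_config`.
#' @param n_batches Number of batches (default 54).
#' @param n_lots Number of QC lots (default 6).
#' @param reps_per_batch QC replicates per batch (default 10).
#' @param true_median True median concentration(s), umol/L; recycled over
#'   metabolites (default 100).
#' @param seed_offset Added to `config$seed` for independent histories.
#' @return A list: `history` (tibble `qc_lot`, `batch_id`, `run_date`,
#'   `hmdb_id`, `conc_umol_l`) and `truth` (medians, lot effects).
#' @export
simulate_qc_history <- function(config, n_batches = 54, n_lots = 6,
                                reps_per_batch = 10, true_median = 100,
                                seed_offset = 0L) {
  stopifnot(inherits(config, "sq_sim_config"), n_lots >= 1, n_batches >= 1)
  with_seed(config$seed + 5L + as.integer(seed_offset), {
    n_met <- config$n_metabolites
    med <- rep_len(true_median, n_met)
    ids <- sprintf("SYN%06d", seq_len(n_met))
    lot_of_batch <- sort(rep_len(seq_len(n_lots), n_batches))
    b <- matrix(rnorm(n_met * n_lots, 0, config$lot_sd_log), n_met, n_lots)
    rows <- purrr::map_dfr(seq_len(n_batches), function(k) {
      lot <- lot_of_batch[k]
      tidyr::expand_grid(hmdb_id = ids, rep = seq_len(reps_per_batch)) |>
        dplyr::mutate(
          qc_lot = sprintf("LOT-%d", lot),
          batch_id = sprintf("BATCH-%03d", k),
          run_date = as.Date("2020-01-01") + (k - 1) * 7,
          conc_umol_l = med[match(.data$hmdb_id, ids)] *
            exp(b[cbind(match(.data$hmdb_id, ids), lot)]) *
            exp(rnorm(dplyr::n(), 0, config$qc_noise_sd_log)))
    })
    list(history = dplyr::select(rows, "qc_lot", "batch_id", "run_date",
                                 "hmdb_id", "conc_umol_l"),
         truth = list(median = setNames(med, ids),
                      lot_sd_log = config$lot_sd_log,
                      noise_sd_log = config$qc_noise_sd_log,
                      lot_effects = b))
  })
}
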
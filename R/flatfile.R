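#' Parse a flat-text quantification export into a tidy batch
#'
#' Vendor quantification software exports one text block per metabolite: a
#' `Compound N: <name>` banner, a tab-separated header
#' (`#`, `Name`, `Sample Text`, `Type`, `Std. Conc`, `RT`, `Area`, `IS Area`,
#' `Conc.`) and one line per injection. `parse_flatfile()` reads every block,
#' checks that all blocks list the same injections in the same order, and
#' returns a long tidy table of per-injection, per-metabolite measurements.
#'
#' Vendor blanks and the literal `N/F` (not found) both become `NA`. Compound
#' names absent from the panel are kept and reported as a warning, with a
#' synthetic `UNKNOWN:<name>` id, never dropped.
#'
#' @param path Path to the flat-text export (UTF-8, tab-separated).
#' @param panel Optional `sq_panel`; used to map compound names to HMDB ids
#'   and to order output columns.
#' @param metadata Optional batch metadata tibble (see
#'   [read_batch_metadata()]); every non-standard, non-blank sample id must
#'   appear in it.
#' @return An `sq_batch`: list with `batch_id`, `records` (long tibble with
#'   `injection_index`, `file_name`, `sample_id`, `sample_type`,
#'   `calibration_level`, `hmdb_id`, `compound`, `std_conc`, `rt`,
#'   `peak_area`, `is_area`, `conc_ppb`) and `metadata`.
#' @examples
#' cfg <- sim_config(seed = 1, n_metabolites = 3, n_samples = 4)
#' files <- simulate_batch(cfg, dir = tempfile())
#' batch <- parse_flatfile(files$flatfile, panel = files$panel,
#'                         metadata = read_batch_metadata(files$metadata))
#' assemble_matrix(batch, "conc_ppb")
#' @export
parse_flatfile <- function(path, panel = NULL, metadata = NULL) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  starts <- grep("^Compound\\s+\\d+:", lines)
  if (length(starts) == 0)
    stop_structural("no 'Compound N:' blocks found; not a recognized flat-file export")
  ends <- c(starts[-1] - 1L, length(lines))

  expected_header <- c("#", "Name", "Sample Text", "Type", "Std. Conc",
                       "RT", "Area", "IS Area", "Conc.")
  parse_num <- function(s, lineno) {
    s <- trimws(s)
    out <- rep(NA_real_, length(s))
    known_missing <- s == "" | s == "N/F"
    val <- suppressWarnings(as.numeric(s[!known_missing]))
    if (anyNA(val)) {
      bad <- which(!known_missing)[which(is.na(val))[1]]
      stop_structural(sprintf("unparseable numeric field '%s' at line %d",
                              s[bad], lineno[bad]))
    }
    out[!known_missing] <- val
    out
  }

  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    banner <- lines[starts[b]]
    compound <- trimws(sub("^Compound\\s+\\d+:\\s*", "", banner))
    hdr_i <- starts[b] + 1L
    if (hdr_i > ends[b] ||
        !identical(strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]], expected_header))
      stop_structural(sprintf("block '%s': missing or malformed header at line %d",
                              compound, hdr_i))
    body_i <- seq(hdr_i + 1L, ends[b])
    body_i <- body_i[body_i <= length(lines) & nzchar(trimws(lines[body_i]))]
    # sentinel keeps trailing empty fields from being dropped by strsplit
    fields <- lapply(strsplit(paste0(lines[body_i], "\t\x03"), "\t",
                              fixed = TRUE), function(f) f[-length(f)])
    nf <- lengths(fields)
    if (any(nf != 9L))
      stop_structural(sprintf("block '%s': expected 9 tab-separated fields at line %d, found %d",
                              compound, body_i[which(nf != 9L)[1]], nf[nf != 9L][1]))
    m <- do.call(rbind, fields)
    blocks[[b]] <- tibble::tibble(
      compound = compound,
      injection_index = as.integer(m[, 1]),
      file_name = m[, 2],
      sample_id = m[, 3],
      type_raw = m[, 4],
      std_conc = parse_num(m[, 5], body_i),
      rt = parse_num(m[, 6], body_i),
      peak_area = parse_num(m[, 7], body_i),
      is_area = parse_num(m[, 8], body_i),
      conc_ppb = parse_num(m[, 9], body_i))
  }

  # reconcile: every block must list the same injections in the same order
  key <- function(df) paste(df$injection_index, df$sample_id, df$type_raw, sep = "\r")
  ref_key <- key(blocks[[1]])
  for (b in seq_along(blocks)[-1]) {
    if (!identical(key(blocks[[b]]), ref_key))
      stop_structural(sprintf(
        "inconsistent injection list: block '%s' diverges from block '%s'",
        blocks[[b]]$compound[1], blocks[[1]]$compound[1]))
  }

  records <- dplyr::bind_rows(blocks)
  type_map <- c(Standard = "standard", QC = "qc", Blank = "blank",
                Analyte = "sample", Sample = "sample")
  unknown_type <- setdiff(unique(records$type_raw), names(type_map))
  if (length(unknown_type) > 0)
    stop_structural(paste0("unknown sample Type value(s): ",
                           paste(unknown_type, collapse = ", ")))
  records$sample_type <- unname(type_map[records$type_raw])
  records$calibration_level <- ifelse(
    records$sample_type == "standard",
    suppressWarnings(as.integer(sub("^STD-0*", "", records$sample_id))),
    NA_integer_)

  if (!is.null(panel)) {
    idx <- match(records$compound, panel$entries$name)
    records$hmdb_id <- panel$entries$hmdb_id[idx]
    unmatched <- unique(records$compound[is.na(idx)])
    if (length(unmatched) > 0) {
      warn(paste0("compound(s) not in panel, kept with UNKNOWN ids: ",
                  paste(unmatched, collapse = ", ")))
      records$hmdb_id[is.na(idx)] <- paste0("UNKNOWN:", records$compound[is.na(idx)])
    }
  } else {
    records$hmdb_id <- paste0("UNKNOWN:", records$compound)
  }

  records <- dplyr::select(records, "injection_index", "file_name", "sample_id",
                           "sample_type", "calibration_level", "hmdb_id",
                           "compound", "std_conc", "rt", "peak_area",
                           "is_area", "conc_ppb")

  if (!is.null(metadata)) {
    need <- unique(records$sample_id[records$sample_type %in% c("sample", "qc")])
    missing_meta <- setdiff(need, metadata$sample_id)
    if (length(missing_meta) > 0)
      stop_validation(paste0("sample id(s) without batch metadata: ",
                             paste(missing_meta, collapse = ", ")))
  }

  structure(list(batch_id = tools::file_path_sans_ext(basename(path)),
                 records = records,
                 panel = panel,
                 metadata = metadata),
            class = "sq_batch")
}

#' Read a batch metadata CSV
#'
#' Schema: `sample_id, sample_type, phenotype_group, matrix_type,
#' dilution_factor, tissue_weight_mg, cell_count, qc_lot, calibration_level`.
#' `matrix_type` is one of `biofluid`, `tissue`, `cells`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_batch_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", sample_type = "c", phenotype_group = "c",
                    matrix_type = "c", dilution_factor = "d",
                    tissue_weight_mg = "d", cell_count = "d", qc_lot = "c",
                    calibration_level = "i"))
}

#' Pivot a parsed batch into a sample-by-metabolite matrix
#'
#' Rows are injections in acquisition order; QC, blank and standard rows stay
#' separable from experimental samples through the `sample_type` column.
#' Missing measurements stay `NA` — never zero-filled. Metabolite column
#' order follows the panel when one was supplied, making the result
#' independent of block order in the source file.
#'
#' @param batch An `sq_batch` from [parse_flatfile()].
#' @param value Which measurement to spread: `"conc_ppb"`, `"peak_area"` or
#'   `"rt"`.
#' @return A tibble with `injection_index`, `sample_id`, `sample_type` and
#'   one column per metabolite (named by HMDB id).
#' @export
assemble_matrix <- function(batch, value = c("conc_ppb", "peak_area", "rt")) {
  stopifnot(inherits(batch, "sq_batch"))
  value <- match.arg(value)
  wide <- batch$records |>
    dplyr::select("injection_index", "sample_id", "sample_type",
                  "hmdb_id", value = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "hmdb_id", values_from = "value") |>
    dplyr::arrange(.data$injection_index)
  if (!is.null(batch$panel)) {
    ordered_ids <- intersect(batch$panel$entries$hmdb_id, names(wide))
    extra <- setdiff(names(wide),
                     c("injection_index", "sample_id", "sample_type", ordered_ids))
    wide <- dplyr::select(wide, "injection_index", "sample_id", "sample_type",
                          dplyr::all_of(c(ordered_ids, extra)))
  }
  wide
}

#' Write a processed-results workbook (one CSV per sheet)
#'
#' Emits a directory of diff-able CSV sheets: `concentrations` (experimental
#' samples rearranged by phenotypic group, acquisition order preserved in a
#' column), `qc_summary` (per-metabolite QC mean / %CV) and `flags` (same
#' shape as `concentrations`; outlier cells carry the distinct marks
#' `outlier_1sd` and `outlier_2sd`, mirroring a two-color spreadsheet
#' highlight, alongside `below_lloq` / `above_uloq`).
#'
#' @param results An `sq_quant` table from [quantify_batch()] (optionally
#'   after [group_stats()]).
#' @param path Output directory (created; an `.xlsx`-style extension is
#'   stripped).
#' @return The directory path, invisibly.
#' @export
write_workbook <- function(results, path) {
  stopifnot(inherits(results, "sq_quant") || is.data.frame(results))
  if (nrow(results) == 0) stop_validation("empty results table")
  dir_path <- sub("\\.(xlsx|xls)$", "", path)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) stop_validation(paste0("cannot create ", dir_path))

  exp <- dplyr::filter(results, .data$sample_type == "sample")
  conc <- exp |>
    dplyr::select("sample_id", "phenotype_group", "injection_index",
                  "hmdb_id", "value") |>
    tidyr::pivot_wider(names_from = "hmdb_id", values_from = "value") |>
    dplyr::arrange(.data$phenotype_group, .data$sample_id)
  readr::write_csv(conc, file.path(dir_path, "concentrations.csv"))

  qc <- dplyr::filter(results, .data$sample_type == "qc")
  qc_summary <- if (nrow(qc) > 0) {
    qc |>
      dplyr::group_by(.data$hmdb_id) |>
      dplyr::summarise(n = sum(!is.na(.data$value)),
                       mean_conc = mean(.data$value, na.rm = TRUE),
                       cv_pct = cv_pct(.data$value), .groups = "drop")
  } else {
    tibble::tibble(hmdb_id = character(), n = integer(),
                   mean_conc = double(), cv_pct = double())
  }
  readr::write_csv(qc_summary, file.path(dir_path, "qc_summary.csv"))

  flag_str <- function(df) {
    has <- function(col) if (col %in% names(df)) df[[col]] %in% TRUE else rep(FALSE, nrow(df))
    marks <- cbind(
      ifelse(has("below_lloq"), "below_lloq", NA),
      ifelse(has("above_uloq"), "above_uloq", NA),
      ifelse(has("outlier_2sd"), "outlier_2sd",
             ifelse(has("outlier_1sd"), "outlier_1sd", NA)),
      ifelse(is.na(df$value), "missing", NA))
    apply(marks, 1, function(r) paste(r[!is.na(r)], collapse = ";"))
  }
  flags <- exp |>
    dplyr::mutate(flag = flag_str(exp)) |>
    dplyr::select("sample_id", "phenotype_group", "injection_index",
                  "hmdb_id", "flag") |>
    tidyr::pivot_wider(names_from = "hmdb_id", values_from = "flag") |>
    dplyr::arrange(.data$phenotype_group, .data$sample_id)
  readr::write_csv(flags, file.path(dir_path, "flags.csv"))
  invisible(dir_path)
}

#' Read one sheet back from a CSV workbook directory
#'
#' @param path Workbook directory written by [write_workbook()].
#' @param sheet Sheet name: `"concentrations"`, `"qc_summary"` or `"flags"`.
#' @return A tibble.
#' @export
read_workbook_sheet <- function(path, sheet = c("concentrations", "qc_summary", "flags")) {
  sheet <- match.arg(sheet)
  readr::read_csv(file.path(path, paste0(sheet, ".csv")), show_col_types = FALSE)
}

#' @export
print.sq_batch <- function(x, ...) {
  cat(sprintf("<sq_batch> '%s': %d injections x %d metabolites\n", x$batch_id,
              dplyr::n_distinct(x$records$injection_index),
              dplyr::n_distinct(x$records$hmdb_id)))
  print(dplyr::count(x$records[!duplicated(x$records$injection_index), ],
                     .data$sample_type))
  invisible(x)
}
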
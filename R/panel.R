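#' Metabolite panels and the packaged serum reference database
#'
#' A *panel* defines the metabolites a targeted LC-MS/MS assay measures:
#' identity (name, HMDB accession), chemical class, average molecular weight
#' (g/mol, used to convert ppb to micromolar), the class-representative
#' labeled internal standard assigned to each metabolite, a process-efficiency
#' factor (combined extraction-recovery x matrix-effect attenuation; final
#' concentrations are divided by it) and a default dilution factor.
#'
#' The packaged default panel covers 102 polar metabolites from 24 chemical
#' classes and carries a healthy-adult serum reference database: for each
#' metabolite the population median concentration (umol/L) with a 95%
#' credibility interval, estimated from long-term pooled-serum QC histories
#' under a lot-corrected hierarchical log-normal model.
#'
#' @param path Path to a delimited panel file. The delimiter is autodetected
#'   from the extension (`.csv` comma, `.tsv`/`.txt` tab). Required columns:
#'   `name, hmdb_id, class, molecular_weight, internal_standard,
#'   process_efficiency, default_dilution`.
#' @param reference_path Optional path to a reference-database CSV with
#'   columns `hmdb_id, median_umol_l, ci_lower, ci_upper`.
#' @return `load_panel()` and `default_panel()` return an `sq_panel`: a list
#'   with tibbles `entries` and `references` plus the character vector
#'   `internal_standards`.
#' @examples
#' p <- default_panel()
#' nrow(p$entries)                       # 102
#' dplyr::n_distinct(p$entries$class)    # 24
#' lookup_reference(p, "HMDB0000161")    # alanine median + 95% CrI
#' @name panel
NULL

panel_columns <- c("name", "hmdb_id", "class", "molecular_weight",
                   "internal_standard", "process_efficiency", "default_dilution")

new_panel <- function(entries, references = NULL) {
  entries <- tibble::as_tibble(entries)
  if (is.null(references)) {
    references <- tibble::tibble(hmdb_id = character(), median_umol_l = double(),
                                 ci_lower = double(), ci_upper = double())
  }
  references <- tibble::as_tibble(references)
  validate_panel(entries, references)
  structure(
    list(entries = entries,
         references = references,
         internal_standards = sort(unique(entries$internal_standard[
           !is.na(entries$internal_standard) & entries$internal_standard != ""]))),
    class = "sq_panel")
}

validate_panel <- function(entries, references) {
  missing_cols <- setdiff(panel_columns, names(entries))
  if (length(missing_cols) > 0)
    stop_validation(paste0("panel file is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  dup <- entries$hmdb_id[duplicated(entries$hmdb_id)]
  if (length(dup) > 0)
    stop_validation(paste0("duplicate hmdb_id in panel: ",
                           paste(unique(dup), collapse = ", ")))
  bad_mw <- which(!is.finite(entries$molecular_weight) | entries$molecular_weight <= 0)
  if (length(bad_mw) > 0)
    stop_validation(paste0("non-positive molecular_weight in panel row(s) ",
                           paste(bad_mw, collapse = ", "), " (",
                           paste(entries$name[bad_mw], collapse = ", "), ")"))
  bad_pe <- which(!is.finite(entries$process_efficiency) | entries$process_efficiency <= 0)
  if (length(bad_pe) > 0)
    stop_validation(paste0("non-positive process_efficiency in panel row(s) ",
                           paste(bad_pe, collapse = ", ")))
  bad_dil <- which(!is.finite(entries$default_dilution) | entries$default_dilution < 1)
  if (length(bad_dil) > 0)
    stop_validation(paste0("default_dilution < 1 in panel row(s) ",
                           paste(bad_dil, collapse = ", ")))
  if (nrow(references) > 0) {
    orphan <- setdiff(references$hmdb_id, entries$hmdb_id)
    if (length(orphan) > 0)
      stop_validation(paste0("reference entries without a panel entry: ",
                             paste(orphan, collapse = ", ")))
    bad <- with(references, !(ci_lower <= median_umol_l & median_umol_l <= ci_upper) |
                  ci_lower <= 0)
    if (any(bad))
      stop_validation(paste0("reference rows violate ci_lower <= median <= ci_upper ",
                             "(all positive): ",
                             paste(references$hmdb_id[bad], collapse = ", ")))
  }
  invisible(TRUE)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) readr::read_tsv(path, show_col_types = FALSE)
  else readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname panel
#' @export
load_panel <- function(path, reference_path = NULL) {
  entries <- read_delim_auto(path)
  references <- if (!is.null(reference_path)) read_delim_auto(reference_path)
  new_panel(entries, references)
}

#' @rdname panel
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "serum_panel.csv", package = "semiquantr",
                         mustWork = TRUE),
             system.file("extdata", "serum_reference.csv", package = "semiquantr",
                         mustWork = TRUE))
}

#' Write a panel (and its reference database) back to delimited text
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f), ...)` round-trips
#' losslessly for any valid panel.
#'
#' @param panel An `sq_panel`.
#' @param path Output path for the entries table (`.csv` or `.tsv`).
#' @param reference_path Optional output path for the reference database CSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, reference_path = NULL) {
  stopifnot(inherits(panel, "sq_panel"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) readr::write_tsv(panel$entries, path)
  else readr::write_csv(panel$entries, path)
  if (!is.null(reference_path)) readr::write_csv(panel$references, reference_path)
  invisible(path)
}

#' @rdname panel
#' @param panel An `sq_panel`.
#' @param hmdb_id HMDB accession to look up.
#' @return `lookup_reference()` returns a one-row tibble with `hmdb_id`,
#'   `name`, `median_umol_l`, `ci_lower`, `ci_upper`.
#' @export
lookup_reference <- function(panel, hmdb_id) {
  stopifnot(inherits(panel, "sq_panel"))
  hit <- panel$references[panel$references$hmdb_id == hmdb_id, , drop = FALSE]
  if (nrow(hit) == 0)
    abort(paste0("no reference entry for ", hmdb_id),
          class = "semiquantr_not_found_error")
  dplyr::left_join(hit, dplyr::select(panel$entries, "hmdb_id", "name"),
                   by = "hmdb_id") |>
    dplyr::select("hmdb_id", "name", "median_umol_l", "ci_lower", "ci_upper")
}

#' @export
print.sq_panel <- function(x, ...) {
  cat(sprintf("<sq_panel> %d metabolites, %d classes, %d internal standards, %d reference entries\n",
              nrow(x$entries), dplyr::n_distinct(x$entries$class),
              length(x$internal_standards), nrow(x$references)))
  print(x$entries, n = 5)
  invisible(x)
}
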
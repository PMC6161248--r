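# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_panel_tbl <- function(n = 2) {
  tibble::tibble(
    name = sprintf("Toy%02d", seq_len(n)),
    hmdb_id = sprintf("TOY%06d", seq_len(n)),
    class = rep(c("Class X", "Class Y"), length.out = n),
    molecular_weight = seq(100, by = 50, length.out = n),
    internal_standard = "IS-T",
    process_efficiency = 1,
    default_dilution = 1)
}

toy_panel <- function(n = 2) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(toy_panel_tbl(n), path)
  load_panel(path)
}

# Write a flat-file export from a list of per-compound data frames with
# columns sample_id, type, std_conc, rt, area, is_area, conc. All compounds
# must list the same injections (unless deliberately broken for a test).
write_toy_flatfile <- function(blocks, path = tempfile(fileext = ".txt")) {
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  txt <- unlist(lapply(seq_along(blocks), function(i) {
    d <- blocks[[i]]
    c(sprintf("Compound %d:  %s", i, names(blocks)[i]),
      paste(c("#", "Name", "Sample Text", "Type", "Std. Conc", "RT",
              "Area", "IS Area", "Conc."), collapse = "\t"),
      sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
              seq_len(nrow(d)), sprintf("file%03d", seq_len(nrow(d))),
              d$sample_id, d$type, fmt(d$std_conc), fmt(d$rt),
              fmt(d$area), fmt(d$is_area), fmt(d$conc)))
  }))
  writeLines(txt, path)
  path
}

toy_block <- function(conc = c(10, 20, 30)) {
  tibble::tibble(sample_id = sprintf("SAMPLE-%03d", seq_along(conc)),
                 type = "Analyte", std_conc = NA, rt = 5.0,
                 area = conc * 100, is_area = 10000, conc = conc)
}

toy_metadata <- function(sample_ids, group = "G1", matrix_type = "biofluid",
                         dilution = 1) {
  tibble::tibble(sample_id = sample_ids, sample_type = "sample",
                 phenotype_group = group, matrix_type = matrix_type,
                 dilution_factor = dilution, tissue_weight_mg = NA_real_,
                 cell_count = NA_real_, qc_lot = NA_character_,
                 calibration_level = NA_integer_)
}

# Independent weighted-least-squares oracle: explicit normal equations on a
# centered/scaled basis (for numerical conditioning), mapped back to the raw
# polynomial coefficients in closed form. No lm().
oracle_fit <- function(series, model, transform, weighting) {
  x <- series$nominal_conc
  y <- series$response
  if (transform == "loglog") {
    x <- log(x); y <- log(y); weighting <- "none"
  }
  w <- if (weighting == "inv_x") 1 / series$nominal_conc else rep(1, length(x))
  mx <- mean(x); sx <- sd(x)
  z <- (x - mx) / sx
  Z <- if (model == "linear") cbind(1, z) else cbind(1, z, z^2)
  WZ <- Z * w
  g <- solve(t(Z) %*% WZ, t(WZ) %*% y)   # normal equations in the z basis
  beta <- if (model == "linear") {
    c(g[1] - g[2] * mx / sx, g[2] / sx)
  } else {
    c(g[1] - g[2] * mx / sx + g[3] * mx^2 / sx^2,
      g[2] / sx - 2 * g[3] * mx / sx^2,
      g[3] / sx^2)
  }
  yhat <- as.vector(Z %*% g)
  wm <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - wm)^2)
  list(coefficients = beta, r_squared = r2)
}

random_series <- function(seed, n_levels = 8, curved = FALSE) {
  set.seed(seed)
  d <- make_serial_dilution(runif(1, 100, 2000), n_levels, runif(1, 1.5, 3))
  slope <- runif(1, 0.5, 5)
  quad <- if (curved) runif(1, 1e-4, 1e-3) else 0
  tibble::tibble(nominal_conc = d$nominal_conc,
                 response = (slope * d$nominal_conc + quad * d$nominal_conc^2) *
                   (1 + rnorm(n_levels, 0, 0.05)))
}
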
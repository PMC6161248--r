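#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibration curve fit
#'
#' @param x An `sq_curvefit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (`term`, `estimate`).
#'   `glance()`: one row with `r.squared`, `lloq`, `uloq`, `model`,
#'   `transform`, `weighting`, `n_levels`, `rejected`.
#' @method tidy sq_curvefit
#' @export
tidy.sq_curvefit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.sq_curvefit
#' @method glance sq_curvefit
#' @export
glance.sq_curvefit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, lloq = x$lloq, uloq = x$uloq,
                 model = x$model, transform = x$transform,
                 weighting = x$weighting, n_levels = nrow(x$series),
                 rejected = x$rejected)
}

#' Tidy a reference-median fit
#'
#' @param x An `sq_reffit`.
#' @param ... Unused.
#' @return `tidy()`: the per-metabolite estimate tibble (posterior median,
#'   95% CrI, variance components). `glance()`: one row with the sampler
#'   settings and metabolite count.
#' @method tidy sq_reffit
#' @export
tidy.sq_reffit <- function(x, ...) x$estimates

#' @rdname tidy.sq_reffit
#' @method glance sq_reffit
#' @export
glance.sq_reffit <- function(x, ...) {
  tibble::tibble(n_metabolites = nrow(x$estimates),
                 n_draws = x$n_draws, burn_in = x$burn_in,
                 seed = as.integer(x$seed))
}
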
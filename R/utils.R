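#' @importFrom rlang abort warn .data
#' @importFrom stats sd median quantile rnorm runif lm coef predict fitted setNames complete.cases
#' @importFrom utils head tail
NULL

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample coefficient of variation, in percent; NA when undefined
cv_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

stop_domain <- function(msg) abort(msg, class = "semiquantr_domain_error")
stop_validation <- function(msg) abort(msg, class = "semiquantr_validation_error")
stop_structural <- function(msg) abort(msg, class = "semiquantr_structural_error")
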
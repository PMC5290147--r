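#' @keywords internal
"_PACKAGE"

# Boltzmann constant, J/K (2019 SI exact value)
.kB <- 1.380649e-23

#' Derive a reproducible substream seed from a master seed and labels
#'
#' Independent pseudo-random substreams for each (condition, cell, purpose)
#' are derived from one master seed by hashing a label string, so that adding
#' a condition to a configuration never perturbs the draws of the others.
#' The hash is a plain polynomial rolling hash over the UTF-8 bytes of the
#' label, combined with the master seed modulo 2^31 - 1 (all arithmetic stays
#' below 2^53, so it is exact in double precision on every platform).
#'
#' @param master integer master seed.
#' @param ... label components; concatenated with "/".
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "pKO-b1", 3, "forces")
substream_seed <- function(master, ...) {
  label <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 1000000007
  as.integer((abs(as.numeric(master)) %% 2147483647 * 7919 + h) %% 2147483647)
}

# run expr with a local RNG state seeded by `seed`; if seed is NULL the
# global stream is used (and advanced) as usual
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ordinary least squares y ~ x without lm() overhead
simple_lm <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx * dx)
  slope <- if (sxx == 0) 0 else sum(dx * (y - my)) / sxx
  c(intercept = my - slope * mx, slope = slope)
}

#' Significance stars for p-values
#'
#' Standard convention: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, otherwise `NS`.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  cut(p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "NS"), right = FALSE) |>
    as.character()
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
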
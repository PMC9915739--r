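#' @keywords internal
"_PACKAGE"

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a global seed and a stage label,
# so pipeline stages can be rerun in isolation. Kept below 2^31.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Score-based interval used for all per-bin neuron proportions. Unlike the
#' Wald interval it behaves sensibly at proportions near 0 or 1, which is the
#' regime most position bins are in.
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials.
#' @param conf.level Confidence level; default 0.95.
#' @return A data.frame with columns `estimate`, `lower`, `upper`.
#' @examples
#' wilson_ci(5, 100)
#' @export
wilson_ci <- function(x, n, conf.level = 0.95) {
  stopifnot(all(x >= 0), all(n > 0), all(x <= n), conf.level > 0, conf.level < 1)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(estimate = p, lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Standard error of the mean
#' @param x Numeric vector; NAs removed.
#' @return SD/sqrt(n).
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  stats::sd(x) / sqrt(length(x))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
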
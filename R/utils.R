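# Shared numerical helpers.

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Empirical percentile by order statistic without interpolation:
# rank ceiling(q * (n + 1)), clamped to [1, n].  With 100 replicates this
# gives exact attained levels for the randomization tests.
percentileBound <- function(x, q) {
  n <- length(x)
  r <- min(max(ceiling(q * (n + 1)), 1L), n)
  sort(x)[r]
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Derive a stage-specific random seed
#'
#' One global seed drives the whole pipeline; each stochastic stage uses a
#' substream derived by hashing the stage name into the seed, so stages can
#' be re-run independently yet reproducibly.  The result is always a
#' positive integer below 2^31 - 1.
#'
#' @param seed integer master seed
#' @param stage character stage label
#' @return integer seed
#' @export
deriveSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 + h) %% 2147483629 + 1)
}

# Average squared pairwise distance between a set of values; 0 for a
# singleton.  Identity: mean over pairs of (x_i - x_j)^2 = 2 * var(x).
#' Disparity of a set of trait values
#'
#' Disparity is the mean squared pairwise distance between values, the
#' statistic accumulated by the disparity-through-time curve.
#'
#' @param values numeric vector (at least one value)
#' @return non-negative scalar
#' @examples
#' disparityOf(c(0, 2))     # 4
#' disparityOf(c(0, 1, 2))  # 2
#' @export
disparityOf <- function(values) {
  if (length(values) == 0L) stop("disparity of an empty set is undefined")
  if (length(values) == 1L) return(0)
  2 * stats::var(values)
}
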
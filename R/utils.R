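#' Two-sided t-based confidence interval from summary statistics
#'
#' The interval \code{mean +/- t_{1-(1-level)/2, n-1} * sd / sqrt(n)} used for
#' all descriptive group and cluster summaries in the pipeline.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (n-1 denominator).
#' @param n sample size (>= 2).
#' @param level confidence level, default 0.95.
#' @return named numeric vector \code{c(lower, upper)}.
#' @examples
#' t_ci(0.962, 0.129, 9) # c(0.863, 1.061) to three decimals
#' @export
t_ci <- function(mean, sd, n, level = 0.95) {
  if (any(n < 2)) stop("t_ci() requires n >= 2", call. = FALSE)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Format p values for reporting
#'
#' Three decimals, values below 0.001 rendered as \code{"<0.001"}.
#'
#' @param p numeric vector of p values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

# Deterministic child seeds for named stage streams, derived from one master
# seed so stages can be rerun independently yet reproducibly.
child_seeds <- function(master_seed, streams) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}

# run `expr` under a temporary seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

stop_field <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}
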
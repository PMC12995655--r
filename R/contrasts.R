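delta_column <- function(endpoint) {
  ok <- c("delta_upper", "delta_lower")
  if (!endpoint %in% ok)
    stop_field("unknown endpoint '%s' (use %s)", endpoint,
               paste(ok, collapse = " or "))
  endpoint
}

#' Descriptive group summaries for a change endpoint
#'
#' Per group: n, mean, sample SD (n-1 denominator), and the t-based 95%
#' confidence interval \code{mean +/- t_{0.975, n-1} sd / sqrt(n)}.
#'
#' @param delta a \code{delta_table}.
#' @param endpoint \code{"delta_upper"} or \code{"delta_lower"}.
#' @param level confidence level, default 0.95.
#' @return data frame with columns \code{endpoint, group, n, mean, sd,
#'   ci_lower, ci_upper}, one row per group in order of first appearance.
#' @export
describe_deltas <- function(delta, endpoint = "delta_upper", level = 0.95) {
  col <- delta_column(endpoint)
  groups <- unique(delta$group)
  rows <- lapply(groups, function(g) {
    x <- delta[[col]][delta$group == g]
    if (length(x) < 2)
      stop_field("insufficient data: group '%s' has n = %d (< 2)", g, length(x))
    ci <- t_ci(mean(x), sd(x), length(x), level)
    data.frame(endpoint = endpoint, group = g, n = length(x),
               mean = mean(x), sd = sd(x),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Difference in sample means
#' @param a,b numeric samples.
#' @return \code{mean(a) - mean(b)}.
#' @export
mean_diff <- function(a, b) {
  if (!length(a) || !length(b)) stop_field("mean_diff() needs nonempty samples")
  mean(a) - mean(b)
}

#' Hedges g standardized mean difference with small-sample correction
#'
#' \code{g = J * (mean(a) - mean(b)) / s_pooled} with
#' \code{s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))} and
#' \code{J = 1 - 3 / (4 (n_a+n_b-2) - 1)}.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return unitless effect size.
#' @export
hedges_g <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_field("hedges_g() needs n >= 2 per sample")
  hedges_g_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' @rdname hedges_g
#' @param m1,s1,n1,m2,s2,n2 summary statistics of the two samples.
#' @examples
#' hedges_g_summary(0.962, 0.129, 9, 0.762, 0.218, 9) # ~ 1.06
#' @export
hedges_g_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) stop_field("degenerate input: zero pooled variance")
  (1 - 3 / (4 * df - 1)) * (m1 - m2) / sqrt(sp2)
}

#' Two-sided permutation test for a difference in means
#'
#' The test statistic is the mean difference. For small pooled samples
#' (total n <= \code{exact_threshold}) all \code{choose(n, n_a)} relabelings
#' are enumerated and \code{p = #\{|T*| >= |T|\} / #splits}. Otherwise
#' \code{n_perm} random relabelings preserving group sizes are drawn and
#' \code{p = (1 + #\{|T*| >= |T|\}) / (n_perm + 1)} (the add-one estimator,
#' which keeps Monte-Carlo p strictly positive); set \code{plus_one = FALSE}
#' for the uncorrected \code{#/n_perm} estimator.
#'
#' @param a,b numeric samples.
#' @param n_perm number of random permutations (Monte-Carlo path).
#' @param seed optional integer seed for the Monte-Carlo path.
#' @param exact_threshold largest pooled size for exhaustive enumeration
#'   (default 12).
#' @param plus_one use the add-one Monte-Carlo estimator (default TRUE).
#' @return p value in (0, 1], with attributes \code{method}
#'   (\code{"exact"}/\code{"monte-carlo"}) and \code{n_used}.
#' @export
permutation_test <- function(a, b, n_perm = 1e5, seed = NULL,
                             exact_threshold = 12, plus_one = TRUE) {
  if (!is_count(n_perm)) stop_field("'n_perm' must be a positive integer")
  pool <- c(a, b)
  na <- length(a); nb <- length(b); n <- na + nb
  if (!na || !nb) stop_field("permutation_test() needs nonempty samples")
  obs <- mean(a) - mean(b)
  tot <- sum(pool)
  # |T*| >= |T| with a tolerance so the observed split always counts
  thr <- abs(obs) - 1e-12 * max(1, abs(obs))
  stat <- function(sa) sa / na - (tot - sa) / nb
  if (n <= exact_threshold) {
    splits <- combn(n, na)
    sums <- colSums(matrix(pool[splits], nrow = na))
    p <- mean(abs(stat(sums)) >= thr)
    return(structure(p, method = "exact", n_used = ncol(splits)))
  }
  with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      sa <- sum(pool[sample.int(n, na)])
      if (abs(stat(sa)) >= thr) cnt <- cnt + 1L
    }
    p <- if (plus_one) (1 + cnt) / (n_perm + 1) else cnt / n_perm
    structure(p, method = "monte-carlo", n_used = n_perm)
  })
}

#' Bootstrap percentile confidence interval for a mean difference
#'
#' Resamples within each group independently with replacement (stratified,
#' preserving the two-sample design), recomputes the mean difference, and
#' returns the 2.5th and 97.5th percentiles.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param n_boot number of bootstrap resamples (default 20000).
#' @param seed optional integer seed.
#' @param level confidence level, default 0.95.
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
bootstrap_ci_mean_diff <- function(a, b, n_boot = 2e4, seed = NULL,
                                   level = 0.95) {
  if (length(a) < 2 || length(b) < 2)
    stop_field("bootstrap_ci_mean_diff() needs n >= 2 per group")
  if (!is_count(n_boot)) stop_field("'n_boot' must be a positive integer")
  with_seed(seed, {
    ma <- matrix(sample(a, length(a) * n_boot, replace = TRUE), nrow = n_boot)
    mb <- matrix(sample(b, length(b) * n_boot, replace = TRUE), nrow = n_boot)
    d <- rowMeans(ma) - rowMeans(mb)
    q <- quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    c(lower = q[1], upper = q[2])
  })
}

#' Holm step-down adjustment of p values
#'
#' Standard step-down procedure: sort ascending, take running maxima of
#' \code{(m - j + 1) * p_(j)}, cap at 1, return in input order. Input p values
#' must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p values.
#' @return adjusted p values, same order as input.
#' @export
holm_adjust <- function(p_values) {
  if (!length(p_values) || any(!is.finite(p_values)) ||
      any(p_values <= 0) || any(p_values > 1))
    stop_field("holm_adjust() requires p values in (0, 1]")
  p.adjust(p_values, method = "holm")
}

#' All pairwise group contrasts for both change endpoints
#'
#' For each endpoint (delta upper, delta lower) and each of the three group
#' pairs: mean difference, stratified-bootstrap percentile 95% CI, two-sided
#' permutation p, Holm-adjusted p (family = the three pairwise contrasts
#' within the endpoint), and Hedges g. All randomness derives from
#' \code{seed} through per-contrast child seeds, so results are reproducible.
#'
#' @param delta a \code{delta_table} with exactly 3 groups.
#' @param n_perm permutations per contrast (default 100000).
#' @param n_boot bootstrap resamples per contrast CI (default 20000).
#' @param seed master integer seed.
#' @return data frame of class \code{contrast_results} with columns
#'   \code{endpoint, group_a, group_b, mean_diff, ci_lower, ci_upper,
#'   p_perm, p_holm, hedges_g, n_perm, n_boot}; 6 rows (2 endpoints x 3
#'   pairs). The master seed is attached as attribute \code{"seed"}.
#' @export
run_contrasts <- function(delta, n_perm = 1e5, n_boot = 2e4, seed = 1L) {
  groups <- unique(delta$group)
  if (length(groups) != 3)
    stop_field("run_contrasts() expects exactly 3 groups, got %d",
               length(groups))
  pairs <- combn(groups, 2)
  streams <- as.vector(outer(
    c("delta_upper", "delta_lower"),
    paste(pairs[1, ], pairs[2, ], sep = "."),
    paste, sep = "."))
  seeds <- child_seeds(seed, c(outer(streams, c("perm", "boot"), paste,
                                     sep = ".")))
  out <- list()
  for (endpoint in c("delta_upper", "delta_lower")) {
    block <- list()
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1, j]; gb <- pairs[2, j]
      a <- delta[[endpoint]][delta$group == ga]
      b <- delta[[endpoint]][delta$group == gb]
      key <- paste(endpoint, ga, gb, sep = ".")
      p <- permutation_test(a, b, n_perm = n_perm,
                            seed = seeds[[paste0(key, ".perm")]])
      ci <- bootstrap_ci_mean_diff(a, b, n_boot = n_boot,
                                   seed = seeds[[paste0(key, ".boot")]])
      block[[j]] <- data.frame(
        endpoint = endpoint, group_a = ga, group_b = gb,
        mean_diff = mean_diff(a, b),
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        p_perm = as.numeric(p), p_holm = NA_real_,
        hedges_g = hedges_g(a, b),
        n_perm = n_perm, n_boot = n_boot, stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, block)
    block$p_holm <- holm_adjust(block$p_perm)
    out[[endpoint]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  class(res) <- c("contrast_results", "data.frame")
  res
}

#' @export
print.contrast_results <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$p_perm <- format_p(df$p_perm)
  df$p_holm <- format_p(df$p_holm)
  num <- c("mean_diff", "ci_lower", "ci_upper", "hedges_g")
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
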
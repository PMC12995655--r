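panel_cols <- function(indicators, timepoint) paste(indicators, timepoint, sep = "_")

#' Fit a baseline one-component PCA composite model
#'
#' Standardizes the Pre columns of the listed indicators by their own mean and
#' SD, eigendecomposes the correlation matrix of the standardized block, and
#' retains the leading eigenvector as fixed loadings. The eigenvector is
#' oriented so its coefficient sum is positive (all-positive loadings for
#' positively correlated power indicators); an exact zero sum is resolved by
#' making the first coefficient non-negative. \code{variance_explained} is the
#' leading eigenvalue divided by the trace.
#'
#' @param panel a \code{cohort_panel} (or data frame with the needed columns).
#' @param domain label, \code{"upper"} or \code{"lower"}.
#' @param indicators ordered indicator names; defaults to the domain's
#'   standard set (bench press power + medicine-ball throw for upper;
#'   CMJ, SJ, DJ, SLJ for lower).
#' @return object of class \code{composite_model}: list with \code{domain},
#'   \code{indicators}, \code{baseline_mean}, \code{baseline_sd},
#'   \code{loadings} (unit norm), \code{variance_explained}.
#' @examples
#' panel <- generate_cohort(sim_config(seed = 1))
#' fit_baseline_pca(panel, "upper")
#' @export
fit_baseline_pca <- function(panel, domain = c("upper", "lower"),
                             indicators = indicator_names(domain)) {
  domain <- match.arg(domain)
  cols <- panel_cols(indicators, "pre")
  missing <- setdiff(cols, names(panel))
  if (length(missing))
    stop_field("missing baseline columns: %s", paste(missing, collapse = ", "))
  if (nrow(panel) < 3)
    stop_field("insufficient data: baseline PCA needs >= 3 swimmers, got %d",
               nrow(panel))
  X <- as.matrix(panel[, cols, drop = FALSE])
  if (anyNA(X)) stop_field("missing values in baseline indicator columns")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero))
    stop_field("degenerate input: zero baseline variance for indicator(s) %s",
               paste(indicators[zero], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  R <- cor(Z)
  eig <- eigen(R, symmetric = TRUE)
  v <- eig$vectors[, 1]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[1] < 0)) v <- -v
  structure(
    list(domain = domain, indicators = indicators,
         baseline_mean = setNames(as.numeric(mu), indicators),
         baseline_sd = setNames(as.numeric(sdv), indicators),
         loadings = setNames(as.numeric(v), indicators),
         variance_explained = eig$values[1] / sum(eig$values)),
    class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("Composite model (%s-limb power), PC1 of %d baseline indicators\n",
              x$domain, length(x$indicators)))
  cat(sprintf("  variance explained: %.3f\n", x$variance_explained))
  cat("  loadings:", paste(sprintf("%s=%.3f", x$indicators, x$loadings),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Project a panel onto a fitted composite model
#'
#' Computes \code{sum_j loadings_j * (x_j - baseline_mean_j) / baseline_sd_j}
#' for every swimmer at the requested time point. The baseline means and SDs
#' are always the Pre-fit values, whatever the time point, so composite scores
#' at Pre, Mid, and Post live on one baseline-anchored scale.
#'
#' @param model a \code{composite_model}.
#' @param panel a \code{cohort_panel}.
#' @param timepoint \code{"pre"}, \code{"mid"}, or \code{"post"}.
#' @return numeric vector of composite scores (composite units).
#' @export
apply_composite <- function(model, panel, timepoint = c("pre", "mid", "post")) {
  timepoint <- match.arg(timepoint)
  cols <- panel_cols(model$indicators, timepoint)
  missing <- setdiff(cols, names(panel))
  if (length(missing))
    stop_field("missing columns for timepoint '%s': %s", timepoint,
               paste(missing, collapse = ", "))
  X <- as.matrix(panel[, cols, drop = FALSE])
  if (anyNA(X)) stop_field("missing values in '%s' indicator columns", timepoint)
  Z <- sweep(sweep(X, 2, model$baseline_mean), 2, model$baseline_sd, "/")
  as.numeric(Z %*% model$loadings)
}

#' Composite scores at all time points and Post-Pre change scores
#'
#' @param upper_model,lower_model \code{composite_model}s fitted on this
#'   panel's Pre data.
#' @param panel a \code{cohort_panel}.
#' @return a \code{delta_table}: data frame with \code{swimmer_id},
#'   \code{group}, composite scores \code{upper_pre/mid/post} and
#'   \code{lower_pre/mid/post}, and change scores \code{delta_upper},
#'   \code{delta_lower} (Post minus Pre), row order preserved.
#' @export
compute_deltas <- function(upper_model, lower_model, panel) {
  out <- data.frame(
    swimmer_id = panel$swimmer_id,
    group = panel$group,
    stringsAsFactors = FALSE)
  for (tp in c("pre", "mid", "post")) {
    out[[paste0("upper_", tp)]] <- apply_composite(upper_model, panel, tp)
    out[[paste0("lower_", tp)]] <- apply_composite(lower_model, panel, tp)
  }
  out$delta_upper <- out$upper_post - out$upper_pre
  out$delta_lower <- out$lower_post - out$lower_pre
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Serialize / restore a composite model as JSON
#'
#' @param model a \code{composite_model}.
#' @param path file path; with \code{NULL}, \code{composite_to_json} returns
#'   the JSON string.
#' @return \code{composite_to_json}: the path (invisibly) or a JSON string;
#'   \code{composite_from_json}: a \code{composite_model}.
#' @export
composite_to_json <- function(model, path = NULL) {
  obj <- unclass(model)
  obj$baseline_mean <- as.list(obj$baseline_mean)
  obj$baseline_sd <- as.list(obj$baseline_sd)
  obj$loadings <- as.list(obj$loadings)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname composite_to_json
#' @param json JSON string (alternative to \code{path}).
#' @export
composite_from_json <- function(path = NULL, json = NULL) {
  obj <- if (is.null(json)) jsonlite::read_json(path, simplifyVector = TRUE)
         else jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(
    list(domain = obj$domain, indicators = obj$indicators,
         baseline_mean = unlist(obj$baseline_mean),
         baseline_sd = unlist(obj$baseline_sd),
         loadings = unlist(obj$loadings),
         variance_explained = obj$variance_explained),
    class = "composite_model")
}
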
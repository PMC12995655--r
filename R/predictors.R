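#' Default penalty grid for the regularized models
#'
#' 25 log-spaced values spanning 1e-3 to 1e3.
#' @return numeric vector.
#' @export
default_penalty_grid <- function() 10^seq(-3, 3, length.out = 25)

#' Build the predictor design matrix
#'
#' Features per swimmer: training-group indicators (CG as reference), a sex
#' indicator (male = 1), and four standardized continuous predictors -- years
#' of training, best 50 m freestyle time (seconds; larger = slower), and the
#' baseline upper and lower composite scores. Continuous predictors are
#' z-scored on this sample and the scaler stored; standardization is fixed at
#' design-build time (the scaler is part of the design, also during
#' cross-validation). Outcomes carried along: \code{delta_upper},
#' \code{delta_lower}, and, if cluster labels are supplied, a binary
#' \code{responder} indicator (1 = member of the cluster with the larger mean
#' \code{delta_upper}).
#'
#' @param panel a \code{cohort_panel}.
#' @param delta the matching \code{delta_table} (same swimmers, same order).
#' @param labels optional cluster labels aligned with the rows.
#' @param group_levels full set of group labels defining the indicator
#'   columns; the last level (or \code{"CG"} if present) is the reference.
#'   Subsamples lacking a level keep its (all-zero) indicator column.
#' @return object of class \code{predictor_design}: list with \code{X}
#'   (n x 7 matrix), \code{outcomes}, \code{scaler}, \code{groups},
#'   \code{swimmer_id}.
#' @export
build_design <- function(panel, delta, labels = NULL,
                         group_levels = c("MSTG", "PTG", "CG")) {
  if (!identical(as.character(panel$swimmer_id),
                 as.character(delta$swimmer_id)))
    stop_field("panel and delta rows are misaligned (swimmer_id mismatch)")
  extra <- setdiff(unique(panel$group), group_levels)
  if (length(extra))
    stop_field("group label(s) outside 'group_levels': %s",
               paste(extra, collapse = ", "))
  ref <- if ("CG" %in% group_levels) "CG" else group_levels[length(group_levels)]
  non_ref <- setdiff(group_levels, ref)
  ind <- vapply(non_ref, function(g) as.numeric(panel$group == g),
                numeric(nrow(panel)))
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = nrow(panel))
  colnames(ind) <- paste0("group_", non_ref)
  cont <- cbind(years_training = panel$years_training,
                best_50m = panel$best_50m,
                upper_pre = delta$upper_pre,
                lower_pre = delta$lower_pre)
  mu <- colMeans(cont)
  sdv <- apply(cont, 2, sd)
  if (any(sdv <= 0)) stop_field("zero-variance continuous predictor")
  Xc <- sweep(sweep(cont, 2, mu), 2, sdv, "/")
  X <- cbind(ind, sex_M = as.numeric(panel$sex == "M"), Xc)
  outcomes <- list(delta_upper = delta$delta_upper,
                   delta_lower = delta$delta_lower)
  if (!is.null(labels)) {
    if (length(labels) != nrow(panel))
      stop_field("labels length must match nrow(panel)")
    means <- tapply(delta$delta_upper, labels, mean)
    high <- names(means)[which.max(means)]
    outcomes$responder <- as.numeric(as.character(labels) == high)
  }
  structure(
    list(X = X, outcomes = outcomes,
         scaler = list(mean = mu, sd = sdv),
         reference_group = ref, groups = panel$group,
         swimmer_id = panel$swimmer_id),
    class = "predictor_design")
}

# ridge solve with unpenalized intercept: X1 includes the intercept column
ridge_coef <- function(X1, y, lambda) {
  P <- diag(c(0, rep(1, ncol(X1) - 1)))
  solve(crossprod(X1) + lambda * P, crossprod(X1, y))
}

ridge_loo_errors <- function(X1, y, lambda) {
  n <- nrow(X1)
  vapply(seq_len(n), function(i) {
    b <- ridge_coef(X1[-i, , drop = FALSE], y[-i], lambda)
    y[i] - drop(X1[i, , drop = FALSE] %*% b)
  }, numeric(1))
}

#' Ridge regression of a change endpoint with LOO-CV penalty selection
#'
#' For each penalty in the grid, leave-one-out predictions are computed by
#' explicit refitting (intercept unpenalized); the penalty minimizing the
#' LOO squared error is selected. Reported: \code{loo_rmse}, cross-validated
#' \code{cv_r2 = 1 - SS_loo / SS_total}, full-data coefficients at the
#' selected penalty, and case-resampling bootstrap percentile 95% intervals
#' with two-sided bootstrap p values
#' (\code{p = 2 min(frac <= 0, frac >= 0)}, capped at 1) per coefficient.
#'
#' @param design a \code{predictor_design}.
#' @param outcome \code{"delta_upper"} or \code{"delta_lower"}.
#' @param penalty_grid candidate ridge penalties (default
#'   \code{\link{default_penalty_grid}}).
#' @param n_boot bootstrap replicates for coefficient uncertainty
#'   (default 2000).
#' @param seed optional integer seed.
#' @return object of class \code{regression_report}: list with
#'   \code{outcome}, \code{penalty}, \code{penalty_grid},
#'   \code{coefficients} (data frame: term, estimate, ci_lower, ci_upper,
#'   p_boot), \code{loo_rmse}, \code{cv_r2}, \code{n_boot}, \code{seed}.
#' @export
fit_ridge_loo <- function(design, outcome = c("delta_upper", "delta_lower"),
                          penalty_grid = default_penalty_grid(),
                          n_boot = 2000, seed = NULL) {
  outcome <- match.arg(outcome)
  if (!length(penalty_grid)) stop_field("'penalty_grid' must be nonempty")
  y <- design$outcomes[[outcome]]
  X1 <- cbind(`(Intercept)` = 1, design$X)
  n <- nrow(X1)
  if (n < 5) stop_field("fit_ridge_loo() needs n >= 5")
  grid <- sort(penalty_grid)
  loo_mse <- vapply(grid, function(l) mean(ridge_loo_errors(X1, y, l)^2),
                    numeric(1))
  lambda <- grid[which.min(loo_mse)]
  e <- ridge_loo_errors(X1, y, lambda)
  beta <- drop(ridge_coef(X1, y, lambda))
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      drop(ridge_coef(X1[idx, , drop = FALSE], y[idx], lambda))
    }, numeric(ncol(X1))))
  })
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  p_boot <- apply(boot, 2, function(bb)
    min(1, 2 * min(mean(bb <= 0), mean(bb >= 0))))
  structure(
    list(outcome = outcome, penalty = lambda, penalty_grid = grid,
         coefficients = data.frame(
           term = colnames(X1), estimate = beta,
           ci_lower = ci[1, ], ci_upper = ci[2, ], p_boot = p_boot,
           row.names = NULL, stringsAsFactors = FALSE),
         loo_rmse = sqrt(mean(e^2)),
         cv_r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
         loo_mse_by_penalty = setNames(loo_mse, signif(grid, 4)),
         n_boot = n_boot, seed = seed),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Ridge regression of %s: penalty %.4g, LOO RMSE %.3f, CV R2 %.3f\n",
              x$outcome, x$penalty, x$loo_rmse, x$cv_r2))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

# L2-penalized logistic fit by Newton iterations; intercept unpenalized.
logistic_ridge_coef <- function(X1, y, lambda, max_iter = 100, tol = 1e-10) {
  p1 <- ncol(X1)
  P <- diag(c(0, rep(1, p1 - 1)))
  beta <- numeric(p1)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X1, mu - y) + 2 * lambda * P %*% beta
    H <- crossprod(X1 * w, X1) + 2 * lambda * P
    step <- solve(H, grad)
    beta <- beta - drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

log_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' L2-logistic classification of responder membership with LOO-CV
#'
#' L2-penalized logistic regression of the binary responder indicator on the
#' design features. The penalty is selected by leave-one-out log-loss
#' (explicit refitting); reported: LOO accuracy at threshold 0.5, mean LOO
#' log-loss (natural log), full-data coefficients with bootstrap percentile
#' intervals, bootstrap intervals for the pairwise between-group log-odds
#' contrasts, and predicted high-responder probabilities by training group at
#' mean covariate values (sex entered as its sample proportion).
#'
#' @inheritParams fit_ridge_loo
#' @param y optional binary outcome; defaults to the design's
#'   \code{responder} outcome.
#' @return object of class \code{classification_report}: list with
#'   \code{penalty}, \code{penalty_grid}, \code{coefficients},
#'   \code{group_contrasts}, \code{loo_accuracy}, \code{loo_logloss},
#'   \code{predicted_prob_by_group}, \code{n_boot}, \code{seed}.
#' @export
fit_logistic_l2_loo <- function(design, y = design$outcomes$responder,
                                penalty_grid = default_penalty_grid(),
                                n_boot = 2000, seed = NULL) {
  if (is.null(y)) stop_field("no binary outcome: supply cluster labels to build_design()")
  if (!length(penalty_grid)) stop_field("'penalty_grid' must be nonempty")
  y <- as.numeric(y)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop_field("both outcome classes must be present with >= 2 members")
  X1 <- cbind(`(Intercept)` = 1, design$X)
  n <- nrow(X1)
  grid <- sort(penalty_grid)
  loo_probs <- function(lambda) {
    vapply(seq_len(n), function(i) {
      b <- logistic_ridge_coef(X1[-i, , drop = FALSE], y[-i], lambda)
      plogis(drop(X1[i, , drop = FALSE] %*% b))
    }, numeric(1))
  }
  loo_ll <- vapply(grid, function(l) log_loss(y, loo_probs(l)), numeric(1))
  lambda <- grid[which.min(loo_ll)]
  p_loo <- loo_probs(lambda)
  beta <- logistic_ridge_coef(X1, y, lambda)
  names(beta) <- colnames(X1)

  group_cols <- grep("^group_", colnames(design$X), value = TRUE)
  contrast_of <- function(b) {
    b <- setNames(b, colnames(X1))
    cs <- c()
    for (g in group_cols)
      cs[paste(sub("^group_", "", g), "vs", design$reference_group)] <- b[[g]]
    if (length(group_cols) == 2)
      cs[paste(sub("^group_", "", group_cols[1]), "vs",
               sub("^group_", "", group_cols[2]))] <-
        b[[group_cols[1]]] - b[[group_cols[2]]]
    cs
  }
  obs_contrasts <- contrast_of(beta)

  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, ncol(X1) + length(obs_contrasts))
    b <- 1L; tries <- 0L
    while (b <= n_boot && tries < 50L * n_boot) {
      tries <- tries + 1L
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2) next  # single-class draw: redraw
      bb <- logistic_ridge_coef(X1[idx, , drop = FALSE], y[idx], lambda)
      out[b, ] <- c(bb, contrast_of(bb))
      b <- b + 1L
    }
    out[seq_len(b - 1L), , drop = FALSE]
  })
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  nc <- ncol(X1)

  # predicted probability per group at mean covariates
  xbar <- colMeans(design$X)
  prob_by_group <- setNames(numeric(0), character(0))
  for (g in unique(design$groups)) {
    x <- xbar
    x[group_cols] <- as.numeric(paste0("group_", g) == group_cols)
    prob_by_group[g] <- plogis(drop(c(1, x) %*% beta))
  }

  structure(
    list(penalty = lambda, penalty_grid = grid,
         coefficients = data.frame(
           term = colnames(X1), estimate = beta,
           ci_lower = ci[1, seq_len(nc)], ci_upper = ci[2, seq_len(nc)],
           row.names = NULL, stringsAsFactors = FALSE),
         group_contrasts = data.frame(
           contrast = names(obs_contrasts), log_odds = obs_contrasts,
           ci_lower = ci[1, nc + seq_along(obs_contrasts)],
           ci_upper = ci[2, nc + seq_along(obs_contrasts)],
           row.names = NULL, stringsAsFactors = FALSE),
         loo_accuracy = mean((p_loo >= 0.5) == (y == 1)),
         loo_logloss = log_loss(y, p_loo),
         loo_logloss_by_penalty = setNames(loo_ll, signif(grid, 4)),
         predicted_prob_by_group = prob_by_group,
         n_boot = nrow(boot), seed = seed),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "L2-logistic responder model: penalty %.4g, LOO accuracy %.3f, LOO log-loss %.3f\n",
    x$penalty, x$loo_accuracy, x$loo_logloss))
  cat("Predicted high-responder probability at mean covariates:\n")
  print(round(x$predicted_prob_by_group, 3))
  print(x$group_contrasts, row.names = FALSE, digits = 3)
  invisible(x)
}
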
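#' Standardize the two-dimensional change vector
#'
#' Z-scores \code{delta_upper} and \code{delta_lower} by their full-sample
#' mean and SD; the scaler is returned so bootstrap replicates can be placed
#' in the same standardized change space as the original solution.
#'
#' @param delta a \code{delta_table} with n >= 3 rows.
#' @return list with \code{points} (n x 2 matrix, columns
#'   \code{delta_upper}, \code{delta_lower}) and \code{scaler} (list of
#'   \code{mean}, \code{sd} per column).
#' @export
standardize_deltas <- function(delta) {
  if (nrow(delta) < 3) stop_field("standardize_deltas() needs n >= 3")
  X <- as.matrix(delta[, c("delta_upper", "delta_lower")])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  bad <- sdv <= 0 | !is.finite(sdv)
  if (any(bad))
    stop_field("zero-variance change column(s): %s",
               paste(colnames(X)[bad], collapse = ", "))
  list(points = sweep(sweep(X, 2, mu), 2, sdv, "/"),
       scaler = list(mean = mu, sd = sdv))
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2, scaler$mean), 2, scaler$sd, "/")
}

#' Ward agglomerative clustering cut at k clusters
#'
#' Ward's minimum-variance linkage on Euclidean distances
#' (\code{stats::hclust}, method \code{"ward.D2"}), cut into \code{k}
#' clusters. Labels are renumbered in order of first appearance, so the
#' assignment is deterministic given the input row order.
#'
#' @param points numeric matrix (n x d).
#' @param k number of clusters, \code{2 <= k <= n}.
#' @return integer vector of cluster labels in \code{1..k}.
#' @export
ward_cluster <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is_count(k, min = 2) || k > n)
    stop_field("'k' must be an integer in [2, n = %d]", n)
  labels <- cutree(hclust(dist(points), method = "ward.D2"), k = k)
  as.integer(factor(labels, levels = unique(labels)))
}

#' Mean silhouette score of a clustering
#'
#' For each point, \code{s = (b - a) / max(a, b)} where \code{a} is its mean
#' distance to the other members of its own cluster and \code{b} the smallest
#' mean distance to any other cluster; a singleton contributes \code{s = 0}.
#' Returns the mean over points.
#'
#' @param points numeric matrix (n x d).
#' @param labels integer cluster labels with \code{2 <= k <= n - 1} clusters.
#' @return mean silhouette width in \code{[-1, 1]}.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(labels) != n) stop_field("labels length must match nrow(points)")
  ks <- sort(unique(labels))
  if (length(ks) < 2 || length(ks) > n - 1)
    stop_field("silhouette needs 2 <= k <= n - 1 nonempty clusters")
  D <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(ks[ks != labels[i]],
                    function(kk) mean(D[i, labels == kk]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# selection rule on a candidates table: drop candidates whose smallest
# cluster is below min_cluster_size, take max silhouette among survivors;
# if none survive, max silhouette overall with a warning. Ties go to the
# smaller k (earlier row).
pick_candidate <- function(candidates, min_cluster_size) {
  ok <- candidates$min_size >= min_cluster_size
  pool <- if (any(ok)) candidates[ok, ] else candidates
  if (!any(ok))
    warning("all candidate solutions have a cluster smaller than ",
            min_cluster_size, "; selecting by silhouette alone", call. = FALSE)
  pool$k[which.max(pool$silhouette)]
}

#' Select the number of clusters by silhouette with a small-cluster guard
#'
#' Fits Ward clustering for every k in \code{k_range}, discards candidates
#' whose smallest cluster has fewer than \code{min_cluster_size} members, and
#' picks the surviving solution with the highest silhouette score (if every
#' candidate is discarded, the overall silhouette maximum is used with a
#' warning). Diagnostics for all candidates are retained.
#'
#' @param points numeric matrix (n x d), typically standardized change scores.
#' @param k_range candidate cluster numbers (default \code{2:4}).
#' @param min_cluster_size smallest admissible cluster (default 5).
#' @return object of class \code{cluster_solution}: list with \code{k},
#'   \code{labels}, \code{silhouette}, \code{sizes}, and a \code{candidates}
#'   data frame (\code{k, silhouette, min_size, sizes}).
#' @export
select_k <- function(points, k_range = 2:4, min_cluster_size = 5) {
  if (!length(k_range)) stop_field("'k_range' must be nonempty")
  points <- as.matrix(points)
  n <- nrow(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop_field("'k_range' must lie within [2, n - 1]")
  fits <- lapply(k_range, function(k) {
    labels <- ward_cluster(points, k)
    sizes <- as.integer(table(labels))
    list(k = k, labels = labels, sizes = sizes,
         silhouette = silhouette_score(points, labels))
  })
  candidates <- do.call(rbind, lapply(fits, function(f)
    data.frame(k = f$k, silhouette = f$silhouette,
               min_size = min(f$sizes),
               sizes = paste(f$sizes, collapse = "; "),
               stringsAsFactors = FALSE)))
  k_sel <- pick_candidate(candidates, min_cluster_size)
  sel <- fits[[match(k_sel, k_range)]]
  structure(
    list(k = sel$k, labels = sel$labels, silhouette = sel$silhouette,
         sizes = sel$sizes, candidates = candidates,
         min_cluster_size = min_cluster_size),
    class = "cluster_solution")
}

#' Responder-signature discovery on a change table
#'
#' Standardizes (delta upper, delta lower), runs \code{\link{select_k}}, and
#' attaches the standardization scaler and raw-unit cluster profiles. This is
#' the entry point whose output feeds \code{\link{bootstrap_stability}}.
#'
#' @inheritParams select_k
#' @param delta a \code{delta_table}.
#' @return a \code{cluster_solution} with additional fields \code{scaler}
#'   and \code{profiles}.
#' @export
find_signatures <- function(delta, k_range = 2:4, min_cluster_size = 5) {
  std <- standardize_deltas(delta)
  sol <- select_k(std$points, k_range = k_range,
                  min_cluster_size = min_cluster_size)
  sol$scaler <- std$scaler
  sol$profiles <- cluster_profiles(delta, sol$labels)
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Ward clustering, selected k = %d (silhouette %.3f, sizes %s)\n",
              x$k, x$silhouette, paste(x$sizes, collapse = "; ")))
  cat("Candidates:\n")
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Cluster profiles in raw composite units
#'
#' Per cluster and endpoint: n, mean, sample SD, and t-based 95% CI of the
#' change scores (not the standardized values).
#'
#' @param delta a \code{delta_table}.
#' @param labels integer cluster labels aligned with \code{delta} rows.
#' @return data frame with columns \code{cluster, endpoint, n, mean, sd,
#'   ci_lower, ci_upper}.
#' @export
cluster_profiles <- function(delta, labels) {
  if (length(labels) != nrow(delta))
    stop_field("labels length must match nrow(delta)")
  rows <- list()
  for (cl in sort(unique(labels))) {
    for (endpoint in c("delta_upper", "delta_lower")) {
      x <- delta[[endpoint]][labels == cl]
      ci <- if (length(x) >= 2) t_ci(mean(x), sd(x), length(x))
            else c(lower = NA_real_, upper = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, endpoint = endpoint, n = length(x),
        mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_,
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting Rand index corrected for chance agreement; 1 for identical
#' partitions (up to label names), about 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return numeric ARI in \code{[-1, 1]}.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_field("labelings must have equal length")
  n <- length(labels_a)
  if (n < 2) stop_field("adjusted_rand_index() needs length >= 2")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Jaccard similarity between two sets
#'
#' \code{|intersection| / |union|} of the two member sets.
#'
#' @param set_a,set_b vectors of member identifiers (duplicates ignored).
#' @return numeric in \code{[0, 1]}.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) && !length(set_b))
    stop_field("jaccard_index() needs at least one nonempty set")
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

# all permutations of 1..n in lexicographic order (n <= ~6)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

#' Maximum-overlap matching of cluster labels
#'
#' One-to-one assignment of new cluster ids to reference ids maximizing the
#' total overlap on the k x k contingency table (optimal assignment by
#' exhaustive enumeration; differing cluster counts are handled by padding
#' with empty pseudo-clusters). Ties are broken toward the lexicographically
#' first assignment, i.e. the lowest reference id.
#'
#' @param labels_ref,labels_new labelings over the same point set.
#' @return named integer vector mapping each new cluster id to a reference
#'   cluster id.
#' @export
max_overlap_match <- function(labels_ref, labels_new) {
  if (length(labels_ref) != length(labels_new))
    stop_field("labelings must have equal length")
  ref_ids <- sort(unique(labels_ref))
  new_ids <- sort(unique(labels_new))
  k <- max(length(ref_ids), length(new_ids))
  tab <- matrix(0, k, k)
  cnt <- table(factor(labels_ref, levels = ref_ids),
               factor(labels_new, levels = new_ids))
  tab[seq_along(ref_ids), seq_along(new_ids)] <- cnt
  perms <- all_perms(k)  # row i: ref id index assigned to new-cluster index i
  overlaps <- apply(perms, 1, function(p)
    sum(tab[cbind(p, seq_len(k))]))
  best <- perms[which.max(overlaps), ]
  # pad ids beyond the observed ones so the mapping stays one-to-one
  ref_full <- c(ref_ids, setdiff(seq_len(max(k, max(ref_ids))), ref_ids))[seq_len(k)]
  new_full <- c(new_ids, setdiff(seq_len(max(k, max(new_ids))), new_ids))[seq_len(k)]
  setNames(as.integer(ref_full[best]), new_full)[as.character(new_ids)]
}

#' Bootstrap stability of a clustering solution
#'
#' Per replicate: resample n swimmers with replacement, standardize with the
#' original scaler (so replicate and original points share one space), refit
#' Ward clustering with the selected k, compute the replicate's cluster
#' centroids in standardized space, assign every original swimmer to the
#' nearest centroid (Euclidean; ties to the lowest cluster id), align the
#' assigned labels to the original solution by maximum-overlap matching, and
#' record the adjusted Rand index plus each original cluster's Jaccard
#' similarity with its matched cluster. A replicate whose assignment leaves a
#' cluster empty is retained and scored on the realized sets.
#'
#' @param delta a \code{delta_table}.
#' @param solution a \code{cluster_solution} from \code{\link{find_signatures}}
#'   (must carry the standardization scaler).
#' @param n_replicates bootstrap replicates (default 2000).
#' @param seed optional integer seed.
#' @param resample with \code{FALSE} every "bootstrap sample" is the original
#'   sample (diagnostic mode; ARI and Jaccard are then exactly 1).
#' @return object of class \code{stability_report}: list with
#'   \code{n_replicates}, \code{ari_mean}, \code{ari_sd}, \code{ari_ci95},
#'   \code{ari_distribution}, and \code{jaccard} (per-cluster data frame with
#'   mean, sd, percentile 95% interval) plus the replicate-level
#'   \code{jaccard_distribution}.
#' @export
bootstrap_stability <- function(delta, solution, n_replicates = 2000,
                                seed = NULL, resample = TRUE) {
  if (is.null(solution$scaler))
    stop_field("solution carries no scaler; use find_signatures()")
  if (!is_count(n_replicates)) stop_field("'n_replicates' must be >= 1")
  k <- solution$k
  if (k < 2) stop_field("stability needs a fitted solution with k >= 2")
  Z <- apply_scaler(solution$scaler,
                    delta[, c("delta_upper", "delta_lower")])
  n <- nrow(Z)
  orig <- solution$labels
  clusters <- sort(unique(orig))
  with_seed(seed, {
    ari <- numeric(n_replicates)
    jac <- matrix(NA_real_, n_replicates, length(clusters),
                  dimnames = list(NULL, paste0("cluster_", clusters)))
    for (r in seq_len(n_replicates)) {
      idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      Zr <- Z[idx, , drop = FALSE]
      lab_r <- ward_cluster(Zr, k)
      cent <- vapply(seq_len(k), function(cl)
        colMeans(Zr[lab_r == cl, , drop = FALSE]), numeric(ncol(Z)))
      d2 <- outer(rowSums(Z^2), rep(1, k)) - 2 * Z %*% cent +
        outer(rep(1, n), colSums(cent^2))
      assigned <- max.col(-d2, ties.method = "first")
      mapping <- max_overlap_match(orig, assigned)
      mapped <- mapping[as.character(assigned)]
      ari[r] <- adjusted_rand_index(orig, mapped)
      for (ci in seq_along(clusters)) {
        A <- which(orig == clusters[ci])
        B <- which(mapped == clusters[ci])
        jac[r, ci] <- if (!length(A) && !length(B)) NA_real_
                      else jaccard_index(A, B)
      }
    }
    qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    jdf <- do.call(rbind, lapply(seq_along(clusters), function(ci) {
      x <- jac[, ci]
      data.frame(cluster = clusters[ci], mean = mean(x, na.rm = TRUE),
                 sd = sd(x[!is.na(x)]),
                 ci_lower = qs(x)[1], ci_upper = qs(x)[2],
                 stringsAsFactors = FALSE)
    }))
    structure(
      list(n_replicates = n_replicates,
           ari_mean = mean(ari), ari_sd = sd(ari),
           ari_ci95 = c(lower = qs(ari)[1], upper = qs(ari)[2]),
           ari_distribution = ari,
           jaccard = jdf, jaccard_distribution = jac,
           seed = seed),
      class = "stability_report")
  })
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap stability (%d replicates): mean ARI %.3f [%.3f, %.3f]\n",
              x$n_replicates, x$ari_mean, x$ari_ci95[["lower"]],
              x$ari_ci95[["upper"]]))
  cat("Cluster-wise Jaccard similarity:\n")
  print(x$jaccard, row.names = FALSE)
  invisible(x)
}

pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0))
    stop_field("empty row/column category in contingency table")
  sum((tab - E)^2 / E)
}

#' Permutation chi-square test of group-cluster association
#'
#' Pearson chi-square statistic on the observed cluster x group table; the
#' null distribution is generated by randomly permuting the group assignments
#' (which preserves both margins), and
#' \code{p = (1 + #\{chi2* >= chi2\}) / (n_perm + 1)}.
#'
#' @param groups group labels per swimmer (>= 2 categories).
#' @param labels cluster labels per swimmer (>= 2 categories).
#' @param n_perm number of permutations (default 100000).
#' @param seed optional integer seed.
#' @return object of class \code{association_report}: list with
#'   \code{contingency} (cluster x group), \code{chi2}, \code{p_perm},
#'   \code{n_perm}, \code{seed}.
#' @export
permutation_chi2 <- function(groups, labels, n_perm = 1e5, seed = NULL) {
  if (length(groups) != length(labels))
    stop_field("'groups' and 'labels' must have equal length")
  if (length(groups) < 2) stop_field("permutation_chi2() needs n >= 2")
  gf <- factor(groups); cf <- factor(labels)
  if (nlevels(gf) < 2 || nlevels(cf) < 2)
    stop_field("need >= 2 groups and >= 2 clusters")
  if (!is_count(n_perm)) stop_field("'n_perm' must be a positive integer")
  tab <- table(cluster = cf, group = gf)
  chi2 <- pearson_chi2(tab)
  K <- nlevels(cf); G <- nlevels(gf)
  ci <- as.integer(cf); gi <- as.integer(gf)
  E <- as.vector(outer(rowSums(tab), colSums(tab)) / length(gi))
  thr <- chi2 - 1e-12 * max(1, chi2)
  with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      gp <- gi[sample.int(length(gi))]
      O <- tabulate(ci + K * (gp - 1L), nbins = K * G)
      if (sum((O - E)^2 / E) >= thr) cnt <- cnt + 1L
    }
    structure(
      list(contingency = tab, chi2 = chi2,
           p_perm = (1 + cnt) / (n_perm + 1), n_perm = n_perm, seed = seed),
      class = "association_report")
  })
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("Permutation chi-square: chi2 = %.3f, p = %s (%d permutations)\n",
              x$chi2, format_p(x$p_perm), x$n_perm))
  print(x$contingency)
  invisible(x)
}
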
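#' Scatter of the change space with cluster labels
#'
#' The (delta upper, delta lower) plane in composite units, colored by
#' responder signature and shaped by training group.
#'
#' @param delta a \code{delta_table}.
#' @param labels cluster labels aligned with the rows.
#' @return a ggplot object.
#' @export
plot_change_space <- function(delta, labels) {
  df <- data.frame(delta_upper = delta$delta_upper,
                   delta_lower = delta$delta_lower,
                   group = delta$group,
                   cluster = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(
      x = delta_upper, y = delta_lower,
      colour = cluster, shape = group)) +
    ggplot2::geom_point(size = 3, alpha = 0.9) +
    ggplot2::labs(x = "ΔUpper (Post−Pre, composite units)",
                  y = "ΔLower (Post−Pre, composite units)",
                  colour = "Signature", shape = "Group") +
    ggplot2::theme_minimal()
}

#' Silhouette score by candidate cluster number
#'
#' @param candidates the \code{candidates} table of a
#'   \code{cluster_solution}.
#' @return a ggplot object.
#' @export
plot_silhouette_by_k <- function(candidates) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(x = factor(k), y = silhouette)) +
    ggplot2::geom_col(width = 0.6, fill = "grey35") +
    ggplot2::labs(x = "k", y = "Mean silhouette") +
    ggplot2::theme_minimal()
}

#' Histogram of bootstrap adjusted Rand index values
#'
#' @param stability a \code{stability_report}.
#' @return a ggplot object.
#' @export
plot_ari_histogram <- function(stability) {
  df <- data.frame(ari = stability$ari_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = ari)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = stability$ari_mean, linetype = 2) +
    ggplot2::labs(x = "Adjusted Rand index", y = "Replicates") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("delta_upper", "delta_lower", "cluster", "group",
                         "k", "silhouette", "ari"))
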
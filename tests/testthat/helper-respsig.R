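# sample of size n with exactly the requested mean and sd
sample_with_stats <- function(m, s, n) {
  z <- seq_len(n)
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

# two/three well-separated Gaussian blobs in 2-D
make_blobs <- function(sizes, centers, spread = 0.3, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_along(sizes), function(i)
      cbind(rnorm(sizes[i], centers[[i]][1], spread),
            rnorm(sizes[i], centers[[i]][2], spread))))
    list(points = pts, truth = rep(seq_along(sizes), sizes))
  })
}

# exhaustive minimum within-cluster-sum-of-squares 2-partition
brute_min_wss_k2 <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  wss <- function(X) if (nrow(X) <= 1) 0 else
    sum(sweep(X, 2, colMeans(X))^2)
  best <- NULL; best_w <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # point 1 fixed in cluster 1
    memb <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    w <- wss(points[memb == 1, , drop = FALSE]) +
      wss(points[memb == 2, , drop = FALSE])
    if (w < best_w) { best_w <- w; best <- memb }
  }
  list(labels = best, wss = best_w)
}

# minimal hand-made panel with just the columns the composite stage needs
hand_panel <- function(values) {
  # values: named list of indicator_timepoint vectors, plus ids/groups
  n <- length(values[[1]])
  df <- data.frame(swimmer_id = sprintf("S%02d", seq_len(n)),
                   group = rep("G", n), stringsAsFactors = FALSE)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  df
}

# delta_table built directly from change scores (bypassing composites)
hand_delta <- function(delta_upper, delta_lower, group = NULL) {
  n <- length(delta_upper)
  structure(
    data.frame(swimmer_id = sprintf("S%02d", seq_len(n)),
               group = group %||% rep("G", n),
               delta_upper = delta_upper, delta_lower = delta_lower,
               stringsAsFactors = FALSE),
    class = c("delta_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Table 2 printed group summaries (composite units)
table2 <- data.frame(
  endpoint = rep(c("delta_upper", "delta_lower"), each = 3),
  group = rep(c("MSTG", "PTG", "CG"), 2),
  mean = c(0.962, 0.762, 0.332, 0.822, 0.758, 0.388),
  sd = c(0.129, 0.218, 0.058, 0.125, 0.150, 0.059),
  ci_lower = c(0.863, 0.595, 0.288, 0.726, 0.643, 0.343),
  ci_upper = c(1.061, 0.930, 0.377, 0.918, 0.873, 0.434),
  stringsAsFactors = FALSE)
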
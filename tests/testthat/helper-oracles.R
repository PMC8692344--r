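# Shared fixtures and independent oracles.

# Exhaustive-search Ward agglomeration: at every step evaluate the increase
# in within-cluster sum of squares for every cluster pair and merge the
# minimum. Heights reported on the distance scale, sqrt(2 * delta SS).
bf_ward <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (i < j) {
      A <- clusters[[i]]; B <- clusters[[j]]
      mA <- colMeans(X[A, , drop = FALSE]); mB <- colMeans(X[B, , drop = FALSE])
      dss <- length(A) * length(B) / (length(A) + length(B)) * sum((mA - mB)^2)
      if (dss < best[1] - 1e-12) best <- c(dss, i, j)
    }
    heights[s] <- sqrt(2 * best[1])
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[s]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","), "")),
        collapse = "|")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small all-one-stage hypnogram helper.
stage_block <- function(stage, minutes) hypnogram(rep(stage, minutes * 2))

# A z-scored random feature matrix with subject names.
random_features <- function(n = 60, p = 33, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)), paste0("f", seq_len(p))))
  X
}

quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))
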
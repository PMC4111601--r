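# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they cross-check, never mirror, the implementation.

# Naive O(n^3) average-linkage agglomeration on a row matrix. Returns the
# merge heights (in order) and the cluster membership vector after each
# merge.
naive_avg_linkage <- function(X) {
  d <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  membership <- function(cl) {
    v <- integer(nrow(X))
    for (i in seq_along(cl)) v[cl[[i]]] <- i
    v
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1L]) best <- c(h, i, j)
      }
    }
    i <- best[2L]; j <- best[3L]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1L])
    partitions[[length(partitions) + 1L]] <- membership(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# partitions equal up to label renaming: compare co-membership matrices
co_membership_equal <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# exact hypergeometric upper tail by enumeration over the support
hyper_tail_enum <- function(k, K, N, n) {
  js <- max(k, 0):min(n, K)
  if (length(js) == 0L || max(js) < k) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# direct covariance / (sd * sd) Pearson formula
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# build an slr_matrix fixture directly from values
make_slr <- function(vals, times, baseline = colnames(vals)[1L],
                     condition = "maturation") {
  structure(vals,
            timepoints = stats::setNames(times, colnames(vals)),
            baseline = baseline, condition = condition,
            class = c("slr_matrix", "matrix", "array"))
}

# n replicates realizing a printed mean +/- SD exactly (n = 3)
replicates_from_summary <- function(mean, sd) c(mean - sd, mean, mean + sd)

# quick expression matrix fixture
make_expr <- function(vals, channel = "mRNA") {
  trioma::expression_matrix(vals, channel, allow_negative = TRUE)
}
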
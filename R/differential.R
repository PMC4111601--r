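#' Threshold-based differential-expression calls
#'
#' A probe is differentially expressed iff |SLR| strictly exceeds the cut
#' at one or more non-baseline timepoints ("on at least one of the days as
#' compared to Day 2"). The per-timepoint direction is `up` when SLR > cut,
#' `down` when SLR < -cut, `flat` otherwise.
#'
#' @param slr an `slr_matrix` from [compute_slr()].
#' @param cut positive threshold on |SLR|; 1.0 for the mRNA/lncRNA
#'   channels, 0.6 for miRNA (see [analysis_config()]).
#' @return data.frame with `probe_id`, `max_abs_slr`, `is_de` and one
#'   `dir_<sample>` factor column per non-baseline timepoint.
#' @export
call_differential <- function(slr, cut = 1.0) {
  if (cut <= 0) stop("'cut' must be positive")
  base <- attr(slr, "baseline")
  nb <- setdiff(colnames(slr), base)
  vals <- unclass(slr)[, nb, drop = FALSE]
  if (nrow(slr) == 0L) {
    out <- data.frame(probe_id = character(), max_abs_slr = numeric(),
                      is_de = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  m <- apply(abs(vals), 1L, max)
  out <- data.frame(probe_id = rownames(slr), max_abs_slr = m,
                    is_de = m > cut, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (s in nb) {
    d <- ifelse(vals[, s] > cut, "up", ifelse(vals[, s] < -cut, "down", "flat"))
    out[[paste0("dir_", s)]] <- factor(d, levels = c("down", "flat", "up"))
  }
  out
}

#' Average-linkage hierarchical clustering of SLR profiles
#'
#' UPGMA agglomeration on Euclidean distances, as used for the expression
#' heatmaps: at each step the pair of clusters with the smallest average
#' pairwise distance is merged. Delegates to [stats::hclust()] with
#' `method = "average"`.
#'
#' @param x an `slr_matrix` or plain numeric matrix (no missing values).
#' @param on cluster the `"probes"` (rows) or the `"samples"` (columns).
#' @return an object of class `hclust` (leaves = items, `height` = average
#'   inter-cluster distance at each merge).
#' @export
hierarchical_cluster <- function(x, on = c("probes", "samples")) {
  on <- match.arg(on)
  m <- unclass(x)
  if (on == "samples") m <- t(m)
  if (nrow(m) < 2L) stop("need >= 2 items to cluster")
  if (anyNA(m)) stop("missing values not allowed")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' Cuts at the smallest merge height that yields exactly `k` clusters.
#' When tied merge heights make a count unreachable, the achievable counts
#' are reported in the error.
#'
#' @param tree an `hclust` object.
#' @param k desired number of clusters, between 1 and the leaf count.
#' @return named integer vector of cluster labels (1..k) per leaf.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  labels <- stats::cutree(tree, k = k)
  if (length(unique(labels)) != k) {
    achievable <- sort(unique(vapply(seq_len(n), function(j)
      length(unique(stats::cutree(tree, k = j))), integer(1L))))
    stop("k = ", k, " unreachable under tied merge heights; achievable ",
         "cluster counts: ", paste(achievable, collapse = ", "))
  }
  labels
}
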
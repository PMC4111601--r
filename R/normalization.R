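#' Quantile-normalize an expression matrix
#'
#' First-stage normalization of the mRNA/lncRNA channels: every sample
#' (column) is forced onto the common reference distribution given by the
#' row-wise mean of the sorted columns. Tied values within a column receive
#' the mean of the reference quantiles over their rank span. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param x an [expression_matrix()] (or plain numeric matrix) with at least
#'   two samples.
#' @return matrix of the same shape and class with equalized column
#'   distributions.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L)
    stop("quantile normalization needs >= 2 samples")
  if (!all(is.finite(x))) stop("values must be finite")
  out <- limma::normalizeQuantiles(unclass(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (inherits(x, "expr_matrix"))
    out <- expression_matrix(out, channel(x), allow_negative = TRUE)
  out
}

#' Preprocess the miRNA channel: detection floor and control scaling
#'
#' Input intensities are background-subtracted. A probe is flagged
#' *detected* iff its mean intensity across samples is at or above the
#' detection floor (default 300). Each sample is then scaled by the
#' geometric mean of that sample's endogenous-control probes. Detection
#' flags are computed on the input, before control scaling, so they do not
#' depend on the controls. Undetected probes are retained (flag `FALSE`)
#' for the caller to exclude from differential calls.
#'
#' @param x miRNA-channel [expression_matrix()].
#' @param control_probes probe ids of the endogenous controls; must all be
#'   present with strictly positive intensity in every sample.
#' @param floor detection floor on the mean background-subtracted intensity.
#' @param background optional matrix of background intensities to subtract
#'   (same shape as `x`); use when `x` holds raw rather than
#'   background-subtracted values.
#' @return list with `matrix` (control-normalized `expr_matrix`) and
#'   `detected` (named logical per probe).
#' @export
mirna_preprocess <- function(x, control_probes, floor = 300,
                             background = NULL) {
  if (!identical(channel(x), "miRNA"))
    stop("mirna_preprocess expects the miRNA channel")
  vals <- unclass(x)
  if (!is.null(background)) vals <- vals - as.matrix(background)
  missing <- setdiff(control_probes, rownames(vals))
  if (length(missing))
    stop("control probe missing from matrix: ", missing[1L])
  ctl <- vals[control_probes, , drop = FALSE]
  if (any(ctl <= 0)) {
    bad <- which(ctl <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("control probe '%s' non-positive in sample '%s'",
                 control_probes[bad[["row"]]], colnames(vals)[bad[["col"]]]))
  }
  detected <- rowMeans(vals) >= floor
  scale <- exp(colMeans(log(ctl)))   # per-sample geometric mean of controls
  norm <- sweep(vals, 2L, scale, "/")
  list(matrix = expression_matrix(norm, "miRNA", allow_negative = TRUE),
       detected = detected)
}

#' Second-stage normalization: baseline-anchored Signal Log Ratios
#'
#' Divides every sample by the condition's baseline sample (Day 2 for
#' maturation, 0 h for OGD) and log2-transforms, yielding the Signal Log
#' Ratio SLR\[p, t\] = log2(intensity\[p, t\] / intensity\[p, baseline\]).
#' The baseline column of the result is identically zero. Probes with a
#' non-positive intensity in any design sample cannot enter the log ratio
#' and are dropped with a message.
#'
#' @param x an [expression_matrix()] containing the design's samples.
#' @param design a [sample_design()].
#' @return matrix of class `slr_matrix` (probes x timepoints) with
#'   attributes `timepoints`, `baseline` and `condition`; columns are named
#'   by sample id.
#' @export
compute_slr <- function(x, design) {
  stopifnot(inherits(design, "sample_design"))
  if (!design$baseline %in% colnames(x))
    stop("baseline sample missing from matrix: ", design$baseline)
  miss <- setdiff(design$samples, colnames(x))
  if (length(miss)) stop("design sample missing from matrix: ", miss[1L])
  vals <- unclass(x)[, design$samples, drop = FALSE]
  ok <- apply(vals > 0, 1L, all)
  if (!all(ok))
    message(sum(!ok), " probe(s) dropped from SLR (non-positive intensity)")
  vals <- vals[ok, , drop = FALSE]
  slr <- log2(vals / vals[, design$baseline])
  structure(slr,
            timepoints = stats::setNames(design$timepoints, design$samples),
            baseline = design$baseline,
            condition = design$condition,
            class = c("slr_matrix", "matrix", "array"))
}

#' @export
print.slr_matrix <- function(x, ...) {
  cat(sprintf("<slr_matrix> %s, %d probes, baseline %s, timepoints %s\n",
              attr(x, "condition"), nrow(x), attr(x, "baseline"),
              paste(attr(x, "timepoints"), collapse = "/")))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Timepoint coordinates of an SLR matrix
#' @param x an `slr_matrix`.
#' @return named numeric vector (sample id -> time).
#' @export
slr_timepoints <- function(x) attr(x, "timepoints")
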
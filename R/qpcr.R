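#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-condition delta-Ct (target minus reference gene), the
#' delta-delta-Ct against the calibrator condition and the fold change
#' 2^-ddCt. When replicate C_T vectors of equal length are given, the
#' delta-Ct is formed per replicate and the SD of the replicate ddCt values
#' is propagated; otherwise replicate means are used.
#'
#' "Undetermined" wells must be encoded as `NA` and resolved (via
#' [presence_call()]) before quantification; any `NA` here is an error.
#'
#' @param ct_target,ct_ref C_T replicates of the target and reference gene
#'   in the sample of interest.
#' @param ct_target_cal,ct_ref_cal the same in the calibrator condition
#'   (Day 2 or 0 h OGD).
#' @return list with `fold`, `ddct`, `sd` (NA when replicate-wise SD is not
#'   computable) and `fold_range` (fold at ddct -/+ sd).
#' @export
ddct_fold_change <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  all_ct <- c(ct_target, ct_ref, ct_target_cal, ct_ref_cal)
  if (anyNA(all_ct))
    stop("Undetermined C_T in input; run presence_call() first")
  paired <- length(ct_target) == length(ct_ref) &&
    length(ct_target_cal) == length(ct_ref_cal) &&
    length(ct_target) == length(ct_target_cal) && length(ct_target) > 1L
  if (paired) {
    ddct_rep <- (ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)
    ddct <- mean(ddct_rep)
    s <- stats::sd(ddct_rep)
  } else {
    ddct <- (mean(ct_target) - mean(ct_ref)) -
      (mean(ct_target_cal) - mean(ct_ref_cal))
    s <- NA_real_
  }
  list(fold = 2^(-ddct), ddct = ddct, sd = s,
       fold_range = if (is.na(s)) c(NA_real_, NA_real_) else
         2^(-c(ddct + s, ddct - s)))
}

#' Presence/absence call for a qPCR assay
#'
#' An assay is *absent* when its mean C_T exceeds the absence cut (strict
#' >, default 35 cycles). Otherwise it is called *present* only when a
#' pooled two-sample t-test shows its C_T values significantly below the
#' no-template control at `alpha` (default 0.01, the strict level of the
#' purity assays). "Undetermined" wells (`NA`) are treated as the maximum
#' cycle count (40) for this comparison only.
#'
#' @param ct numeric C_T replicates of the assay; `NA` = Undetermined.
#' @param ntc C_T replicates of the no-template control; `NA` allowed.
#' @param cut absence cut on the mean C_T.
#' @param alpha significance level against the NTC.
#' @param max_cycles cycle ceiling substituted for Undetermined wells.
#' @return list with `call` (`"present"`/`"absent"`), `mean_ct`, `p`
#'   (NA when the absence cut already decides).
#' @export
presence_call <- function(ct, ntc, cut = 35, alpha = 0.01, max_cycles = 40) {
  if (length(ntc) == 0L) stop("no NTC replicates supplied")
  ct[is.na(ct)] <- max_cycles
  ntc[is.na(ntc)] <- max_cycles
  m <- mean(ct)
  if (m > cut)
    return(list(call = "absent", mean_ct = m, p = NA_real_))
  p <- tryCatch(
    stats::t.test(ct, ntc, var.equal = TRUE)$p.value,
    error = function(e) if (isTRUE(all.equal(mean(ct), mean(ntc)))) 1 else 0)
  list(call = if (p < alpha && m < mean(ntc)) "present" else "absent",
       mean_ct = m, p = p)
}

#' Rank housekeeping-gene candidates by cross-condition stability
#'
#' For each candidate reference gene, runs pooled two-sample t-tests on its
#' C_T values between every pair of conditions. A candidate is *stable*
#' iff no pair differs at `alpha`; among stable candidates the one with the
#' smallest maximum |t| is chosen. If none is stable, the least unstable
#' candidate (largest minimum p) is returned with a warning.
#'
#' @param ct_by_condition named list: candidate -> named list of numeric
#'   C_T replicate vectors per condition (>= 2 conditions, >= 2 replicates
#'   each).
#' @param alpha instability level (default 0.05).
#' @return list with `ranking` (data.frame `candidate`, `min_p`, `max_t`,
#'   `stable`) and `chosen` (candidate name).
#' @export
housekeeping_stability <- function(ct_by_condition, alpha = 0.05) {
  score <- function(conds) {
    if (length(conds) < 2L) stop("need >= 2 conditions per candidate")
    if (any(lengths(conds) < 2L)) stop("need >= 2 replicates per condition")
    combs <- utils::combn(length(conds), 2L)
    stats_ <- apply(combs, 2L, function(ij) {
      a <- conds[[ij[1L]]]; b <- conds[[ij[2L]]]
      r <- two_sample_t_summary(mean(a), stats::sd(a), length(a),
                                mean(b), stats::sd(b), length(b))
      c(p = r$p, t = abs(r$t))
    })
    c(min_p = min(stats_["p", ]), max_t = max(stats_["t", ]))
  }
  sc <- t(vapply(ct_by_condition, score, numeric(2L)))
  ranking <- data.frame(candidate = rownames(sc), min_p = sc[, "min_p"],
                        max_t = sc[, "max_t"],
                        stable = sc[, "min_p"] >= alpha,
                        stringsAsFactors = FALSE, row.names = NULL)
  ranking <- ranking[order(!ranking$stable, ranking$max_t), , drop = FALSE]
  rownames(ranking) <- NULL
  if (!any(ranking$stable)) {
    warning("no stable housekeeping candidate; returning least unstable")
    chosen <- ranking$candidate[which.max(ranking$min_p)]
  } else {
    chosen <- ranking$candidate[1L]
  }
  list(ranking = ranking, chosen = chosen)
}
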
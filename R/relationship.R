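#' Per-condition mRNA-lncRNA sign concordance
#'
#' Within one condition, an mRNA-lncRNA pair is `synergistic` when the two
#' Pearson trend coefficients carry the same defined sign, `inverse` when
#' they carry opposite defined signs, and `undefined` when either sign is
#' indeterminate. A sign is + when R >= tau, - when R <= -tau, and
#' indeterminate when |R| < tau; tau defaults to 0.1 (see the methods
#' vignette for how this value is pinned down by the published labels).
#'
#' @param r_mrna,r_lnc Pearson coefficients (vectorized); `NA` propagates
#'   to an `undefined` verdict.
#' @param tau sign threshold, >= 0. With `tau = 0`, sign(0) counts as +.
#' @return character vector in `{"synergistic", "inverse", "undefined"}`.
#' @export
condition_relationship <- function(r_mrna, r_lnc, tau = 0.1) {
  if (tau < 0) stop("'tau' must be >= 0")
  sgn <- function(x) {
    ifelse(is.na(x), NA_integer_,
           ifelse(x >= tau, 1L, ifelse(x <= -tau, -1L, NA_integer_)))
  }
  s1 <- sgn(r_mrna)
  s2 <- sgn(r_lnc)
  ifelse(is.na(s1) | is.na(s2), "undefined",
         ifelse(s1 == s2, "synergistic", "inverse"))
}

#' Cross-condition relationship label
#'
#' The final label of a pair: `synergistic` when both condition verdicts
#' are synergistic, `inverse` when both are inverse, `inconclusive` for any
#' mixed or undefined combination.
#'
#' @param maturation,injury verdicts from [condition_relationship()]
#'   (vectorized).
#' @return character vector in
#'   `{"synergistic", "inverse", "inconclusive"}`.
#' @export
final_relationship <- function(maturation, injury) {
  ifelse(maturation == "synergistic" & injury == "synergistic", "synergistic",
         ifelse(maturation == "inverse" & injury == "inverse", "inverse",
                "inconclusive"))
}

#' Classify a table of mRNA-lncRNA pairs
#'
#' Convenience wrapper applying [condition_relationship()] per condition
#' and [final_relationship()] across conditions to a pair table. The R
#' columns may come straight from published tables or from
#' [pearson_trend()]; both routes share this classifier.
#'
#' @param pairs data.frame with columns `gene`, `mrna`, `lncrna`,
#'   `r_mrna_maturation`, `r_lnc_maturation`, `r_mrna_injury`,
#'   `r_lnc_injury`.
#' @param tau sign threshold, see [condition_relationship()].
#' @return the input with added `verdict_maturation`, `verdict_injury`
#'   and `final` columns, plus a `tau` attribute.
#' @export
classify_pairs <- function(pairs, tau = 0.1) {
  need <- c("gene", "mrna", "lncrna", "r_mrna_maturation",
            "r_lnc_maturation", "r_mrna_injury", "r_lnc_injury")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing pair column: ", miss[1L])
  pairs$verdict_maturation <- condition_relationship(
    pairs$r_mrna_maturation, pairs$r_lnc_maturation, tau)
  pairs$verdict_injury <- condition_relationship(
    pairs$r_mrna_injury, pairs$r_lnc_injury, tau)
  pairs$final <- final_relationship(pairs$verdict_maturation,
                                    pairs$verdict_injury)
  attr(pairs, "tau") <- tau
  pairs
}

#' Genes with at least one conclusive mRNA-lncRNA pair
#'
#' A gene is eligible for the downstream miRNA mapping iff at least one of
#' its classified pairs carries a non-inconclusive (inverse or synergistic)
#' final label.
#'
#' @param pairs data.frame with columns `gene` and `final` (e.g. from
#'   [classify_pairs()]).
#' @return sorted character vector of eligible gene symbols.
#' @export
eligible_genes <- function(pairs) {
  keep <- pairs$final != "inconclusive"
  sort(unique(pairs$gene[keep]))
}
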
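# Accessors for the published reference values shipped with the package
# (GSE44834 neuronal maturation / OGD study): the OGD expression profiles
# of the 11 shortlisted genes and their lncRNAs, the culture-purity qPCR
# C_T values, the enriched maturation pathways, and the genome-wide
# detection/DE counts used for report arithmetic.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "trioma")
  if (!nzchar(path)) stop("reference file not installed: ", file)
  path
}

#' Published OGD expression profiles of the shortlisted genes
#'
#' One row per transcript (11 mRNAs, 14 associated lncRNAs): SLR mean/SD at
#' 2 h and 4 h of OGD relative to the 0 h control, the printed significance
#' marks (hash marks from the 2 h vs 4 h comparison; stars from the
#' one-sample test on the OGD SLRs), the Pearson trend coefficients under
#' maturation and injury, the lncRNA genomic orientation and the published
#' mRNA-lncRNA relationship label. Empty marks/fields are ".".
#'
#' @return data.frame, one row per transcript.
#' @export
ogd_reference <- function() {
  utils::read.delim(.extdata("ogd_profiles.tsv"), stringsAsFactors = FALSE)
}

#' Published mRNA-lncRNA pairs with their trend coefficients
#'
#' Reshapes [ogd_reference()] into the 14-row pair table consumed by
#' [classify_pairs()]: each associated lncRNA paired with its gene's mRNA,
#' with the published maturation and injury Pearson coefficients.
#'
#' @return data.frame with columns `gene`, `mrna`, `lncrna`,
#'   `r_mrna_maturation`, `r_lnc_maturation`, `r_mrna_injury`,
#'   `r_lnc_injury`, `published_label`.
#' @export
ogd_reference_pairs <- function() {
  df <- ogd_reference()
  m <- df[df$type == "mRNA", ]
  l <- df[df$type == "lncRNA", ]
  i <- match(l$gene, m$gene)
  data.frame(gene = l$gene, mrna = m$transcript[i], lncrna = l$transcript,
             r_mrna_maturation = m$r_maturation[i],
             r_lnc_maturation = l$r_maturation,
             r_mrna_injury = m$r_injury[i],
             r_lnc_injury = l$r_injury,
             published_label = l$relationship,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Culture-purity qPCR C_T reference values
#'
#' Mean +/- SD cycle thresholds of miR-124 (neuron-specific), miR-143
#' (astrocyte-enriched) and miR-223 (glia-enriched) in neuronal cultures,
#' OGD samples, an astrocyte-enriched culture and the no-template controls.
#'
#' @return data.frame with `assay`, `sample`, `group`, `mean_ct`, `sd_ct`.
#' @export
marker_ct_reference <- function() {
  utils::read.delim(.extdata("marker_ct.tsv"), stringsAsFactors = FALSE)
}

#' Enriched maturation pathways and their member genes
#'
#' Long-format pathway membership for the dual-DE gene list, with the
#' published enrichment p-value and a flag marking the genes that are
#' predicted targets of the differentially expressed miRNAs.
#'
#' @return data.frame with `pathway`, `p_value`, `gene`, `mirna_target`.
#' @export
maturation_pathways <- function() {
  utils::read.delim(.extdata("maturation_pathways.tsv"),
                    stringsAsFactors = FALSE)
}

#' Genome-wide detection and differential-expression counts
#'
#' The array-scale counts of the profiled study, used for report
#' arithmetic: probes/transcripts detected per channel and how many of the
#' detected ones were differentially expressed.
#'
#' @return named list of `c(count, total)` pairs.
#' @export
profiling_counts <- function() {
  list(detection = list(miRNA = c(395, 1040)),
       differential = list(mRNA = c(6965, 14213),
                           lncRNA = c(7455, 15715)))
}

#' Reference gene shortlists of the cascade
#'
#' The funnel stages: the 23 pathway genes that are predicted miRNA
#' targets, the 11 of them differentially expressed in the mature phenotype
#' (Days 6 and 8), the 7 with a conclusive mRNA-lncRNA relationship, and
#' the 10 network miRNAs targeting 2 or more of the 7.
#'
#' @return list with `pathway_mirna_targets`, `mature_phenotype`,
#'   `conclusive_relationship`, `network_mirnas`.
#' @export
shortlist_reference <- function() {
  paths <- maturation_pathways()
  list(
    pathway_mirna_targets = sort(unique(paths$gene[paths$mirna_target])),
    mature_phenotype = sort(c("Axin2", "Igf1r", "Ikbkb", "Prkcb", "Ralgds",
                              "Cntn1", "Ncam1", "Negr1", "Nrxn1", "Ntrk2",
                              "Sh2b3")),
    conclusive_relationship = sort(c("Axin2", "Prkcb", "Cntn1", "Ncam1",
                                     "Negr1", "Nrxn1", "Sh2b3")),
    network_mirnas = c("miR-124", "miR-128", "miR-129-5p", "miR-203",
                       "miR-218", "miR-290-5p", "miR-326", "miR-329",
                       "miR-377", "miR-495"))
}
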
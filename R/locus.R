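#' Classify a lncRNA locus by genomic orientation
#'
#' Places a lncRNA locus into the orientation taxonomy used for associated
#' genes:
#' \describe{
#'   \item{sense / antisense overlap}{the locus shares at least one base
#'     with a coding transcript span, on the same / opposite strand;}
#'   \item{bidirectional}{no transcript overlap, but a coding gene on the
#'     opposite strand has its TSS within `window` bp of the lncRNA's TSS
#'     with the two transcripts pointing away from each other
#'     (head-to-head divergent);}
#'   \item{intergenic}{none of the above.}
#' }
#' A locus that overlaps only the promoter (the `promoter_bp` bases
#' upstream of the TSS, strand-aware) is classed as sense/antisense
#' overlap with sub-region `promoter`; bidirectional takes precedence for
#' opposite-strand divergent loci, so promoter-only overlap is effectively
#' a same-strand or convergent configuration.
#'
#' Sub-regions for transcript overlaps: `three_prime_UTR` when the overlap
#' is confined to the 3' UTR, `exon` when only exons are touched, `intron`
#' when only introns are touched (`first_intron` when the only intron
#' touched is intron 1 in transcription order), `intron_exon` when both.
#'
#' The nearest qualifying gene wins (transcript overlap at distance 0,
#' promoter overlap at the gap to the transcript span, bidirectional at the
#' TSS-to-TSS gap); ties are broken by the lexicographically smaller gene
#' id.
#'
#' @param lnc an [lnc_locus()].
#' @param genes a `gene_models` collection (or list of [gene_model()]).
#' @param window bidirectional TSS-to-TSS window in bp (default 1000).
#' @param promoter_bp promoter extent upstream of the TSS (default 1000).
#' @return list of class `locus_relation` with fields `lnc_id`, `gene_id`
#'   (`""` if intergenic), `category`, `subregion`, `distance_bp`.
#' @export
classify_locus <- function(lnc, genes, window = 1000, promoter_bp = 1000) {
  stopifnot(inherits(lnc, "lnc_locus"))
  best <- NULL
  for (g in genes) {
    if (g$chrom != lnc$chrom) next
    if (is.null(g$tss)) stop("gene model lacking TSS: ", g$id)
    cand <- .relate_one(lnc, g, window, promoter_bp)
    if (is.null(cand)) next
    if (is.null(best) ||
        cand$rank < best$rank ||
        (cand$rank == best$rank && cand$distance_bp < best$distance_bp) ||
        (cand$rank == best$rank && cand$distance_bp == best$distance_bp &&
         cand$gene_id < best$gene_id)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(lnc_id = lnc$id, gene_id = "", category = "intergenic",
                 subregion = "none", distance_bp = NA_real_)
  } else {
    best$rank <- NULL
  }
  structure(best, class = "locus_relation")
}

# One lncRNA against one gene. Returns NULL when no relation qualifies.
# rank: 1 transcript overlap, 2 bidirectional, 3 promoter-only overlap.
.relate_one <- function(lnc, g, window, promoter_bp) {
  ov <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
  tx_ov <- ov(lnc$start, lnc$end, g$start, g$end)
  same <- lnc$strand == g$strand
  cat_by_strand <- if (same) "sense_overlap" else "antisense_overlap"
  if (tx_ov > 0) {
    return(list(lnc_id = lnc$id, gene_id = g$id, category = cat_by_strand,
                subregion = .overlap_subregion(lnc, g), distance_bp = 0,
                rank = 1L))
  }
  # head-to-head divergent within the window, opposite strands, no overlap
  if (!same) {
    gap <- abs(lnc$tss - g$tss)
    divergent <- (g$strand == "+" && lnc$tss <= g$tss) ||
                 (g$strand == "-" && lnc$tss >= g$tss)
    if (divergent && gap <= window) {
      return(list(lnc_id = lnc$id, gene_id = g$id, category = "bidirectional",
                  subregion = "none", distance_bp = gap, rank = 2L))
    }
  }
  prom <- .promoter_interval(g, promoter_bp)
  if (ov(lnc$start, lnc$end, prom[1L], prom[2L]) > 0) {
    gap_tx <- max(g$start - lnc$end, lnc$start - g$end, 0)
    return(list(lnc_id = lnc$id, gene_id = g$id, category = cat_by_strand,
                subregion = "promoter", distance_bp = gap_tx, rank = 3L))
  }
  NULL
}

.promoter_interval <- function(g, promoter_bp) {
  if (g$strand == "+") c(g$start - promoter_bp, g$start)
  else c(g$end, g$end + promoter_bp)
}

# Sub-region of a transcript-span overlap, from the parts the lncRNA
# interval touches. 3' UTR containment is checked first.
.overlap_subregion <- function(lnc, g) {
  ov <- function(b) max(0, min(lnc$end, b[2L]) - max(lnc$start, b[1L]))
  lo <- max(lnc$start, g$start)
  hi <- min(lnc$end, g$end)
  if (!is.null(g$utr3) && lo >= g$utr3[1L] && hi <= g$utr3[2L])
    return("three_prime_UTR")
  exons <- g$exons
  exon_hit <- any(apply(exons, 1L, ov) > 0)
  introns <- if (nrow(exons) > 1L)
    cbind(exons[-nrow(exons), 2L], exons[-1L, 1L]) else
    matrix(numeric(), ncol = 2L)
  intron_hits <- if (nrow(introns)) which(apply(introns, 1L, ov) > 0) else integer()
  if (exon_hit && length(intron_hits)) return("intron_exon")
  if (exon_hit) return("exon")
  if (length(intron_hits)) {
    # intron 1 in transcription order: leftmost gap on +, rightmost on -
    first <- if (g$strand == "+") 1L else nrow(introns)
    if (identical(intron_hits, first)) return("first_intron")
    return("intron")
  }
  "none"
}

#' Classify many lncRNA loci at once
#'
#' @param lncs list of [lnc_locus()] objects.
#' @inheritParams classify_locus
#' @return data.frame with one row per locus: `lnc_id`, `gene_id`,
#'   `category`, `subregion`, `distance_bp`.
#' @export
classify_loci <- function(lncs, genes, window = 1000, promoter_bp = 1000) {
  rel <- lapply(lncs, classify_locus, genes = genes, window = window,
                promoter_bp = promoter_bp)
  data.frame(lnc_id = vapply(rel, `[[`, character(1L), "lnc_id"),
             gene_id = vapply(rel, `[[`, character(1L), "gene_id"),
             category = vapply(rel, `[[`, character(1L), "category"),
             subregion = vapply(rel, `[[`, character(1L), "subregion"),
             distance_bp = vapply(rel, `[[`, numeric(1L), "distance_bp"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene associations and orientation census of classified loci
#'
#' Non-intergenic loci are associated with their gene; the census gives the
#' percentage of each orientation class over a chosen subset of loci
#' (typically the differentially expressed ones).
#'
#' @param relations data.frame from [classify_loci()].
#' @param subset optional character vector of lncRNA ids to census over;
#'   defaults to all classified loci.
#' @return list with `associations` (data.frame `lnc_id`, `gene_id`,
#'   `category`, `subregion`) and `census` (data.frame `category`, `n`,
#'   `percent`, percentages rounded to 1 dp).
#' @export
associate_lnc_genes <- function(relations, subset = NULL) {
  assoc <- relations[relations$category != "intergenic",
                     c("lnc_id", "gene_id", "category", "subregion")]
  rownames(assoc) <- NULL
  cats <- c("intergenic", "antisense_overlap", "sense_overlap", "bidirectional")
  sel <- if (is.null(subset)) relations else
    relations[relations$lnc_id %in% subset, , drop = FALSE]
  if (nrow(sel) == 0L) {
    census <- data.frame(category = character(), n = integer(),
                         percent = numeric(), stringsAsFactors = FALSE)
  } else {
    n <- vapply(cats, function(cc) sum(sel$category == cc), integer(1L))
    census <- data.frame(category = cats, n = n,
                         percent = round(100 * n / nrow(sel), 1),
                         stringsAsFactors = FALSE, row.names = NULL)
  }
  list(associations = assoc, census = census)
}
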
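#' Genes with both a differentially expressed mRNA and lncRNA
#'
#' First stage of the shortlisting cascade: keep genes whose mRNA is
#' differentially expressed and which have at least one associated,
#' differentially expressed lncRNA.
#'
#' @param mrna_de character vector of gene symbols whose mRNA is DE, or a
#'   [call_differential()] data.frame together with `mrna_annotation`.
#' @param lnc_de character vector of DE lncRNA ids, or a
#'   [call_differential()] data.frame (its DE probe ids are taken as
#'   lncRNA ids).
#' @param associations data.frame with columns `lnc_id` and `gene_id`
#'   (from [associate_lnc_genes()] or a vendor annotation table).
#' @param mrna_annotation optional data.frame `probe_id` -> `gene` used to
#'   translate a probe-level mRNA call table to gene symbols.
#' @return sorted character vector of dual-DE gene symbols.
#' @export
shortlist_dual_de <- function(mrna_de, lnc_de, associations,
                              mrna_annotation = NULL) {
  if (is.data.frame(mrna_de)) {
    if (is.null(mrna_annotation))
      stop("probe-level mRNA calls need 'mrna_annotation' (probe_id -> gene)")
    probes <- mrna_de$probe_id[mrna_de$is_de]
    mrna_de <- mrna_annotation$gene[match(probes, mrna_annotation$probe_id)]
  }
  if (is.data.frame(lnc_de)) lnc_de <- lnc_de$probe_id[lnc_de$is_de]
  de_assoc <- associations[associations$lnc_id %in% lnc_de, , drop = FALSE]
  sort(unique(intersect(unique(mrna_de), unique(de_assoc$gene_id))))
}

#' Hypergeometric / EASE pathway enrichment
#'
#' One-sided upper-tail hypergeometric p-value per gene set for the overlap
#' between a gene list and each set, over the collection's universe. The
#' EASE variant (default) removes one gene from the overlap before taking
#' the tail — the conservative score used by annotation servers; an
#' overlap of 0 then scores p = 1.
#'
#' @param genes character vector of gene symbols, a subset of the universe.
#' @param sets a [gene_sets()] collection.
#' @param method `"ease"` (default) or `"fisher"` (plain hypergeometric).
#' @return data.frame sorted by p: `set`, `overlap`, `list_size`,
#'   `set_size`, `universe_size`, `p`.
#' @export
enrich_pathways <- function(genes, sets, method = c("ease", "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "gene_sets"))
  N <- length(sets$universe)
  if (N == 0L) stop("empty universe")
  outside <- setdiff(genes, sets$universe)
  if (length(outside))
    stop("gene outside universe: ", outside[1L])
  genes <- unique(genes)
  n <- length(genes)
  res <- lapply(names(sets$sets), function(nm) {
    s <- sets$sets[[nm]]
    k <- length(intersect(genes, s))
    K <- length(s)
    k_eff <- if (method == "ease") max(k - 1L, 0L) else k
    p <- if (method == "ease" && k == 0L) 1 else
      stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, list_size = n, set_size = K,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes targeted by differentially expressed miRNAs
#'
#' @param genes candidate gene symbols.
#' @param targets a [target_table()].
#' @param de_mirnas ids of the differentially expressed miRNAs.
#' @return sorted subset of `genes` with at least one (DE miRNA -> gene)
#'   target row.
#' @export
intersect_mirna_targets <- function(genes, targets, de_mirnas) {
  hit <- targets$gene[targets$mirna %in% de_mirnas]
  sort(intersect(unique(genes), unique(hit)))
}

#' Keep genes differentially expressed in the mature phenotype
#'
#' Retains genes whose mRNA |SLR| exceeds the cut on the late-maturation
#' days (Days 6 and 8). `mode = "both"` (default) requires the cut on both
#' days; `"either"` on at least one.
#'
#' @param genes candidate gene symbols.
#' @param slr `slr_matrix` of the maturation condition with rows named by
#'   gene symbol (collapse probe-level rows first).
#' @param days numeric days that define the mature phenotype.
#' @param cut positive |SLR| threshold (strict inequality).
#' @param mode `"both"` or `"either"`.
#' @return sorted subset of `genes`.
#' @export
mature_phenotype_filter <- function(genes, slr, days = c(6, 8), cut = 1.0,
                                    mode = c("both", "either")) {
  mode <- match.arg(mode)
  tp <- slr_timepoints(slr)
  cols <- names(tp)[tp %in% days]
  if (length(cols) != length(days))
    stop("day missing from SLR matrix: ",
         paste(setdiff(days, tp), collapse = ", "))
  present <- intersect(genes, rownames(slr))
  hit <- abs(unclass(slr)[present, cols, drop = FALSE]) > cut
  keep <- if (mode == "both") apply(hit, 1L, all) else apply(hit, 1L, any)
  sort(present[keep])
}

#' miRNAs targeting at least k eligible genes
#'
#' Maps the differentially expressed miRNAs to those predicted or validated
#' to target `k` or more distinct eligible genes.
#'
#' @param genes eligible gene symbols.
#' @param targets a [target_table()] (already restricted to the miRNAs of
#'   interest, e.g. the DE set).
#' @param k minimum number of distinct eligible genes (default 2).
#' @return sorted character vector of miRNA ids.
#' @export
map_mirnas_min_genes <- function(genes, targets, k = 2L) {
  rel <- targets[targets$gene %in% genes, , drop = FALSE]
  counts <- tapply(rel$gene, rel$mirna, function(g) length(unique(g)))
  sort(names(counts)[counts >= k])
}

#' Assemble the integrated mRNA-lncRNA-miRNA regulatory network
#'
#' Builds the typed node/edge lists of the final network: mRNA nodes for
#' the eligible genes, lncRNA nodes joined by `relationship` edges
#' (synergistic rendered as a feedback arrow, inverse as inhibitory) and by
#' their genomic `association` class, and miRNA nodes joined by `targeting`
#' edges (validated vs predicted).
#'
#' @param genes eligible gene symbols (mRNA nodes).
#' @param pairs classified pair table from [classify_pairs()]; rows with a
#'   conclusive final label and a gene in `genes` become relationship
#'   edges.
#' @param relations locus classification data.frame (from
#'   [classify_loci()] or an annotation table) providing each lncRNA's
#'   orientation class; may be `NULL`.
#' @param targets [target_table()] rows define targeting edges for miRNAs
#'   in `mirnas` against `genes`.
#' @param mirnas miRNA ids to include (e.g. from
#'   [map_mirnas_min_genes()]).
#' @param directions optional data.frame `id`, `maturation`, `injury`
#'   giving per-node expression direction annotations.
#' @return list of class `regulatory_network` with `nodes` (`id`, `type`,
#'   optional direction columns) and `edges` (`from`, `to`, `type`,
#'   `subtype`).
#' @export
build_network <- function(genes, pairs, relations = NULL, targets = NULL,
                          mirnas = character(), directions = NULL) {
  rel_rows <- pairs[pairs$gene %in% genes & pairs$final != "inconclusive", ,
                    drop = FALSE]
  lnc_ids <- unique(rel_rows$lncrna)
  tgt_rows <- if (is.null(targets)) NULL else
    targets[targets$mirna %in% mirnas & targets$gene %in% genes, , drop = FALSE]
  mir_ids <- if (is.null(tgt_rows)) character() else unique(tgt_rows$mirna)

  nodes <- data.frame(
    id = c(genes, lnc_ids, mir_ids),
    type = c(rep("mRNA", length(genes)), rep("lncRNA", length(lnc_ids)),
             rep("miRNA", length(mir_ids))),
    stringsAsFactors = FALSE)
  if (!is.null(directions)) {
    nodes$maturation <- directions$maturation[match(nodes$id, directions$id)]
    nodes$injury <- directions$injury[match(nodes$id, directions$id)]
  }

  edges <- data.frame(from = character(), to = character(),
                      type = character(), subtype = character(),
                      stringsAsFactors = FALSE)
  if (nrow(rel_rows)) {
    edges <- rbind(edges, data.frame(
      from = rel_rows$lncrna, to = rel_rows$gene, type = "relationship",
      subtype = rel_rows$final, stringsAsFactors = FALSE))
    if (!is.null(relations)) {
      m <- match(rel_rows$lncrna, relations$lnc_id)
      orient <- relations$category[m]
      ok <- !is.na(orient) & orient != "intergenic"
      if (any(ok)) {
        edges <- rbind(edges, data.frame(
          from = rel_rows$lncrna[ok], to = rel_rows$gene[ok],
          type = "association",
          subtype = sub("_overlap$", "", orient[ok]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(tgt_rows) && nrow(tgt_rows)) {
    edges <- rbind(edges, data.frame(
      from = tgt_rows$mirna, to = tgt_rows$gene, type = "targeting",
      subtype = tgt_rows$evidence, stringsAsFactors = FALSE))
  }
  dangling <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(dangling)) stop("dangling network reference: ", dangling[1L])
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes),
              paste(names(table(x$nodes$type)),
                    table(x$nodes$type), sep = ":", collapse = " "),
              nrow(x$edges),
              if (nrow(x$edges)) paste(names(table(x$edges$type)),
                                       table(x$edges$type), sep = ":",
                                       collapse = " ") else "none"))
  invisible(x)
}

#' Export a regulatory network
#'
#' @param net a [build_network()] result.
#' @param tsv optional path for a tab-delimited edge list.
#' @param json optional path for a JSON dump of nodes and edges.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(net$edges, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(nodes = net$nodes, edges = net$edges), json,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' Percentage rounded to one decimal place
#'
#' The report convention for detection and DE rates, e.g. 395 of 1040
#' probes -> 38.0.
#'
#' @param x count.
#' @param n total.
#' @return numeric percentage rounded to 1 dp.
#' @export
pct1 <- function(x, n) round(100 * x / n, 1)

#' Stage-by-stage summary report
#'
#' Collates detection and differential-expression counts per channel (with
#' percentages at 1 dp), the lncRNA orientation census and the shortlist
#' funnel into one report object.
#'
#' @param detected named list/vector: per channel, `c(count, total)` for
#'   detection.
#' @param de named list: per channel, `c(count, total)` for differential
#'   expression among the detected probes.
#' @param census optional orientation census data.frame (from
#'   [associate_lnc_genes()]).
#' @param funnel optional named integer vector of cascade stage sizes
#'   (monotone non-increasing).
#' @return list of class `trioma_report` with `detection` and
#'   `differential` data.frames carrying `percent` columns.
#' @export
summary_report <- function(detected = NULL, de = NULL, census = NULL,
                           funnel = NULL) {
  tab <- function(lst) {
    if (is.null(lst)) return(NULL)
    data.frame(channel = names(lst),
               count = vapply(lst, `[[`, numeric(1L), 1L),
               total = vapply(lst, `[[`, numeric(1L), 2L),
               percent = vapply(lst, function(v) pct1(v[[1L]], v[[2L]]),
                                numeric(1L)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(detection = tab(detected), differential = tab(de),
                 census = census, funnel = funnel),
            class = "trioma_report")
}

#' @export
print.trioma_report <- function(x, ...) {
  if (!is.null(x$detection)) {
    cat("Detection:\n")
    print(x$detection)
  }
  if (!is.null(x$differential)) {
    cat("Differential expression:\n")
    print(x$differential)
  }
  if (!is.null(x$census)) {
    cat("lncRNA orientation census:\n")
    print(x$census)
  }
  if (!is.null(x$funnel)) {
    cat("Shortlist funnel: ",
        paste(names(x$funnel), x$funnel, sep = "=", collapse = " -> "), "\n")
  }
  invisible(x)
}
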
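#' Construct an expression matrix for one channel
#'
#' The basic container of the pipeline: a probe x sample matrix of
#' linear-scale, non-negative intensities for one of the three array
#' channels (mRNA, lncRNA or miRNA).
#'
#' @param values numeric matrix with probe ids as rownames and sample ids as
#'   colnames. All values must be finite; raw intensities must be >= 0.
#' @param channel one of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param allow_negative logical; post-normalization matrices (e.g. after
#'   control scaling) may carry values below zero on the linear scale only
#'   when this is set. Raw readers always validate non-negativity.
#' @return a matrix of class `expr_matrix` with a `channel` attribute.
#' @export
expression_matrix <- function(values, channel = c("mRNA", "lncRNA", "miRNA"),
                              allow_negative = FALSE) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs probe ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         rownames(values)[anyDuplicated(rownames(values))])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[anyDuplicated(colnames(values))])
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (!allow_negative && any(values < 0))
    stop("raw intensities must be non-negative")
  structure(values, channel = channel,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> channel=%s, %d probes x %d samples\n",
              attr(x, "channel"), nrow(x), ncol(x)))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Channel of an expression matrix
#' @param x an `expr_matrix`.
#' @return character scalar.
#' @export
channel <- function(x) attr(x, "channel")

#' Read a tab-delimited expression table
#'
#' Expects a header row; the first column holds probe ids and the remaining
#' named columns hold numeric intensities, one column per sample.
#'
#' @param path path to a tab-delimited text file.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, channel = c("mRNA", "lncRNA", "miRNA")) {
  channel <- match.arg(channel)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed expression table: ", path)
  probes <- df[[1L]]
  if (anyDuplicated(probes))
    stop("duplicate probe id in ", path, ": ",
         probes[duplicated(probes)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                 path, bad[["row"]], colnames(vals)[bad[["col"]]]))
  }
  rownames(num) <- probes
  expression_matrix(num, channel)
}

#' Write an expression matrix as a tab-delimited table
#'
#' @param x an `expr_matrix` (or plain named matrix).
#' @param path output path.
#' @param id_column header of the probe-id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "probe_id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Describe the samples of one experimental condition
#'
#' The study has two conditions: neuronal maturation (samples at days
#' 2/4/6/8, baseline Day 2) and OGD ischemic injury (samples at 0/2/4 h of
#' oxygen-glucose deprivation, baseline 0 h). The baseline sample anchors
#' the Signal Log Ratios of [compute_slr()].
#'
#' @param samples character vector of sample ids, in timepoint order.
#' @param timepoints numeric coordinates (days or hours), strictly
#'   increasing, same length as `samples`.
#' @param condition `"maturation"` or `"OGD"`.
#' @param baseline the baseline sample id; defaults to the first sample.
#' @return a list of class `sample_design`.
#' @export
sample_design <- function(samples, timepoints,
                          condition = c("maturation", "OGD"),
                          baseline = samples[1L]) {
  condition <- match.arg(condition)
  if (length(samples) != length(timepoints))
    stop("'samples' and 'timepoints' must have equal length")
  if (anyDuplicated(samples)) stop("duplicate sample id in design")
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (sum(samples == baseline) != 1L)
    stop("exactly one baseline sample required; not found: ", baseline)
  structure(list(samples = as.character(samples),
                 timepoints = as.numeric(timepoints),
                 condition = condition,
                 baseline = as.character(baseline)),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  unit <- if (x$condition == "maturation") "day" else "hr"
  cat(sprintf("<sample_design> %s: %s (baseline %s)\n", x$condition,
              paste0(x$samples, "=", x$timepoints, unit, collapse = ", "),
              x$baseline))
  invisible(x)
}

# ---- gene models and lncRNA loci -------------------------------------------
# Internal coordinates are 0-based half-open throughout; conversion from the
# 1-based inclusive GFF3 convention happens only at the I/O boundary.

#' Construct a coding-gene model
#'
#' @param id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end transcript interval, 0-based half-open.
#' @param exons two-column integer matrix (start, end) of exon intervals,
#'   0-based half-open; must be sorted, non-overlapping and contained in the
#'   transcript interval.
#' @param utr3 optional c(start, end) of the 3' UTR, or `NULL`.
#' @param symbol gene symbol; defaults to `id`.
#' @return list of class `gene_model`, with the TSS derived per strand
#'   (transcript start on `+`, `end - 1` on `-`).
#' @export
gene_model <- function(id, chrom, strand, start, end, exons,
                       utr3 = NULL, symbol = id) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  if (end <= start) stop("empty transcript interval for gene ", id)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("empty exon in gene ", id)
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end))
    stop("exon outside transcript span in gene ", id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in gene ", id)
  structure(list(id = id, symbol = symbol, chrom = chrom, strand = strand,
                 start = as.numeric(start), end = as.numeric(end),
                 exons = exons, utr3 = utr3,
                 tss = if (strand == "+") as.numeric(start) else as.numeric(end) - 1),
            class = "gene_model")
}

#' Construct a lncRNA locus
#'
#' @param id lncRNA accession.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end locus interval, 0-based half-open, non-empty.
#' @param ultraconserved optional annotation flag.
#' @return list of class `lnc_locus`. TSS is strand-derived as for genes.
#' @export
lnc_locus <- function(id, chrom, strand, start, end, ultraconserved = FALSE) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  if (end <= start) stop("empty lncRNA interval: ", id)
  structure(list(id = id, chrom = chrom, strand = strand,
                 start = as.numeric(start), end = as.numeric(end),
                 tss = if (strand == "+") as.numeric(start) else as.numeric(end) - 1,
                 ultraconserved = isTRUE(ultraconserved)),
            class = "lnc_locus")
}

#' Read coding-gene models from GFF3 or BED12
#'
#' GFF3 files are expected to carry gene/mRNA/exon/three_prime_UTR features
#' linked by ID/Parent attributes (one transcript per gene); BED12 blocks
#' become exons and the 3' end outside `thick` becomes the 3' UTR. Parsing
#' is delegated to [rtracklayer::import()]; coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return named list of [gene_model()] objects, class `gene_models`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  models <- if (format == "gff3") .genes_from_gff3(path) else .genes_from_bed12(path)
  structure(models, class = "gene_models")
}

.genes_from_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  # resolve each feature to its top-level gene id
  tx_parent <- stats::setNames(parent[type %in% c("mRNA", "transcript")],
                               ids[type %in% c("mRNA", "transcript")])
  to_gene <- function(i) {
    p <- parent[i]
    if (!is.na(p) && p %in% names(tx_parent)) tx_parent[[p]] else p
  }
  gene_idx <- which(type == "gene")
  out <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    strand <- as.character(BiocGenerics::strand(gr))[gi]
    if (!strand %in% c("+", "-")) stop("unknown strand for gene ", gid)
    g_start <- BiocGenerics::start(gr)[gi] - 1L   # 1-based incl. -> 0-based half-open
    g_end <- BiocGenerics::end(gr)[gi]
    member <- vapply(seq_along(gr), function(i)
      identical(to_gene(i), gid), logical(1L))
    ex <- which(type == "exon" & member)
    if (length(ex) == 0L) {
      exons <- cbind(g_start, g_end)
    } else {
      exons <- cbind(BiocGenerics::start(gr)[ex] - 1L, BiocGenerics::end(gr)[ex])
    }
    utr <- which(type == "three_prime_UTR" & member)
    utr3 <- if (length(utr))
      c(BiocGenerics::start(gr)[utr[1L]] - 1L, BiocGenerics::end(gr)[utr[1L]]) else NULL
    name <- if (!is.null(gr$Name) && !is.na(gr$Name[gi])) as.character(gr$Name[gi]) else gid
    out[[gid]] <- gene_model(gid, as.character(GenomicRanges::seqnames(gr))[gi],
                             strand, g_start, g_end, exons, utr3, symbol = name)
  }
  out
}

.genes_from_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- list()
  for (i in seq_along(gr)) {
    gid <- as.character(gr$name[i])
    strand <- as.character(BiocGenerics::strand(gr))[i]
    if (!strand %in% c("+", "-")) stop("unknown strand for record ", gid)
    g_start <- BiocGenerics::start(gr)[i] - 1L
    g_end <- BiocGenerics::end(gr)[i]
    blocks <- gr$blocks[[i]]
    exons <- if (length(blocks))
      cbind(g_start + BiocGenerics::start(blocks) - 1L,
            g_start + BiocGenerics::end(blocks))
    else cbind(g_start, g_end)
    utr3 <- NULL
    thick <- gr$thick[i]
    t_start <- BiocGenerics::start(thick) - 1L
    t_end <- BiocGenerics::end(thick)
    if (t_end > t_start) {  # thick = CDS; remainder on the 3' side is the UTR
      if (strand == "+" && t_end < g_end) utr3 <- c(t_end, g_end)
      if (strand == "-" && t_start > g_start) utr3 <- c(g_start, t_start)
    }
    out[[gid]] <- gene_model(gid, as.character(GenomicRanges::seqnames(gr))[i],
                             strand, g_start, g_end, exons, utr3)
  }
  out
}

#' Read lncRNA loci from a BED file
#'
#' BED6 is sufficient (chrom, start, end, name, score, strand); the score
#' column is ignored. An optional `ultraconserved` flag can be supplied
#' separately via annotation.
#'
#' @param path path to a BED file.
#' @return named list of [lnc_locus()] objects.
#' @export
read_lnc_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- list()
  for (i in seq_along(gr)) {
    out[[as.character(gr$name[i])]] <- lnc_locus(
      as.character(gr$name[i]),
      as.character(GenomicRanges::seqnames(gr))[i],
      as.character(BiocGenerics::strand(gr))[i],
      BiocGenerics::start(gr)[i] - 1L, BiocGenerics::end(gr)[i])
  }
  out
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (pathway name -> members).
#' @param universe background gene universe; defaults to the union of all
#'   sets. Members absent from a supplied universe are dropped.
#' @return list of class `gene_sets` with elements `sets` and `universe`.
#' @export
gene_sets <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(as.character(universe))
    sets <- lapply(sets, intersect, y = universe)
  }
  if (any(lengths(sets) == 0L))
    stop("empty gene set after universe restriction: ",
         names(sets)[lengths(sets) == 0L][1L])
  structure(list(sets = sets, universe = universe), class = "gene_sets")
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param path path to a `.gmt` file.
#' @inheritParams gene_sets
#' @return a [gene_sets()] collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with fewer than 3 fields at line ",
         which(lengths(fields) < 3L)[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  gene_sets(sets, universe)
}

#' Read a miRNA target table
#'
#' Expects tab-delimited columns `mirna`, `gene`, `evidence`, `source`.
#' Rows are deduplicated on (miRNA, gene); when a pair occurs with both
#' evidence levels, `validated` wins over `predicted`.
#'
#' @param path path to a tab-delimited file with a header row.
#' @return data.frame of class `target_table`.
#' @export
read_target_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("mirna", "gene", "evidence", "source")
  target_table(df)
}

#' Validate and deduplicate a target table
#'
#' @param df data.frame with columns `mirna`, `gene`, `evidence`
#'   (`"predicted"` or `"validated"`) and `source`.
#' @return deduplicated data.frame of class `target_table`.
#' @export
target_table <- function(df) {
  if (nrow(df) == 0L) {
    df <- data.frame(mirna = character(), gene = character(),
                     evidence = character(), source = character(),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("target_table", "data.frame")))
  }
  bad <- setdiff(unique(df$evidence), c("predicted", "validated"))
  if (length(bad))
    stop("evidence must be 'predicted' or 'validated'; found: ", bad[1L])
  # validated rows first so duplicated() keeps them
  df <- df[order(df$mirna, df$gene, df$evidence != "validated"), , drop = FALSE]
  df <- df[!duplicated(df[, c("mirna", "gene")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("target_table", "data.frame"))
}

#' Fixed analysis thresholds
#'
#' Bundles the study-wide constants: the differential-expression SLR cuts
#' (1.0 for mRNA/lncRNA, 0.6 for miRNA), the miRNA detection floor (mean
#' background-subtracted intensity 300), the bidirectional head-to-head
#' window (1000 bp), the sign threshold tau of the relationship classifier
#' (0.1), the minimum eligible genes per miRNA (2), the qPCR absence cut
#' (C_T 35) and the significance alpha levels (0.10, 0.05).
#'
#' @param slr_cut_mrna_lnc,slr_cut_mirna DE thresholds on |SLR|.
#' @param mirna_signal_floor miRNA detection floor (intensity units).
#' @param bidirectional_window_bp TSS-to-TSS window for bidirectional loci.
#' @param promoter_bp promoter extent upstream of the TSS.
#' @param sign_threshold tau of the sign-concordance classifier.
#' @param min_genes_per_mirna minimum distinct eligible genes a miRNA must
#'   target to enter the network.
#' @param ct_absent_cut qPCR cycle-threshold above which an assay is absent.
#' @param alphas significance levels, ordered loose to strict.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(slr_cut_mrna_lnc = 1.0, slr_cut_mirna = 0.6,
                            mirna_signal_floor = 300,
                            bidirectional_window_bp = 1000,
                            promoter_bp = 1000,
                            sign_threshold = 0.1,
                            min_genes_per_mirna = 2L,
                            ct_absent_cut = 35,
                            alphas = c(0.10, 0.05)) {
  vals <- c(slr_cut_mrna_lnc, slr_cut_mirna, mirna_signal_floor,
            bidirectional_window_bp, promoter_bp, min_genes_per_mirna,
            ct_absent_cut)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  if (sign_threshold < 0) stop("sign_threshold must be >= 0")
  if (any(diff(alphas) >= 0)) stop("alphas must be strictly decreasing")
  structure(list(slr_cut_mrna_lnc = slr_cut_mrna_lnc,
                 slr_cut_mirna = slr_cut_mirna,
                 mirna_signal_floor = mirna_signal_floor,
                 bidirectional_window_bp = bidirectional_window_bp,
                 promoter_bp = promoter_bp,
                 sign_threshold = sign_threshold,
                 min_genes_per_mirna = as.integer(min_genes_per_mirna),
                 ct_absent_cut = ct_absent_cut,
                 alphas = alphas),
            class = "analysis_config")
}
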
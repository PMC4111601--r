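# Synthetic study generator: a desk-scale emulation of the three-channel
# neuronal maturation / OGD profiling design (GEO series GSE44834-like
# structure) with planted ground truth for every pipeline stage.

# evaluate expr under a private RNG stream seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Standard sample designs of the synthetic study
#'
#' Maturation: Days 2/4/6/8 with Day 2 as baseline. OGD: 0/2/4 h of
#' oxygen-glucose deprivation with 0 h as baseline.
#'
#' @param condition `"maturation"` or `"OGD"`.
#' @return a [sample_design()].
#' @export
synth_design <- function(condition = c("maturation", "OGD")) {
  condition <- match.arg(condition)
  if (condition == "maturation")
    sample_design(paste0("Day", c(2, 4, 6, 8)), c(2, 4, 6, 8),
                  "maturation", "Day2")
  else
    sample_design(paste0("OGD", c(0, 2, 4), "h"), c(0, 2, 4), "OGD", "OGD0h")
}

#' Generate a toy genome annotation with planted orientation classes
#'
#' Lays out non-overlapping multi-exon coding genes on one toy chromosome
#' and constructs lncRNA loci whose orientation class (and sub-region) is
#' planted by design, using the same geometric rules that
#' [classify_locus()] applies, so that classification recovers the planted
#' classes exactly. The default class mix matches the observed census of
#' differentially expressed lncRNAs (60% intergenic, 20% antisense, 13%
#' sense, 7% bidirectional).
#'
#' @param n_genes number of coding genes (>= 1 when any non-intergenic
#'   class is requested; each gene gets >= 3 exons).
#' @param n_lnc number of lncRNA loci.
#' @param class_mix named fractions over
#'   `c("intergenic", "antisense_overlap", "sense_overlap",
#'   "bidirectional")`; must sum to 1.
#' @param seed RNG seed; same seed, same output.
#' @param window,promoter_bp classifier geometry, as in [classify_locus()].
#' @return list with `genes` (a `gene_models` list), `lncs` (list of
#'   [lnc_locus()]) and `truth` (data.frame `lnc_id`, `category`,
#'   `subregion`, `gene_id`).
#' @export
synth_annotation <- function(n_genes = 50, n_lnc = 500,
                             class_mix = c(intergenic = 0.60,
                                           antisense_overlap = 0.20,
                                           sense_overlap = 0.13,
                                           bidirectional = 0.07),
                             seed = 1, window = 1000, promoter_bp = 1000) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  counts <- round(class_mix * n_lnc)
  counts[1L] <- n_lnc - sum(counts[-1L])
  if (any(counts < 0)) stop("infeasible class_mix")
  if (n_genes < 1L && sum(counts[names(counts) != "intergenic"]) > 0L)
    stop("non-intergenic loci require at least one gene")
  .with_seed(seed, {
    genes <- list()
    spacing <- 20000
    for (i in seq_len(n_genes)) {
      gid <- sprintf("G%03d", i)
      strand <- sample(c("+", "-"), 1L)
      g_start <- 10000 + (i - 1L) * spacing
      n_ex <- sample(3:5, 1L)
      ex_len <- sample(200:500, n_ex, replace = TRUE)
      in_len <- sample(300:800, n_ex - 1L, replace = TRUE)
      pos <- g_start
      exons <- matrix(0, n_ex, 2L)
      for (e in seq_len(n_ex)) {
        exons[e, ] <- c(pos, pos + ex_len[e])
        pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
      }
      g_end <- exons[n_ex, 2L]
      u <- sample(80:150, 1L)   # 3' UTR inside the transcription-last exon
      utr3 <- if (strand == "+") c(g_end - u, g_end) else c(g_start, g_start + u)
      genes[[gid]] <- gene_model(gid, "chrS", strand, g_start, g_end,
                                 exons, utr3)
    }
    classes <- rep(names(counts), counts)
    classes <- sample(classes)
    lncs <- vector("list", n_lnc)
    truth <- data.frame(lnc_id = sprintf("L%04d", seq_len(n_lnc)),
                        category = classes,
                        subregion = "none", gene_id = "",
                        stringsAsFactors = FALSE)
    for (j in seq_len(n_lnc)) {
      id <- truth$lnc_id[j]
      cls <- classes[j]
      if (cls == "intergenic") {
        gi <- if (n_genes > 0L) sample(seq_len(n_genes), 1L) else 1L
        anchor <- if (n_genes > 0L) genes[[gi]]$end else 10000
        start <- anchor + 5000 + sample(0:2000, 1L)
        lncs[[j]] <- lnc_locus(id, "chrS", sample(c("+", "-"), 1L),
                               start, start + sample(500:1500, 1L))
        next
      }
      gi <- sample(seq_len(n_genes), 1L)
      g <- genes[[gi]]
      truth$gene_id[j] <- g$id
      if (cls == "bidirectional") {
        gap <- sample(100:900, 1L)
        len <- sample(400:800, 1L)
        if (g$strand == "+") {
          tss <- g$tss - gap
          lncs[[j]] <- lnc_locus(id, "chrS", "-", tss - len + 1L, tss + 1L)
        } else {
          tss <- g$tss + gap
          lncs[[j]] <- lnc_locus(id, "chrS", "+", tss, tss + len)
        }
        next
      }
      strand <- if (cls == "sense_overlap") g$strand else
        setdiff(c("+", "-"), g$strand)
      subs <- if (cls == "sense_overlap")
        c("promoter", "exon", "intron", "first_intron", "intron_exon",
          "three_prime_UTR")
      else  # opposite-strand promoter-only loci would be bidirectional
        c("exon", "intron", "first_intron", "intron_exon", "three_prime_UTR")
      sub <- sample(subs, 1L)
      truth$subregion[j] <- sub
      lncs[[j]] <- lnc_locus(id, "chrS", strand,
                             .sub_interval(g, sub)[1L],
                             .sub_interval(g, sub)[2L])
    }
    list(genes = structure(genes, class = "gene_models"),
         lncs = stats::setNames(lncs, truth$lnc_id), truth = truth)
  })
}

# an interval realizing the requested sub-region inside gene g
.sub_interval <- function(g, sub) {
  shrink <- function(iv) {
    w <- iv[2L] - iv[1L]
    c(floor(iv[1L] + 0.25 * w), ceiling(iv[1L] + 0.75 * w))
  }
  n_ex <- nrow(g$exons)
  introns <- cbind(g$exons[-n_ex, 2L], g$exons[-1L, 1L])
  first_genomic <- if (g$strand == "+") 1L else nrow(introns)
  other <- setdiff(seq_len(nrow(introns)), first_genomic)[1L]
  switch(sub,
    promoter = shrink(.promoter_interval(g, 1000)),
    exon = shrink(g$exons[2L, ]),   # middle exon, never the UTR-bearing one
    intron = shrink(introns[other, ]),
    first_intron = shrink(introns[first_genomic, ]),
    intron_exon = c(floor(mean(g$exons[2L, ])), ceiling(mean(introns[2L, ]))),
    three_prime_UTR = shrink(g$utr3),
    stop("unknown sub-region: ", sub))
}

#' Generate raw three-channel expression with planted trajectories
#'
#' Emits probe x sample intensity matrices for the mRNA, lncRNA and miRNA
#' channels under both conditions. Each probe carries a planted monotone
#' log2 trajectory (up, down or flat); intensity at time t is
#' `baseline * 2^(trajectory(t) + eps)` with `eps ~ N(0, noise_sd^2)`.
#' Differentially expressed probes receive a trajectory amplitude above the
#' channel's SLR cut, flat probes stay below half of it. Genes reverse
#' their trajectory sign from maturation to OGD, emulating the injury sign
#' flip, and each associated lncRNA is emitted with the sign structure its
#' planted relationship label requires (synergistic: same signs in both
#' conditions; inverse: opposite in both; inconclusive: same under
#' maturation, opposite under OGD). miRNA probes include endogenous-control
#' probes and planted detected/undetected intensity levels around the
#' detection floor.
#'
#' @param annotation output of [synth_annotation()].
#' @param n_mrna_probes total mRNA probes (the first `n_genes` are the
#'   gene-linked probes).
#' @param n_mirna miRNA probes, excluding the 4 control probes.
#' @param noise_sd SD of the per-observation log2 noise (>= 0).
#' @param seed RNG seed.
#' @param config an [analysis_config()] supplying the SLR cuts and the
#'   miRNA floor.
#' @return list with `maturation` and `injury` (each a list of three
#'   [expression_matrix()]), `designs`, and `truth` (probe table, pair
#'   table with planted labels, miRNA detection flags, control probe ids).
#' @export
synth_expression <- function(annotation, n_mrna_probes = 2000,
                             n_mirna = 200, noise_sd = 0.1, seed = 1,
                             config = analysis_config()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_genes <- length(annotation$genes)
  if (n_mrna_probes < n_genes) stop("need at least one probe per gene")
  .with_seed(seed + 1L, {
    des_m <- synth_design("maturation")
    des_i <- synth_design("OGD")
    cut <- config$slr_cut_mrna_lnc

    plant <- function(n, de, cut) {
      # amplitude above/below the cut with a margin robust to the noise
      amp <- ifelse(de, stats::runif(n, cut + 0.4, cut + 2.5),
                    stats::runif(n, 0, 0.5 * cut))
      amp
    }
    # -- mRNA: gene-linked probes first, then free probes ------------------
    gene_ids <- names(annotation$genes)
    mrna_ids <- c(sprintf("M_%s", gene_ids),
                  sprintf("M%04d", seq_len(n_mrna_probes - n_genes)))
    gene_of <- c(gene_ids, rep("", n_mrna_probes - n_genes))
    de_m <- c(rep(TRUE, n_genes),
              sample(c(TRUE, FALSE), n_mrna_probes - n_genes, replace = TRUE))
    dir_mat <- sample(c(-1L, 1L), n_mrna_probes, replace = TRUE)
    dir_inj <- -dir_mat          # injury reverses the maturation trend
    probes <- data.frame(probe_id = mrna_ids, channel = "mRNA",
                         gene = gene_of, de = de_m,
                         dir_maturation = ifelse(de_m, dir_mat, 0L),
                         dir_injury = ifelse(de_m, dir_inj, 0L),
                         amp_maturation = plant(n_mrna_probes, de_m, cut),
                         amp_injury = plant(n_mrna_probes, de_m, cut),
                         stringsAsFactors = FALSE)

    # -- lncRNA: one probe per locus; paired loci get the label's signs ----
    assoc <- annotation$truth[annotation$truth$category != "intergenic", ,
                              drop = FALSE]
    labels <- rep(c("synergistic", "inverse", "inconclusive"),
                  length.out = nrow(assoc))
    gene_dir <- stats::setNames(probes$dir_maturation[seq_len(n_genes)],
                                gene_ids)
    lnc_ids <- annotation$truth$lnc_id
    lnc_de <- rep(NA, length(lnc_ids))
    lnc_dm <- integer(length(lnc_ids))
    lnc_di <- integer(length(lnc_ids))
    is_assoc <- match(lnc_ids, assoc$lnc_id)
    for (k in seq_along(lnc_ids)) {
      a <- is_assoc[k]
      if (!is.na(a)) {
        sm <- gene_dir[[assoc$gene_id[a]]]
        si <- -sm
        lab <- labels[a]
        lnc_de[k] <- TRUE
        lnc_dm[k] <- switch(lab, synergistic = sm, inverse = -sm,
                            inconclusive = sm)
        lnc_di[k] <- switch(lab, synergistic = si, inverse = -si,
                            inconclusive = -si)
      } else {
        lnc_de[k] <- sample(c(TRUE, FALSE), 1L)
        d <- sample(c(-1L, 1L), 1L)
        lnc_dm[k] <- if (lnc_de[k]) d else 0L
        lnc_di[k] <- if (lnc_de[k]) -d else 0L
      }
    }
    probes <- rbind(probes, data.frame(
      probe_id = lnc_ids, channel = "lncRNA",
      gene = annotation$truth$gene_id, de = lnc_de,
      dir_maturation = lnc_dm, dir_injury = lnc_di,
      amp_maturation = plant(length(lnc_ids), lnc_de, cut),
      amp_injury = plant(length(lnc_ids), lnc_de, cut),
      stringsAsFactors = FALSE))
    pairs <- data.frame(gene = assoc$gene_id,
                        mrna = sprintf("M_%s", assoc$gene_id),
                        lncrna = assoc$lnc_id, label = labels,
                        stringsAsFactors = FALSE)

    # -- miRNA: controls + detected/undetected planted around the floor ---
    ctrl_ids <- sprintf("ctrl%02d", 1:4)
    mir_ids <- sprintf("mir%04d", seq_len(n_mirna))
    mir_detected <- sample(c(TRUE, FALSE), n_mirna, replace = TRUE,
                           prob = c(0.4, 0.6))
    mir_de <- mir_detected & sample(c(TRUE, FALSE), n_mirna, replace = TRUE)
    mdir <- sample(c(-1L, 1L), n_mirna, replace = TRUE)
    probes <- rbind(probes, data.frame(
      probe_id = mir_ids, channel = "miRNA", gene = "", de = mir_de,
      dir_maturation = ifelse(mir_de, mdir, 0L),
      dir_injury = ifelse(mir_de, -mdir, 0L),
      amp_maturation = plant(n_mirna, mir_de, config$slr_cut_mirna),
      amp_injury = plant(n_mirna, mir_de, config$slr_cut_mirna),
      stringsAsFactors = FALSE))

    base_for <- function(ch_rows) {
      n <- nrow(ch_rows)
      switch(ch_rows$channel[1L],
             mRNA = exp(stats::rnorm(n, log(500), 0.6)),
             lncRNA = exp(stats::rnorm(n, log(400), 0.6)),
             miRNA = NA)  # handled below
      }
    emit <- function(rows, base, design, which_dir, which_amp) {
      t <- design$timepoints
      frac <- (t - t[1L]) / (t[length(t)] - t[1L])
      traj <- outer(rows[[which_dir]] * rows[[which_amp]], frac)
      eps <- matrix(stats::rnorm(length(traj), 0, noise_sd),
                    nrow(traj), ncol(traj))
      vals <- base * 2^(traj + eps)
      dimnames(vals) <- list(rows$probe_id, design$samples)
      vals
    }
    mk <- function(ch, design, which_dir, which_amp) {
      rows <- probes[probes$channel == ch, , drop = FALSE]
      if (ch == "miRNA") {
        base <- ifelse(mir_detected,
                       exp(stats::runif(nrow(rows), log(1000), log(4000))),
                       stats::runif(nrow(rows), 50, 150))
        vals <- emit(rows, base, design, which_dir, which_amp)
        ctrl <- matrix(5000 * 2^stats::rnorm(4L * length(design$samples),
                                             0, noise_sd),
                       4L, length(design$samples),
                       dimnames = list(ctrl_ids, design$samples))
        vals <- rbind(ctrl, vals)
      } else {
        vals <- emit(rows, base_for(rows), design, which_dir, which_amp)
      }
      expression_matrix(vals, ch)
    }
    out <- list(
      maturation = list(mRNA = mk("mRNA", des_m, "dir_maturation",
                                  "amp_maturation"),
                        lncRNA = mk("lncRNA", des_m, "dir_maturation",
                                    "amp_maturation"),
                        miRNA = mk("miRNA", des_m, "dir_maturation",
                                   "amp_maturation")),
      injury = list(mRNA = mk("mRNA", des_i, "dir_injury", "amp_injury"),
                    lncRNA = mk("lncRNA", des_i, "dir_injury", "amp_injury"),
                    miRNA = mk("miRNA", des_i, "dir_injury", "amp_injury")),
      designs = list(maturation = des_m, injury = des_i),
      truth = list(probes = probes, pairs = pairs,
                   mirna = data.frame(probe_id = mir_ids,
                                      detected = mir_detected,
                                      de = mir_de, stringsAsFactors = FALSE),
                   control_probes = ctrl_ids),
      noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate ancillary inputs: targets, gene sets and qPCR tables
#'
#' Constructs a miRNA target table consistent with a planted miRNA ->
#' eligible-gene map (10 planted miRNAs each targeting >= 2 eligible genes)
#' plus decoy miRNAs targeting at most one; a gene-set collection with one
#' planted enriched set (all members drawn from the eligible genes) among
#' random background sets; and a noiseless qPCR C_T table realizing a
#' planted fold change via `Ct = a - log2(expression)`.
#'
#' @param expr output of [synth_expression()].
#' @param seed RNG seed.
#' @param n_planted_mirnas planted network miRNAs (each targeting >= 2
#'   eligible genes).
#' @param n_decoys decoy miRNAs (each targeting <= 1 eligible gene).
#' @param n_background_sets background gene sets beside the planted one.
#' @return list with `targets` ([target_table()]), `sets`
#'   ([gene_sets()]), `planted_set` (name), `planted_mirnas`,
#'   `eligible_genes`, and `qpcr` (planted fold plus C_T replicate
#'   vectors).
#' @export
synth_ancillary <- function(expr, seed = 1, n_planted_mirnas = 10,
                            n_decoys = 30, n_background_sets = 5) {
  .with_seed(seed + 2L, {
    pairs <- expr$truth$pairs
    eligible <- sort(unique(pairs$gene[pairs$label != "inconclusive"]))
    all_genes <- unique(expr$truth$probes$gene[expr$truth$probes$gene != ""])
    other <- setdiff(all_genes, eligible)
    if (length(eligible) < 2L) stop("too few eligible genes planted")

    mir_pool <- expr$truth$mirna$probe_id[expr$truth$mirna$de]
    planted <- utils::head(mir_pool, n_planted_mirnas)
    decoys <- utils::head(setdiff(expr$truth$mirna$probe_id, planted),
                          n_decoys)
    rows <- list()
    for (m in planted) {
      g <- sample(eligible, sample(2:min(4L, length(eligible)), 1L))
      rows[[m]] <- data.frame(mirna = m, gene = g,
                              evidence = sample(c("predicted", "validated"),
                                                length(g), replace = TRUE),
                              source = "synthetic", stringsAsFactors = FALSE)
    }
    for (m in decoys) {
      g <- character()
      if (stats::runif(1) < 0.5) g <- sample(eligible, 1L)
      if (length(other)) g <- c(g, sample(other, min(length(other),
                                                     sample(1:3, 1L))))
      if (length(g))
        rows[[m]] <- data.frame(mirna = m, gene = unique(g),
                                evidence = "predicted",
                                source = "synthetic",
                                stringsAsFactors = FALSE)
    }
    targets <- target_table(do.call(rbind, rows))

    sets <- list(planted_pathway = eligible)
    for (b in seq_len(n_background_sets)) {
      sets[[sprintf("background_%02d", b)]] <-
        sample(all_genes, min(length(all_genes), sample(8:15, 1L)))
    }
    collection <- gene_sets(sets, universe = all_genes)

    # qPCR table realizing the first pair gene's planted endpoint fold
    g1 <- pairs$gene[1L]
    pr <- expr$truth$probes
    row <- pr[pr$probe_id == sprintf("M_%s", g1), ]
    log_fold <- row$dir_maturation * row$amp_maturation
    a <- 30
    qpcr <- list(gene = g1, fold = 2^log_fold,
                 ct_target = rep(a - log_fold, 3L),
                 ct_ref = rep(18, 3L),
                 ct_target_cal = rep(a, 3L),
                 ct_ref_cal = rep(18, 3L))
    list(targets = targets, sets = collection,
         planted_set = "planted_pathway", planted_mirnas = sort(planted),
         eligible_genes = eligible, qpcr = qpcr)
  })
}
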
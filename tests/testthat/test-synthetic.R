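test_that("generators are deterministic given the seed", {
  a1 <- synth_annotation(n_genes = 10, n_lnc = 50, seed = 7)
  a2 <- synth_annotation(n_genes = 10, n_lnc = 50, seed = 7)
  expect_identical(a1, a2)
  e1 <- synth_expression(a1, n_mrna_probes = 60, n_mirna = 30, seed = 7)
  e2 <- synth_expression(a2, n_mrna_probes = 60, n_mirna = 30, seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(
    e1$maturation$mRNA,
    synth_expression(a1, n_mrna_probes = 60, n_mirna = 30, seed = 8)$maturation$mRNA))
})

test_that("planted orientation classes are recovered exactly", {
  ann <- synth_annotation(n_genes = 30, n_lnc = 200, seed = 3)
  rel <- classify_loci(ann$lncs, ann$genes)
  expect_identical(rel$category, ann$truth$category)
  expect_identical(rel$subregion, ann$truth$subregion)
  expect_identical(rel$gene_id, ann$truth$gene_id)
  # all-intergenic mix yields no associations
  only_int <- synth_annotation(n_genes = 5, n_lnc = 40,
                               class_mix = c(intergenic = 1,
                                             antisense_overlap = 0,
                                             sense_overlap = 0,
                                             bidirectional = 0), seed = 2)
  rel0 <- classify_loci(only_int$lncs, only_int$genes)
  expect_equal(nrow(associate_lnc_genes(rel0)$associations), 0L)
  expect_error(synth_annotation(n_genes = 0, n_lnc = 10, seed = 1),
               "at least one gene")
})

test_that("noiseless emission is recovered exactly by the pipeline", {
  ann <- synth_annotation(n_genes = 15, n_lnc = 80, seed = 5)
  expr <- synth_expression(ann, n_mrna_probes = 300, n_mirna = 60,
                           noise_sd = 0, seed = 5)
  truth <- expr$truth$probes
  for (ch in c("mRNA", "lncRNA")) {
    for (cond in c("maturation", "injury")) {
      des <- expr$designs[[cond]]
      slr <- compute_slr(expr[[cond]][[ch]], des)
      calls <- call_differential(slr, cut = 1)
      t_ch <- truth[truth$channel == ch, ]
      m <- match(calls$probe_id, t_ch$probe_id)
      expect_identical(calls$is_de, t_ch$de[m])
    }
  }
  # planted pair labels recover exactly at zero noise
  pr <- expr$truth$pairs
  r_of <- function(cond, ch, ids) {
    slr <- compute_slr(expr[[cond]][[ch]], expr$designs[[cond]])
    tp <- slr_timepoints(slr)
    vapply(ids, function(p) pearson_trend(unclass(slr)[p, ], tp)$r,
           numeric(1L))
  }
  pairs_df <- data.frame(
    gene = pr$gene, mrna = pr$mrna, lncrna = pr$lncrna,
    r_mrna_maturation = r_of("maturation", "mRNA", pr$mrna),
    r_lnc_maturation = r_of("maturation", "lncRNA", pr$lncrna),
    r_mrna_injury = r_of("injury", "mRNA", pr$mrna),
    r_lnc_injury = r_of("injury", "lncRNA", pr$lncrna))
  expect_identical(classify_pairs(pairs_df)$final, pr$label)
})

test_that("planted miRNA detection flags survive preprocessing", {
  ann <- synth_annotation(n_genes = 10, n_lnc = 40, seed = 11)
  expr <- synth_expression(ann, n_mrna_probes = 50, n_mirna = 150,
                           noise_sd = 0.1, seed = 11)
  pp <- mirna_preprocess(expr$maturation$miRNA, expr$truth$control_probes,
                         floor = 300)
  mt <- expr$truth$mirna
  expect_identical(unname(pp$detected[mt$probe_id]), mt$detected)
  expect_true(all(pp$detected[expr$truth$control_probes]))
})

test_that("ancillary tables are consistent with the planted truth", {
  ann <- synth_annotation(n_genes = 20, n_lnc = 120, seed = 13)
  expr <- synth_expression(ann, n_mrna_probes = 200, n_mirna = 100,
                           noise_sd = 0, seed = 13)
  anc <- synth_ancillary(expr, seed = 13)
  # the planted enriched set scores the smallest enrichment p
  res <- enrich_pathways(anc$eligible_genes, anc$sets, method = "fisher")
  expect_equal(res$set[1L], anc$planted_set)
  expect_lt(res$p[1L], min(res$p[-1L]))
  # decoys never reach the min-gene rule; planted miRNAs all do
  hits <- map_mirnas_min_genes(anc$eligible_genes, anc$targets, k = 2)
  expect_setequal(hits, anc$planted_mirnas)
  # qPCR table inverts to the planted fold change at zero noise
  q <- anc$qpcr
  r <- ddct_fold_change(q$ct_target, q$ct_ref, q$ct_target_cal, q$ct_ref_cal)
  expect_equal(r$fold, q$fold, tolerance = 1e-9)
  # eligible genes from the planted pair labels match the classifier route
  pr <- expr$truth$pairs
  expect_equal(anc$eligible_genes,
               sort(unique(pr$gene[pr$label != "inconclusive"])))
})

test_that("the full synthetic cascade funnels monotonically", {
  ann <- synth_annotation(n_genes = 20, n_lnc = 120, seed = 17)
  expr <- synth_expression(ann, n_mrna_probes = 200, n_mirna = 100,
                           noise_sd = 0.1, seed = 17)
  anc <- synth_ancillary(expr, seed = 17)
  des <- expr$designs$maturation
  mrna_calls <- call_differential(compute_slr(expr$maturation$mRNA, des), 1)
  lnc_calls <- call_differential(compute_slr(expr$maturation$lncRNA, des), 1)
  rel <- classify_loci(ann$lncs, ann$genes)
  assoc <- associate_lnc_genes(rel)$associations
  mrna_ann <- data.frame(
    probe_id = expr$truth$probes$probe_id[expr$truth$probes$channel == "mRNA"],
    gene = expr$truth$probes$gene[expr$truth$probes$channel == "mRNA"])
  stage1 <- shortlist_dual_de(mrna_calls, lnc_calls, assoc, mrna_ann)
  expect_true(length(stage1) > 0)
  mir_de <- expr$truth$mirna$probe_id[expr$truth$mirna$de]
  stage2 <- intersect_mirna_targets(stage1, anc$targets, mir_de)
  expect_true(all(stage2 %in% stage1))
  slr_g <- compute_slr(expr$maturation$mRNA, des)
  rownames(slr_g) <- mrna_ann$gene[match(rownames(slr_g), mrna_ann$probe_id)]
  stage3 <- mature_phenotype_filter(stage2, slr_g, cut = 1)
  expect_true(all(stage3 %in% stage2))
  mirnas <- map_mirnas_min_genes(anc$eligible_genes, anc$targets, k = 2)
  pairs <- expr$truth$pairs
  pairs$final <- pairs$label
  net <- build_network(anc$eligible_genes, pairs, rel, anc$targets, mirnas)
  expect_true(all(net$edges$from %in% net$nodes$id))
  expect_true(all(net$edges$to %in% net$nodes$id))
  expect_equal(sort(unique(net$nodes$type[net$nodes$id %in% mirnas])), "miRNA")
})
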
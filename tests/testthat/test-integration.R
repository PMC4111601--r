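test_that("dual-DE shortlisting needs both channels differentially expressed", {
  assoc <- data.frame(lnc_id = c("L1", "L2", "L3"),
                      gene_id = c("A", "B", "C"))
  out <- shortlist_dual_de(mrna_de = c("A", "B"),
                           lnc_de = c("L1", "L3"),   # B's lncRNA is not DE
                           associations = assoc)
  expect_equal(out, "A")  # C has a DE lncRNA but no DE mRNA
  # probe-level interface with an annotation table
  calls <- data.frame(probe_id = c("p1", "p2"), is_de = c(TRUE, FALSE))
  ann <- data.frame(probe_id = c("p1", "p2"), gene = c("A", "B"))
  expect_equal(shortlist_dual_de(calls, c("L1", "L2"), assoc, ann), "A")
  expect_error(shortlist_dual_de(calls, "L1", assoc), "mrna_annotation")
})

test_that("enrichment matches exact combinatorics", {
  gs <- gene_sets(list(hit = paste0("g", 1:5),
                       other = paste0("g", 6:10)),
                  universe = paste0("g", 1:20))
  res <- enrich_pathways(paste0("g", 1:5), gs, method = "fisher")
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  # EASE removes one success; zero overlap scores exactly 1
  rese <- enrich_pathways(paste0("g", 1:5), gs, method = "ease")
  expect_equal(rese$p[rese$set == "other"], 1)
  expect_gt(rese$p[rese$set == "hit"], res$p[res$set == "hit"])
  expect_true(!is.unsorted(rese$p))
  expect_error(enrich_pathways("zz", gs), "outside universe")
})

test_that("hypergeometric tails equal brute-force enumeration", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(8:25, 1L)
    K <- sample(1:(N - 1L), 1L)
    n <- sample(1:(N - 1L), 1L)
    uni <- paste0("g", seq_len(N))
    gs <- gene_sets(list(s = uni[seq_len(K)]), universe = uni)
    genes <- sample(uni, n)
    k <- length(intersect(genes, gs$sets$s))
    p_fisher <- enrich_pathways(genes, gs, "fisher")$p
    expect_equal(p_fisher, hyper_tail_enum(k, K, N, n), tolerance = 1e-10)
    p_ease <- enrich_pathways(genes, gs, "ease")$p
    expect_equal(p_ease,
                 if (k == 0L) 1 else hyper_tail_enum(k - 1L, K, N, n),
                 tolerance = 1e-10)
  }
})

test_that("miRNA target intersection and min-gene mapping filter correctly", {
  tt <- target_table(data.frame(
    mirna = c("m1", "m1", "m2", "m3"),
    gene = c("A", "B", "A", "C"),
    evidence = "predicted", source = "syn"))
  expect_equal(intersect_mirna_targets(c("A", "B", "C"), tt,
                                       de_mirnas = c("m1")), c("A", "B"))
  expect_equal(intersect_mirna_targets("C", tt, "m1"), character(0))
  expect_equal(intersect_mirna_targets(c("A", "B"), target_table(data.frame()),
                                       "m1"), character(0))
  expect_equal(map_mirnas_min_genes(c("A", "B", "C"), tt, k = 2), "m1")
  expect_equal(map_mirnas_min_genes(c("A", "C"), tt, k = 1),
               c("m1", "m2", "m3"))
})

test_that("the mature-phenotype filter requires both late days by default", {
  vals <- rbind(keep = c(0, 1.4, 1.2, 1.1),
                drop6 = c(0, 1.4, 0.9, 1.1),
                flat = c(0, 0.1, 0.2, 0.3))
  colnames(vals) <- paste0("Day", c(2, 4, 6, 8))
  slr <- make_slr(vals, c(2, 4, 6, 8))
  expect_equal(mature_phenotype_filter(rownames(vals), slr, cut = 1), "keep")
  expect_equal(mature_phenotype_filter(rownames(vals), slr, cut = 1,
                                       mode = "either"),
               c("drop6", "keep"))
  expect_error(mature_phenotype_filter("keep", slr, days = c(6, 14)),
               "day missing")
})

test_that("networks assemble typed nodes and edges and catch danglers", {
  pairs <- data.frame(gene = "A", mrna = "NM_1", lncrna = "L1",
                      final = "inverse")
  tt <- target_table(data.frame(mirna = "m1", gene = "A",
                                evidence = "validated", source = "syn"))
  net <- build_network("A", pairs, relations = NULL, targets = tt,
                       mirnas = "m1")
  expect_equal(nrow(net$nodes), 3L)
  expect_setequal(net$nodes$type, c("mRNA", "lncRNA", "miRNA"))
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$type, c("relationship", "targeting"))
  expect_equal(net$edges$subtype[net$edges$type == "relationship"], "inverse")
  expect_equal(net$edges$subtype[net$edges$type == "targeting"], "validated")
  # orientation association edges appear when relations are supplied
  rel <- data.frame(lnc_id = "L1", category = "antisense_overlap")
  net2 <- build_network("A", pairs, rel, tt, "m1")
  expect_equal(sum(net2$edges$type == "association"), 1L)
  expect_equal(net2$edges$subtype[net2$edges$type == "association"],
               "antisense")
  # exports are plain text
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_network(net2, tsv = tsv, json = js)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(net2$edges))
  expect_named(jsonlite::read_json(js), c("nodes", "edges"))
})

test_that("report percentages recompute from their own counts", {
  rep_ <- summary_report(
    detected = list(miRNA = c(395, 1040)),
    de = list(mRNA = c(6965, 14213), lncRNA = c(7455, 15715)))
  expect_equal(rep_$detection$percent, 38.0)
  expect_equal(rep_$differential$percent, c(49.0, 47.4))
  # 1-dp recompute identity on random counts
  set.seed(17)
  n <- sample(1000:20000, 20)
  x <- sapply(n, function(nn) sample(nn, 1L))
  expect_equal(pct1(x, n), round(100 * x / n, 1))
})
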
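test_that("expression tables round-trip through read and write", {
  vals <- matrix(c(1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4,
                 dimnames = list(c("P1", "P2", "P3"), paste0("S", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(make_expr(vals), f)
  back <- read_expression_table(f, "mRNA")
  expect_equal(dim(back), c(3L, 4L))
  expect_equal(unclass(back), vals, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(vals))
  expect_identical(channel(back), "mRNA")
  # read -> write -> read is the identity
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(back, f2)
  expect_equal(unclass(read_expression_table(f2, "mRNA")), unclass(back))
})

test_that("malformed expression tables are hard errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe\tS1\tS2", "P1\t1\t2", "P1\t3\t4"), f)
  expect_error(read_expression_table(f, "mRNA"), "duplicate probe id.*P1")
  writeLines(c("probe\tS1\tS2", "P1\t1\tx2"), f)
  expect_error(read_expression_table(f, "mRNA"), "non-numeric.*row 1.*S2")
  writeLines(character(), f)
  expect_error(read_expression_table(f, "mRNA"))
  expect_error(expression_matrix(matrix(-1, 1, 1,
                                        dimnames = list("P", "S")), "mRNA"),
               "non-negative")
})

write_gff3_fixture <- function(strand = "+") {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c(
    "##gff-version 3",
    paste("chr1", ".", "gene", 1, 100, ".", strand, ".", "ID=g1", sep = "\t"),
    paste("chr1", ".", "mRNA", 1, 100, ".", strand, ".", "ID=t1;Parent=g1",
          sep = "\t"),
    paste("chr1", ".", "exon", 1, 40, ".", strand, ".", "Parent=t1", sep = "\t"),
    paste("chr1", ".", "exon", 61, 100, ".", strand, ".", "Parent=t1",
          sep = "\t"),
    paste("chr1", ".", "three_prime_UTR", 81, 100, ".", strand, ".",
          "Parent=t1", sep = "\t")), f)
  f
}

test_that("GFF3 genes convert to 0-based half-open with strand-aware TSS", {
  g <- read_gene_models(write_gff3_fixture("+"))[["g1"]]
  expect_equal(c(g$start, g$end), c(0, 100))
  expect_equal(g$tss, 0)
  expect_equal(unname(g$exons), cbind(c(0, 60), c(40, 100)),
               ignore_attr = TRUE)
  expect_equal(g$utr3, c(80, 100))
  gm <- read_gene_models(write_gff3_fixture("-"))[["g1"]]
  expect_equal(gm$tss, 99)
})

test_that("BED12 blocks become exons and match the GFF3 encoding", {
  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 0, 100, "g1", 0, "+", 0, 80, "0", 2,
                   "40,40,", "0,60,", sep = "\t"), fb)
  gb <- read_gene_models(fb)[["g1"]]
  expect_equal(nrow(gb$exons), 2L)
  expect_equal(unname(gb$exons), cbind(c(0, 60), c(40, 100)),
               ignore_attr = TRUE)
  gg <- read_gene_models(write_gff3_fixture("+"))[["g1"]]
  for (field in c("chrom", "strand", "start", "end", "tss", "utr3"))
    expect_equal(gb[[field]], gg[[field]], info = field)
  expect_equal(unname(gb$exons), unname(gg$exons))
})

test_that("GMT collections parse, deduplicate and restrict to a universe", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg2\tg3",
               "setB\tdesc\tg3\tg4"), f)
  gs <- read_gmt(f)
  expect_named(gs$sets, c("setA", "setB"))
  expect_equal(gs$sets$setA, c("g1", "g2", "g3"))  # duplicate stored once
  expect_setequal(gs$universe, paste0("g", 1:4))
  restricted <- read_gmt(f, universe = c("g1", "g2", "g3"))
  expect_equal(restricted$sets$setB, "g3")
  writeLines("bad\tonly_two_fields", f)
  expect_error(read_gmt(f), "fewer than 3 fields")
})

test_that("target tables deduplicate with validated taking precedence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene\tevidence\tsource",
               "miR-377\tNcam1\tpredicted\ttargetscan",
               "miR-377\tNcam1\tvalidated\tcurated",
               "miR-377\tNegr1\tpredicted\ttargetscan",
               "miR-124\tCntn1\tpredicted\ttargetscan",
               "miR-124\tCntn1\tpredicted\tmirdb"), f)
  tt <- read_target_table(f)
  expect_equal(nrow(tt), 3L)  # 5 rows, 2 duplicates collapsed
  expect_equal(tt$evidence[tt$mirna == "miR-377" & tt$gene == "Ncam1"],
               "validated")
  expect_equal(nrow(target_table(data.frame())), 0L)
  expect_error(target_table(data.frame(mirna = "m", gene = "g",
                                       evidence = "guessed", source = "x")),
               "evidence")
})

test_that("sample designs validate baseline and timepoint ordering", {
  d <- sample_design(c("D2", "D4"), c(2, 4), "maturation")
  expect_identical(d$baseline, "D2")
  expect_error(sample_design(c("A", "B"), c(2, 2), "maturation"),
               "strictly increasing")
  expect_error(sample_design(c("A", "B"), c(2, 4), "OGD", baseline = "Z"),
               "baseline")
})
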
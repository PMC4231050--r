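test_that("the four genomic categories follow the containment rules", {
  ann <- toy_annotation()   # gene [100,500), exons [100,200) + [300,500)
  cases <- list(
    list(c(150L, 170L), "exon", FALSE, "g1"),
    list(c(190L, 210L), "exon_intron", FALSE, "g1"),  # spans the junction
    list(c(220L, 260L), "intron", FALSE, "g1"),
    list(c(600L, 620L), "intergenic", FALSE, ""),
    list(c(90L, 110L), "intergenic", TRUE, "")        # straddles gene start
  )
  for (cs in cases) {
    res <- classify_location(hit_row("s1", cs[[1]][1], cs[[1]][2]), ann)
    expect_equal(res$location, cs[[2]], info = paste(cs[[1]], collapse = "-"))
    expect_equal(res$boundary, cs[[3]])
  }
  res <- classify_location(hit_row("s1", 150L, 170L), ann)
  expect_equal(res$gene_ids, "g1")
})

test_that("cds mode requires containment in a CDS segment", {
  ann <- toy_annotation()   # CDS [120,200) + [300,450)
  # inside the exon but upstream of the CDS start: exonic only in exon mode
  expect_equal(classify_location(hit_row("s1", 105L, 115L), ann,
                                 mode = "exon")$location, "exon")
  expect_false(classify_location(hit_row("s1", 105L, 115L), ann,
                                 mode = "cds")$location == "exon")
  expect_equal(classify_location(hit_row("s1", 130L, 150L), ann,
                                 mode = "cds")$location, "exon")
  # between the two CDS segments: intronic in both modes
  expect_equal(classify_location(hit_row("s1", 220L, 260L), ann,
                                 mode = "cds")$location, "intron")
})

test_that("multi-transcript genes use the most exonic reading", {
  ex1 <- matrix(c(0L, 1000L), ncol = 2, dimnames = list(NULL, c("start", "end")))
  ex2 <- matrix(c(0L, 300L, 600L, 1000L), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
  ann <- new_annotation_set(list(
    g = list(gene_id = "g", scaffold = "s1", strand = "+",
             start = 0L, end = 1000L,
             transcripts = list(t1 = list(exons = ex1, cds = ex1),
                                t2 = list(exons = ex2, cds = ex2)),
             annotation = NA_character_, go = NA_character_)
  ))
  # intronic in t2 but exonic in t1 -> exon wins
  expect_equal(classify_location(hit_row("s1", 400L, 420L), ann)$location,
               "exon")
})

test_that("overlapping genes are all reported, first by coordinate", {
  ex_a <- matrix(c(0L, 500L), ncol = 2, dimnames = list(NULL, c("start", "end")))
  ex_b <- matrix(c(200L, 800L), ncol = 2, dimnames = list(NULL, c("start", "end")))
  ann <- new_annotation_set(list(
    gB = list(gene_id = "gB", scaffold = "s1", strand = "+", start = 200L,
              end = 800L, transcripts = list(t = list(exons = ex_b, cds = ex_b)),
              annotation = NA_character_, go = NA_character_),
    gA = list(gene_id = "gA", scaffold = "s1", strand = "+", start = 0L,
              end = 500L, transcripts = list(t = list(exons = ex_a, cds = ex_a)),
              annotation = NA_character_, go = NA_character_)
  ))
  res <- classify_location(hit_row("s1", 250L, 270L), ann)
  expect_equal(res$gene_ids, c("gA", "gB"))
  expect_equal(res$location, "exon")
})

test_that("unknown scaffolds and empty annotations classify as intergenic", {
  ann <- toy_annotation()
  expect_equal(classify_location(hit_row("nowhere", 10L, 30L), ann)$location,
               "intergenic")
  none <- new_annotation_set(list())
  expect_equal(classify_location(hit_row("s1", 150L, 170L), none)$location,
               "intergenic")
})

test_that("classification is exhaustive, exclusive, and monotone under shrinking", {
  ann <- toy_annotation()
  withr::with_seed(3, {
    for (i in 1:100) {
      st <- sample(0:640, 1)
      en <- st + sample(5:60, 1)
      res <- classify_location(hit_row("s1", st, en), ann)
      expect_true(res$location %in% c("exon", "exon_intron", "intron",
                                      "intergenic"))
      if (res$location == "exon" && en - st > 2) {
        inner <- classify_location(hit_row("s1", st + 1L, en - 1L), ann)
        expect_equal(inner$location, "exon")
      }
      if (st >= 200 && en <= 300) {   # fully inside the intron
        expect_equal(res$location, "intron")
      }
    }
  })
})

test_that("linkage groups map with Un for unplaced scaffolds", {
  m <- data.frame(scaffold = c("s1", "s2"), lg = c("LG5", "LG8+LG10"))
  expect_equal(assign_linkage_group(c("s1", "s3", "s2"), m),
               c("LG5", "Un", "LG8+LG10"))
})

test_that("genes-with-repeat fraction counts distinct genes", {
  ann4 <- new_annotation_set(setNames(lapply(1:4, function(i) {
    ex <- matrix(c(0L, 100L), ncol = 2, dimnames = list(NULL, c("start", "end")))
    list(gene_id = paste0("g", i), scaffold = paste0("sc", i), strand = "+",
         start = 0L, end = 100L,
         transcripts = list(t = list(exons = ex, cds = ex)),
         annotation = NA_character_, go = NA_character_)
  }), paste0("g", 1:4)))
  atlas <- data.frame(
    location = c("exon", "intron", "exon", "intergenic"),
    gene_ids = c("g1", "g1", "g2", ""), stringsAsFactors = FALSE)
  res <- genes_with_ssr_fraction(atlas, ann4)
  expect_equal(res$n_genes_with_ssr, 2L)
  expect_equal(res$percent, 50)
  none <- genes_with_ssr_fraction(atlas[atlas$location == "intergenic", ], ann4)
  expect_equal(none$percent, 0)
  expect_error(genes_with_ssr_fraction(atlas, new_annotation_set(list())),
               "no genes")
})
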
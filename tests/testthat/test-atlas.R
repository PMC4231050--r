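test_that("length classes split at 20 bases", {
  expect_equal(bin_length_class(c(12, 19, 20, 35)), c("II", "II", "I", "I"))
  expect_error(bin_length_class(11), ">= 12")
})

test_that("half-up rounding drives all reported percentages", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(percent_of(1, 8, 1), 12.5)
  expect_error(percent_of(1, 0), "positive")
})

test_that("atlas records join hits, contexts, linkage groups and primers", {
  hits <- rbind(hit_row("s1", 10L, 26L, 2L, "AT"),
                hit_row("s1", 100L, 115L, 3L, "AAG"),
                hit_row("s2", 50L, 70L, 4L, "ACGT"))
  ctx <- data.frame(location = c("intron", "exon", "intergenic"),
                    boundary = FALSE, gene_id = c("g1", "g1", ""),
                    gene_ids = c("g1", "g1", ""), stringsAsFactors = FALSE)
  lg <- data.frame(scaffold = "s1", lg = "LG2")
  ga <- data.frame(gene_id = "g1", annotation = "pectin lyase-like",
                   go = "GO:0030570", stringsAsFactors = FALSE)
  primers <- data.frame(ssr_id = ssr_ids(hits)[1:2],
                        status = c("ok", "no_primer"),
                        reason = c("", "tm"),
                        fwd = c("ACGTACGTACGTACGTAC", NA),
                        rev = c("TGCATGCATGCATGCATG", NA),
                        product_size = c(300L, NA),
                        tm_fwd = c(60.0, NA), tm_rev = c(60.5, NA),
                        stringsAsFactors = FALSE)
  atlas <- build_atlas(hits, ctx, lg, ga, primers)
  expect_equal(nrow(atlas), 3L)
  expect_equal(atlas$ssr_id[1], "s1:11-26:2")
  expect_equal(atlas$length_class, c("II", "II", "I"))
  expect_equal(atlas$linkage_group, c("LG2", "LG2", "Un"))
  expect_equal(atlas$annotation[2], "pectin lyase-like")
  expect_equal(atlas$primer_status, c("ok", "no_primer", "no_primer"))
  expect_equal(atlas$primer_reason[2:3], c("tm", "not_attempted"))
  expect_equal(atlas$product_size[1], 300L)
  expect_equal(sum(atlas$length_class == "I") + sum(atlas$length_class == "II"),
               nrow(atlas))
})

test_that("key mismatches between stages are loud", {
  hits <- hit_row("s1", 10L, 26L, 2L, "AT")
  ctx <- data.frame(ssr_id = "s1:99-120:2", location = "exon",
                    boundary = FALSE, gene_id = "g", gene_ids = "g",
                    stringsAsFactors = FALSE)
  expect_error(build_atlas(hits, ctx), "s1:99-120:2")
  ctx2 <- data.frame(location = c("exon", "intron"), boundary = FALSE,
                     gene_id = "", gene_ids = "", stringsAsFactors = FALSE)
  expect_error(build_atlas(hits, ctx2), "align")
  primers <- data.frame(ssr_id = "s1:1-12:2", status = "ok", reason = "",
                        fwd = "A", rev = "A", product_size = 300L,
                        tm_fwd = 60, tm_rev = 60, stringsAsFactors = FALSE)
  good_ctx <- data.frame(location = "exon", boundary = FALSE, gene_id = "g",
                         gene_ids = "g", stringsAsFactors = FALSE)
  expect_error(build_atlas(hits, good_ctx, primers = primers), "s1:1-12:2")
})

test_that("summary tables conserve counts and normalize percentages", {
  hits <- do.call(rbind, lapply(1:40, function(i) {
    hit_row("s1", i * 50L, i * 50L + 12L + (i %% 12L), 2L,
            c("AT", "AG", "AC")[i %% 3 + 1])
  }))
  ctx <- data.frame(location = rep(c("exon", "intron", "intergenic",
                                     "intergenic"), 10),
                    boundary = FALSE, gene_id = "", gene_ids = "",
                    stringsAsFactors = FALSE)
  atlas <- build_atlas(hits, ctx)
  st <- summarize_atlas(atlas, "location", "period")
  expect_equal(st$grand, 40)
  expect_equal(unname(st$counts["Total", "Total"]), 40)
  expect_equal(sum(st$row_pct), 100, tolerance = 0.011)
  for (cn in colnames(st$percents)) {
    expect_equal(sum(st$percents[, cn]), 100, tolerance = 0.11)
  }
  st2 <- summarize_atlas(atlas, "length_class", "location")
  expect_equal(st2$grand, 40)
  expect_error(summarize_atlas(atlas, "flavor", "period"), "unknown")
})

test_that("a single-record atlas yields one full-percentage cell", {
  atlas <- build_atlas(hit_row("s1", 0L, 12L, 2L, "AT"),
                       data.frame(location = "intron", boundary = FALSE,
                                  gene_id = "g", gene_ids = "g",
                                  stringsAsFactors = FALSE))
  st <- summarize_atlas(atlas, "location", "period")
  expect_equal(unname(st$counts["intron", "2"]), 1)
  expect_equal(unname(st$percents["intron", "2"]), 100)
})

test_that("marker screen arithmetic rounds to whole percent", {
  expect_equal(screen_summary(0, 73), 0L)
  expect_equal(screen_summary(73, 73), 100L)
  expect_error(screen_summary(5, 0), "> 0")
  expect_error(screen_summary(80, 73), "between")
  expect_equal(per_gene_mean(1, 1), 1.0)
  expect_error(per_gene_mean(3, 0), "> 0")
})
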
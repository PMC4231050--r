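test_that("backgrounds are deterministic, repeat-free and on-target GC", {
  a <- make_background(10000, gc = 0.5, seed = 7)
  b <- make_background(10000, gc = 0.5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_background(10000, gc = 0.5, seed = 8)))
  expect_equal(nrow(oracle_find_repeats(a)), 0L)
  gc_obs <- sum(chars(a) %in% c("G", "C")) / 10000
  expect_lt(abs(gc_obs - 0.5), 0.02)
  low <- make_background(10000, gc = 0.35, seed = 3)
  expect_lt(abs(sum(chars(low) %in% c("G", "C")) / 10000 - 0.35), 0.02)
  expect_error(make_background(100, gc = 0), "strictly between")
  expect_error(make_background(100, gc = 1), "strictly between")
})

test_that("simulation specs validate plants against scaffolds and genes", {
  sc <- data.frame(name = "s1", length = 1000L)
  ok <- data.frame(scaffold = "s1", position = 100L, motif = "AT", size = 16L)
  expect_s3_class(sim_spec(sc, ok), "sim_spec")
  expect_error(sim_spec(sc, transform(ok, motif = "ATAT")), "primitive")
  expect_error(sim_spec(sc, transform(ok, size = 11L)), ">= 12")
  expect_error(sim_spec(sc, transform(ok, position = 990L)), "beyond")
  expect_error(sim_spec(sc, transform(ok, scaffold = "s9")), "undeclared")
  close_pair <- rbind(ok, data.frame(scaffold = "s1", position = 118L,
                                     motif = "AAG", size = 12L))
  expect_error(sim_spec(sc, close_pair), "apart")
  g <- list(list(gene_id = "g1", scaffold = "s1", strand = "+", start = 50L,
                 end = 500L,
                 exons = matrix(c(50L, 200L, 300L, 500L), ncol = 2,
                                byrow = TRUE)))
  # declared location is cross-checked against the gene layout
  expect_error(sim_spec(sc, transform(ok, location = "intron"), g),
               "implies 'exon'")
  sp <- sim_spec(sc, ok, g)
  expect_equal(sp$plants$location, "exon")
})

test_that("planted repeats come back verbatim in the truth table", {
  sc <- data.frame(name = "s1", length = 3000L)
  plants <- data.frame(scaffold = "s1", position = c(500L, 1500L),
                       motif = c("AT", "AAG"), size = c(16L, 18L),
                       stringsAsFactors = FALSE)
  sim <- simulate_genome(sim_spec(sc, plants, seed = 5))
  expect_equal(sim$truth$period, c(2L, 3L))
  expect_equal(sim$truth$size, c(16L, 18L))
  expect_equal(sim$truth$exponent, c(8, 6))
  expect_equal(sim$truth$location, c("intergenic", "intergenic"))
  expect_equal(sim$truth$lg, c("Un", "Un"))
  s <- sim$genome$s1$sequence
  expect_equal(substring(s, 501, 516), strrep("AT", 8))
  expect_equal(substring(s, 1501, 1518), strrep("AAG", 6))
})

test_that("scanner output equals planted truth across seeds (junction repair)", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_genome(example_sim_spec(seed = seed))
    hits <- scan_genome(sim$genome)
    k_hit <- paste(hits$scaffold, hits$start, hits$end, hits$period)
    k_truth <- paste(sim$truth$scaffold, sim$truth$start, sim$truth$end,
                     sim$truth$period)
    expect_setequal(k_hit, k_truth)
    expect_equal(hits$motif[match(k_truth, k_hit)], sim$truth$motif)
  }
})

test_that("simulation re-runs are identical and files round-trip", {
  d1 <- file.path(tempdir(), "simfix1")
  sim1 <- simulate_genome(example_sim_spec(seed = 4), dir = d1)
  sim2 <- simulate_genome(example_sim_spec(seed = 4))
  expect_identical(sim1$genome$sA$sequence, sim2$genome$sA$sequence)
  g <- read_fasta(file.path(d1, "genome.fasta"))
  expect_equal(g$sA$sequence, sim1$genome$sA$sequence)
  ann <- read_gff3(file.path(d1, "annotation.gff3"))
  expect_setequal(names(ann$genes), names(sim1$annotation$genes))
  expect_equal(ann$genes$geneA1$start, sim1$annotation$genes$geneA1$start)
  expect_equal(unname(ann$genes$geneA1$transcripts[[1]]$exons),
               unname(sim1$annotation$genes$geneA1$transcripts[[1]]$exons))
  lg <- read_lg_map(file.path(d1, "lg_map.tsv"))
  expect_equal(lg, sim1$lg_map)
  truth <- read.delim(file.path(d1, "truth.tsv"))
  expect_equal(nrow(truth), 20L)
  expect_equal(truth$start, sim1$truth$start + 1L)   # printed 1-based
})

test_that("the canned fixture covers all contexts, periods and classes", {
  sp <- example_sim_spec()
  expect_equal(nrow(sp$plants), 20L)
  expect_setequal(unique(sp$plants$location),
                  c("exon", "exon_intron", "intron", "intergenic"))
  expect_setequal(unique(nchar(sp$plants$motif)), 2:6)
  cls <- bin_length_class(sp$plants$size)
  expect_true(all(c("I", "II") %in% cls))
  expect_true(any(sp$plants$size %% nchar(sp$plants$motif) != 0))  # fractional
})
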
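# In-code fixtures shared across test files.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# toy single-gene annotation: gene s1:[100,500), one transcript with exons
# [100,200) and [300,500); CDS trimmed to [120,200) and [300,450)
toy_annotation <- function() {
  exons <- matrix(c(100L, 200L, 300L, 500L), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(c(120L, 200L, 300L, 450L), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
  new_annotation_set(list(
    g1 = list(gene_id = "g1", scaffold = "s1", strand = "+",
              start = 100L, end = 500L,
              transcripts = list(g1.t1 = list(exons = exons, cds = cds)),
              annotation = NA_character_, go = NA_character_)
  ))
}

# minimal hit row in internal coordinates
hit_row <- function(scaffold, start, end, period = 2L, motif = "AT") {
  data.frame(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), period = as.integer(period),
             motif = motif, size = as.integer(end - start),
             exponent = (end - start) / period, stringsAsFactors = FALSE)
}

empty_hits_df <- function() {
  hit_row(character(0), integer(0), integer(0), integer(0), character(0))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small GFF3 mirroring toy_annotation() in 1-based file coordinates
toy_gff3_lines <- function() {
  c("##gff-version 3",
    "s1\ttest\tgene\t101\t500\t.\t+\t.\tID=g1",
    "s1\ttest\tmRNA\t101\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "s1\ttest\texon\t101\t200\t.\t+\t.\tParent=g1.t1",
    "s1\ttest\texon\t301\t500\t.\t+\t.\tParent=g1.t1",
    "s1\ttest\tCDS\t121\t200\t.\t+\t0\tParent=g1.t1",
    "s1\ttest\tCDS\t301\t450\t.\t+\t0\tParent=g1.t1")
}

# 64-mer whose overlapping 3-mers are all distinct (prefix of the greedy
# prefer-largest de Bruijn sequence, which never dead-ends)
distinct_triplet_64mer <- function() {
  s <- "AA"
  seen <- character(0)
  while (nchar(s) < 64) {
    tail2 <- substring(s, nchar(s) - 1, nchar(s))
    ext <- FALSE
    for (b in c("T", "G", "C", "A")) {
      tri <- paste0(tail2, b)
      if (!(tri %in% seen)) {
        s <- paste0(s, b)
        seen <- c(seen, tri)
        ext <- TRUE
        break
      }
    }
    if (!ext) stop("de Bruijn construction dead-ended")
  }
  s
}

# template with an SSR run planted at the center of a clean background
planted_template <- function(seed, flank = 250L, run = strrep("ACGT", 5),
                             gc = 0.5) {
  n <- 2L * flank + nchar(run)
  bg <- make_background(n, gc = gc, seed = seed)
  seqs <- paste0(substring(bg, 1, flank), run,
                 substring(bg, flank + nchar(run) + 1, n))
  rec <- new_sequence_record("t1", seqs)
  hit <- hit_row("t1", flank, flank + nchar(run),
                 period = primitive_period(run),
                 motif = substring(run, 1, primitive_period(run)))
  tpl <- extract_template(rec, hit, flank)
  tpl$masked <- dust_mask(tpl$sequence)
  tpl
}
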
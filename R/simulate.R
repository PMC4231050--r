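# Synthetic genomes with planted repeats.
#
# Backgrounds are i.i.d. base sequences at a requested GC fraction,
# certified repeat-free by the reference scanner (hit intervals are
# locally resampled until oracle_find_repeats() reports nothing). Repeat
# arrays are then planted verbatim at declared positions; bases flanking
# each plant are resampled if the scanner reports a run extending beyond
# the planted interval, so the truth table is exact by construction. Gene
# models, linkage groups and annotations are declared in the same spec,
# which makes expected genomic locations part of the truth as well.

#' Generate a repeat-free background sequence
#'
#' @param length sequence length in bases
#' @param gc GC fraction, strictly between 0 and 1 (a GC of 0 or 1 is a
#'   homopolymer and cannot be repeat-free)
#' @param seed integer seed; the result is a deterministic function of
#'   `(length, gc, seed)`
#' @param params [scan_params()] defining "repeat-free"
#' @return a sequence string with zero reported repeats
#' @export
make_background <- function(length, gc = 0.35, seed = 1L,
                            params = scan_params()) {
  if (!(gc > 0 && gc < 1)) stop("gc must be strictly between 0 and 1")
  stopifnot(length >= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withr::with_seed(as.integer(seed), {
    x <- sample(names(probs), length, replace = TRUE, prob = probs)
    for (iter in 1:100) {
      hits <- oracle_find_repeats(paste(x, collapse = ""), params)
      if (nrow(hits) == 0) break
      for (i in seq_len(nrow(hits))) {
        idx <- (hits$start[i] + 1L):hits$end[i]
        x[idx] <- sample(names(probs), base::length(idx), replace = TRUE,
                         prob = probs)
      }
    }
    if (nrow(oracle_find_repeats(paste(x, collapse = ""), params)) > 0) {
      stop("failed to generate a repeat-free background")
    }
    paste(x, collapse = "")
  })
}

#' Specification for a synthetic genome
#'
#' @param scaffolds data.frame with columns `name`, `length`
#' @param plants data.frame with columns `scaffold`, `position` (0-based),
#'   `motif` (primitive, length 2-6), `size` (>= 12 bases); optional
#'   `location` column declaring the expected genomic context (filled in
#'   and cross-checked against the gene layout)
#' @param genes optional list of gene models: each a list with `gene_id`,
#'   `scaffold`, `strand`, `start`, `end` (0-based half-open) and `exons`
#'   (2-column matrix); one transcript per gene, CDS = exons
#' @param lg optional data.frame with columns `scaffold`, `lg`
#' @param gene_annotations optional data.frame (`gene_id`, `annotation`,
#'   `go`)
#' @param gc background GC fraction (default 0.35, a typical
#'   gene-space-poor plant genome composition)
#' @param seed integer seed driving all randomness
#' @return a validated `sim_spec` object
#' @export
sim_spec <- function(scaffolds, plants, genes = list(), lg = NULL,
                     gene_annotations = NULL, gc = 0.35, seed = 1L) {
  stopifnot(is.data.frame(scaffolds), all(c("name", "length") %in% names(scaffolds)),
            is.data.frame(plants),
            all(c("scaffold", "position", "motif", "size") %in% names(plants)))
  if (anyDuplicated(scaffolds$name)) stop("duplicate scaffold names")
  slen <- setNames(as.integer(scaffolds$length), scaffolds$name)
  if (any(!(plants$scaffold %in% names(slen)))) {
    stop("plant on undeclared scaffold")
  }
  if (any(plants$size < 12)) stop("planted sizes must be >= 12")
  for (m in plants$motif) {
    k <- nchar(m)
    if (k < 2 || k > 6) stop("planted motif length must be 2-6: ", m)
    if (!is_primitive_motif(m)) stop("planted motif must be primitive: ", m)
  }
  if (any(plants$position < 0 |
            plants$position + plants$size > slen[plants$scaffold])) {
    stop("plant extends beyond its scaffold")
  }
  for (sc in unique(plants$scaffold)) {
    p <- plants[plants$scaffold == sc, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    if (nrow(p) > 1) {
      gap <- p$position[-1] - (p$position[-nrow(p)] + p$size[-nrow(p)])
      if (any(gap < 6)) stop("plants on ", sc, " must be >= 6 bases apart")
    }
  }
  ann <- build_sim_annotation(genes)
  if (!"location" %in% names(plants)) plants$location <- NA_character_
  expect <- vapply(seq_len(nrow(plants)), function(i) {
    truth_location(plants$scaffold[i], plants$position[i],
                   plants$position[i] + plants$size[i], genes)
  }, "")
  declared <- !is.na(plants$location)
  if (any(plants$location[declared] != expect[declared])) {
    bad <- which(declared & plants$location != expect)[1]
    stop("plant ", bad, ": declared location '", plants$location[bad],
         "' but gene layout implies '", expect[bad], "'")
  }
  plants$location <- expect
  structure(list(scaffolds = scaffolds, plants = plants, genes = genes,
                 lg = lg, gene_annotations = gene_annotations,
                 gc = gc, seed = as.integer(seed)),
            class = "sim_spec")
}

# independent location reading for well-formed single-transcript fixtures
truth_location <- function(scaffold, s, e, genes) {
  for (g in genes) {
    if (g$scaffold != scaffold) next
    if (e <= g$start || s >= g$end) next
    if (!(g$start <= s && e <= g$end)) {
      stop("plant [", s, ",", e, ") straddles the boundary of gene ",
           g$gene_id, "; place it inside or outside")
    }
    ex <- g$exons
    if (any(ex[, 1] <= s & e <= ex[, 2])) return("exon")
    if (nrow(ex) > 1) {
      gs <- ex[-nrow(ex), 2]; ge <- ex[-1, 1]
      if (any(gs <= s & e <= ge)) return("intron")
    }
    lo <- min(ex[, 1]); hi <- max(ex[, 2])
    if (lo <= s && e <= hi) return("exon_intron")
    stop("plant [", s, ",", e, ") in gene ", g$gene_id,
         " lies outside its transcript; unsupported layout")
  }
  "intergenic"
}

build_sim_annotation <- function(genes) {
  models <- list()
  for (g in genes) {
    ex <- g$exons
    colnames(ex) <- c("start", "end")
    tid <- paste0(g$gene_id, ".1")
    models[[g$gene_id]] <- list(
      gene_id = g$gene_id, scaffold = g$scaffold, strand = g$strand,
      start = as.integer(g$start), end = as.integer(g$end),
      transcripts = setNames(list(list(exons = ex, cds = ex)), tid),
      annotation = NA_character_, go = NA_character_
    )
  }
  new_annotation_set(models)
}

#' Simulate a genome with planted repeats
#'
#' @param spec a [sim_spec()]
#' @param dir optional output directory; when given, writes
#'   `genome.fasta`, `annotation.gff3`, `lg_map.tsv`, `truth.tsv` and (if
#'   annotations were declared) `gene_annotations.tsv`
#' @param params [scan_params()] used for the repeat-free certification
#' @return list with `genome` (an `ssr_genome`), `annotation`
#'   (`ssr_annotation`), `lg_map`, `truth` (data.frame: scaffold, start,
#'   end, period, motif, size, exponent, location, lg) and `dir`
#' @export
simulate_genome <- function(spec, dir = NULL, params = scan_params()) {
  stopifnot(inherits(spec, "sim_spec"))
  plants <- spec$plants
  seqs <- list()
  withr::with_seed(spec$seed, {
    for (i in seq_len(nrow(spec$scaffolds))) {
      nm <- spec$scaffolds$name[i]
      len <- spec$scaffolds$length[i]
      x <- chars(make_background(len, spec$gc, derive_seed(spec$seed, i),
                                 params))
      p <- plants[plants$scaffold == nm, , drop = FALSE]
      expected <- data.frame(start = integer(0), end = integer(0),
                             period = integer(0))
      for (j in seq_len(nrow(p))) {
        k <- nchar(p$motif[j])
        run <- substring(strrep(p$motif[j], ceiling(p$size[j] / k)),
                         1, p$size[j])
        idx <- p$position[j] + seq_len(p$size[j])
        x[idx] <- chars(run)
        expected <- rbind(expected, data.frame(
          start = p$position[j], end = p$position[j] + p$size[j],
          period = k))
      }
      # junction repair: resample background bases implicated in any run
      # that differs from the planted truth
      protected <- logical(len)
      for (j in seq_len(nrow(p))) {
        protected[p$position[j] + seq_len(p$size[j])] <- TRUE
      }
      probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
                 G = spec$gc / 2, T = (1 - spec$gc) / 2)
      for (iter in 1:100) {
        hits <- oracle_find_repeats(paste(x, collapse = ""), params)
        key <- paste(hits$start, hits$end, hits$period)
        ekey <- paste(expected$start, expected$end, expected$period)
        bad <- hits[!(key %in% ekey), , drop = FALSE]
        if (nrow(bad) == 0 && all(ekey %in% key)) break
        if (nrow(bad) == 0) {
          stop("planted repeat lost on ", nm, "; overlapping plants?")
        }
        for (b in seq_len(nrow(bad))) {
          idx <- (bad$start[b] + 1L):bad$end[b]
          idx <- idx[!protected[idx]]
          if (length(idx) == 0) {
            stop("irreparable run at ", nm, ":", bad$start[b],
                 " (entirely within planted bases)")
          }
          x[idx] <- sample(names(probs), length(idx), replace = TRUE,
                           prob = probs)
        }
      }
      seqs[[nm]] <- paste(x, collapse = "")
    }
  })
  genome <- structure(lapply(names(seqs), function(nm) {
    new_sequence_record(nm, seqs[[nm]])
  }), class = "ssr_genome")
  names(genome) <- names(seqs)
  annotation <- build_sim_annotation(spec$genes)
  lg_map <- if (is.null(spec$lg)) {
    data.frame(scaffold = character(0), lg = character(0))
  } else {
    spec$lg
  }
  truth <- data.frame(
    scaffold = plants$scaffold, start = plants$position,
    end = plants$position + plants$size,
    period = nchar(plants$motif), motif = plants$motif,
    size = plants$size, exponent = plants$size / nchar(plants$motif),
    location = plants$location,
    lg = assign_linkage_group(plants$scaffold, lg_map),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  out <- list(genome = genome, annotation = annotation, lg_map = lg_map,
              truth = truth, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(dir, "genome.fasta"))
    write_gff3(annotation, file.path(dir, "annotation.gff3"))
    write.table(lg_map, file.path(dir, "lg_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    tt <- truth
    tt$start <- tt$start + 1L
    write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(spec$gene_annotations)) {
      write.table(spec$gene_annotations,
                  file.path(dir, "gene_annotations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' A canned 20-plant fixture specification
#'
#' Three scaffolds (~100 kb total), five two-exon genes, and twenty
#' planted repeats covering periods 2-6, both length classes, fractional
#' exponents and all four genomic contexts, with two scaffolds mapped to
#' linkage groups and one left unplaced.
#'
#' @param seed integer seed
#' @return a `sim_spec`
#' @export
example_sim_spec <- function(seed = 1L) {
  scaffolds <- data.frame(name = c("sA", "sB", "sC"),
                          length = c(40000L, 40000L, 22000L))
  gene <- function(id, sc, strand, start, end, exons) {
    list(gene_id = id, scaffold = sc, strand = strand,
         start = start, end = end,
         exons = matrix(exons, ncol = 2, byrow = TRUE))
  }
  genes <- list(
    gene("geneA1", "sA", "+", 5000L, 9000L, c(5000L, 6200L, 7000L, 9000L)),
    gene("geneA2", "sA", "-", 15000L, 19000L, c(15000L, 16000L, 16800L, 19000L)),
    gene("geneB1", "sB", "+", 6000L, 10000L, c(6000L, 7200L, 8000L, 10000L)),
    gene("geneB2", "sB", "+", 20000L, 24000L, c(20000L, 21000L, 21800L, 24000L)),
    gene("geneC1", "sC", "+", 3000L, 7000L, c(3000L, 4000L, 4800L, 7000L))
  )
  plants <- data.frame(
    scaffold = c("sA", "sA", "sA", "sA", "sA", "sA", "sA", "sA", "sA", "sA",
                 "sB", "sB", "sB", "sB", "sB", "sB", "sB", "sB",
                 "sC", "sC"),
    position = c(5100L, 5800L, 6192L, 6500L, 7400L, 11000L, 12000L,
                 15200L, 16300L, 16792L,
                 6300L, 7500L, 7194L, 8500L, 20200L, 21300L, 15000L, 30000L,
                 4300L, 10000L),
    motif = c("AGC", "AG", "AAG", "AT", "ACGT", "AATC", "AACGT",
              "ACG", "AATGC", "AC",
              "AGG", "AAT", "AT", "AAGCGT", "CT", "GATC", "ATCC", "AATAT",
              "AAC", "ATGCAT"),
    size = c(18L, 20L, 16L, 14L, 16L, 20L, 22L,
             15L, 17L, 16L,
             12L, 21L, 12L, 24L, 13L, 14L, 16L, 25L,
             12L, 30L),
    stringsAsFactors = FALSE
  )
  lg <- data.frame(scaffold = c("sA", "sB"), lg = c("LG1", "LG2"),
                   stringsAsFactors = FALSE)
  gene_annotations <- data.frame(
    gene_id = c("geneA1", "geneA2", "geneB1", "geneB2", "geneC1"),
    annotation = c("cellulose synthase-like protein",
                   "pectin lyase-like protein",
                   "ethylene response factor",
                   "polygalacturonase",
                   "auxin-responsive protein"),
    go = c("GO:0016760", "GO:0030570", "GO:0003700", "GO:0004650",
           "GO:0009733"),
    stringsAsFactors = FALSE
  )
  sim_spec(scaffolds, plants, genes, lg, gene_annotations, gc = 0.35,
           seed = seed)
}
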
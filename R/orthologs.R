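# Candidate-gene marker nomination from protein alignment hit tables.
#
# Input is an extended tabular alignment format (tab-separated, columns
# qseqid, sseqid, evalue, ppos, length, qlen, slen): the standard 12-column
# tabular output reduced to the fields the filter needs, plus query and
# subject lengths and percent positives. "Similarity" is percent positives
# by default (a similarity, not an identity, measure); coverage is
# alignment length over each sequence's full length. All comparisons are
# inclusive.

HIT_COLUMNS <- c("qseqid", "sseqid", "evalue", "ppos", "length", "qlen", "slen")

#' Read an extended tabular protein-alignment hit table
#'
#' Tab-separated with columns `qseqid`, `sseqid`, `evalue`, `ppos`
#' (percent positives), `length` (alignment length), `qlen`, `slen`.
#' A header row naming these columns is optional.
#'
#' @param path path to the TSV
#' @return data.frame with the seven columns above
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("^qseqid\\b", first)
  df <- if (has_header) {
    read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, header = FALSE, col.names = HIT_COLUMNS,
               stringsAsFactors = FALSE)
  }
  missing <- setdiff(HIT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("evalue", "ppos", "length", "qlen", "slen")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df[, HIT_COLUMNS]
}

#' Ortholog filter thresholds
#'
#' Defaults encode the stringent ortholog-assessment criteria: E-value at
#' most 1e-30, similarity (percent positives) at least 50%, and both query
#' and hit coverage at least 75%.
#'
#' @param max_evalue largest accepted E-value
#' @param min_similarity minimum percent similarity
#' @param min_query_coverage,min_hit_coverage minimum percent coverage of
#'   the query / subject sequence by the alignment
#' @param use_identity if TRUE, the `pident` column is used instead of
#'   `ppos` for the similarity gate (for tables carrying percent identity)
#' @return an `ortholog_filter` list
#' @export
ortholog_filter <- function(max_evalue = 1e-30, min_similarity = 50,
                            min_query_coverage = 75, min_hit_coverage = 75,
                            use_identity = FALSE) {
  stopifnot(max_evalue >= 0,
            min_similarity >= 0, min_similarity <= 100,
            min_query_coverage >= 0, min_query_coverage <= 100,
            min_hit_coverage >= 0, min_hit_coverage <= 100)
  structure(list(max_evalue = max_evalue, min_similarity = min_similarity,
                 min_query_coverage = min_query_coverage,
                 min_hit_coverage = min_hit_coverage,
                 use_identity = isTRUE(use_identity)),
            class = "ortholog_filter")
}

#' Filter alignment hits by ortholog criteria
#'
#' Keeps a hit iff `evalue <= max_evalue`, similarity `>= min_similarity`,
#' `100 * length / qlen >= min_query_coverage` and
#' `100 * length / slen >= min_hit_coverage` (all inclusive).
#'
#' @param hits data.frame from [read_hit_table()]
#' @param filter an [ortholog_filter()]
#' @return the surviving rows of `hits`
#' @export
filter_hits <- function(hits, filter = ortholog_filter()) {
  stopifnot(inherits(filter, "ortholog_filter"))
  zero <- hits$qlen <= 0 | hits$slen <= 0
  if (any(zero)) {
    stop("zero-length query/subject in hit record(s): ",
         paste(paste(hits$qseqid[zero], hits$sseqid[zero], sep = "-"),
               collapse = ", "))
  }
  odd <- hits$length > hits$qlen + hits$slen
  if (any(odd)) {
    warning("alignment longer than query + subject for record(s): ",
            paste(hits$qseqid[odd], collapse = ", "))
  }
  sim <- if (filter$use_identity) hits$pident else hits$ppos
  keep <- hits$evalue <= filter$max_evalue &
    sim >= filter$min_similarity &
    100 * hits$length / hits$qlen >= filter$min_query_coverage &
    100 * hits$length / hits$slen >= filter$min_hit_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per subject gene
#'
#' Deduplicates to one row per subject: lowest E-value, ties broken by
#' highest similarity. Idempotent.
#'
#' @param hits data.frame of (filtered) hit records
#' @return one row per `sseqid`
#' @export
best_hit_per_subject <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$sseqid, hits$evalue, -hits$ppos)
  out <- hits[ord, , drop = FALSE]
  out <- out[!duplicated(out$sseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate candidate-gene markers from filtered hits and the atlas
#'
#' Joins the subject genes surviving [filter_hits()] to the genic atlas
#' records that carry designed primers. A gene hit by several queries is
#' nominated once, with all passing queries listed.
#'
#' @param filtered_hits data.frame from [filter_hits()]
#' @param atlas data.frame from [build_atlas()]
#' @return data.frame: `gene_id`, `n_ssrs`, `n_exonic`, `n_intronic`,
#'   `n_junction`, `best_query`, `best_evalue`, `queries`
#' @export
nominate_genes <- function(filtered_hits, atlas) {
  genic <- atlas[atlas$location %in% c("exon", "exon_intron", "intron") &
                   atlas$primer_status == "ok", , drop = FALSE]
  genes <- intersect(unique(filtered_hits$sseqid), unique(genic$gene_id))
  rows <- lapply(genes, function(g) {
    a <- genic[genic$gene_id == g, , drop = FALSE]
    h <- filtered_hits[filtered_hits$sseqid == g, , drop = FALSE]
    h <- h[order(h$evalue, -h$ppos), , drop = FALSE]
    data.frame(gene_id = g, n_ssrs = nrow(a),
               n_exonic = sum(a$location == "exon"),
               n_intronic = sum(a$location == "intron"),
               n_junction = sum(a$location == "exon_intron"),
               best_query = h$qseqid[1], best_evalue = h$evalue[1],
               queries = paste(unique(h$qseqid), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_ssrs = integer(0),
                      n_exonic = integer(0), n_intronic = integer(0),
                      n_junction = integer(0), best_query = character(0),
                      best_evalue = numeric(0), queries = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$gene_id), , drop = FALSE]
}

#' Repeats per gene over a gene set
#'
#' Counts genic atlas repeats with designed primers per gene of the set;
#' genes with none are excluded from the denominator (the mean is over
#' genes that actually carry a marker).
#'
#' @param atlas data.frame from [build_atlas()]
#' @param gene_set character vector of gene ids (non-empty)
#' @return list with `per_gene` (data.frame `gene_id`, `n_ssrs`),
#'   `n_genes` (genes with >= 1 marker), `total` and `mean` (one decimal,
#'   half-up; see [per_gene_mean()])
#' @export
ssrs_per_gene <- function(atlas, gene_set) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  genic <- atlas[atlas$location %in% c("exon", "exon_intron", "intron") &
                   atlas$primer_status == "ok" &
                   atlas$gene_id %in% gene_set, , drop = FALSE]
  tab <- table(genic$gene_id)
  per_gene <- data.frame(gene_id = names(tab), n_ssrs = as.integer(tab),
                         stringsAsFactors = FALSE)
  n_genes <- nrow(per_gene)
  total <- sum(per_gene$n_ssrs)
  list(per_gene = per_gene, n_genes = n_genes, total = total,
       mean = if (n_genes > 0) per_gene_mean(total, n_genes) else NA_real_)
}
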
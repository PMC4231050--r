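# Genomic context classification.
#
# Each repeat is assigned exactly one of four categories against the gene
# annotation, with priority exon > exon_intron > intron > intergenic:
#   exon        entirely within a single exon (or CDS segment, mode "cds")
#               of any transcript of a containing gene;
#   exon_intron inside some transcript, overlapping both exonic and
#               intronic sequence (a splice-junction repeat);
#   intron      entirely within the gap between two consecutive exons of
#               some transcript;
#   intergenic  everything else, including repeats that straddle a gene
#               boundary (flagged, since they are neither cleanly genic
#               nor cleanly intergenic).
# Introns are always derived as gaps between consecutive segments within
# a transcript, never read from GFF intron features. With mode "cds" the
# CDS segments play the role of exons throughout, so UTR sequence counts
# as "intronic" gap -- the stricter coding-region reading.

LOCATION_LEVELS <- c("exon", "exon_intron", "intron", "intergenic")

#' Classify one repeat against an annotation
#'
#' @param hit a single-row data.frame from [find_repeats()] (or any list
#'   with `scaffold`, `start`, `end` in 0-based half-open coordinates)
#' @param annotation an `ssr_annotation` from [read_gff3()]
#' @param mode `"exon"` (default) to classify against exon features, or
#'   `"cds"` to require containment in CDS segments for the exonic call
#' @return list with `location` (one of exon, exon_intron, intron,
#'   intergenic), `boundary` (TRUE when the repeat overlaps a gene span
#'   without being contained in it), and `gene_ids` (ids of genes whose
#'   span contains the repeat, sorted by coordinate)
#' @export
classify_location <- function(hit, annotation, mode = c("exon", "cds")) {
  mode <- match.arg(mode)
  df <- as.data.frame(hit)[1, , drop = FALSE]
  res <- classify_locations(df, annotation, mode)
  list(location = res$location[1], boundary = res$boundary[1],
       gene_ids = if (nzchar(res$gene_ids[1])) {
         strsplit(res$gene_ids[1], ",", fixed = TRUE)[[1]]
       } else {
         character(0)
       })
}

#' Classify many repeats against an annotation
#'
#' Vectorized form of [classify_location()].
#'
#' @param hits data.frame from [find_repeats()] / [scan_genome()]
#' @param annotation an `ssr_annotation`
#' @param mode `"exon"` or `"cds"`; see [classify_location()]
#' @return data.frame aligned with `hits`: columns `location`, `boundary`,
#'   `gene_id` (first containing gene by coordinate, "" if none) and
#'   `gene_ids` (comma-joined list)
#' @export
classify_locations <- function(hits, annotation, mode = c("exon", "cds")) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "ssr_annotation"))
  n <- nrow(hits)
  location <- rep("intergenic", n)
  boundary <- rep(FALSE, n)
  gene_id <- rep("", n)
  gene_ids <- rep("", n)
  if (n > 0 && length(annotation$genes) > 0) {
    q <- GenomicRanges::GRanges(hits$scaffold,
                                IRanges::IRanges(hits$start + 1L, hits$end))
    # scaffolds absent from the annotation are legitimate (-> intergenic);
    # silence the seqlevels mismatch chatter that GRanges emits for them
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, annotation$index))
    byhit <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (key in names(byhit)) {
      i <- as.integer(key)
      s <- hits$start[i]; e <- hits$end[i]
      cand <- annotation$genes[S4Vectors::mcols(annotation$index)$gene_id[byhit[[key]]]]
      contains <- vapply(cand, function(g) g$start <= s && e <= g$end, TRUE)
      if (!any(contains)) {        # overlaps a gene but straddles its boundary
        boundary[i] <- TRUE
        next
      }
      inside <- cand[contains]
      ord <- order(vapply(inside, `[[`, 0L, "start"),
                   vapply(inside, `[[`, "", "gene_id"))
      inside <- inside[ord]
      ids <- vapply(inside, `[[`, "", "gene_id")
      gene_ids[i] <- paste(ids, collapse = ",")
      gene_id[i] <- ids[1]
      location[i] <- classify_within_genes(s, e, inside, mode)
    }
  }
  data.frame(location = location, boundary = boundary,
             gene_id = gene_id, gene_ids = gene_ids,
             stringsAsFactors = FALSE)
}

# category of interval [s,e) known to be contained in >=1 gene span
classify_within_genes <- function(s, e, genes, mode) {
  in_single_segment <- FALSE
  junction <- FALSE
  in_intron <- FALSE
  for (g in genes) {
    for (tx in g$transcripts) {
      seg <- if (mode == "cds") tx$cds else tx$exons
      if (nrow(seg) == 0) next
      if (any(seg[, 1] <= s & e <= seg[, 2])) in_single_segment <- TRUE
      tx_lo <- min(seg[, 1]); tx_hi <- max(seg[, 2])
      if (tx_lo <= s && e <= tx_hi) {
        ov_seg <- sum(pmax(0L, pmin(e, seg[, 2]) - pmax(s, seg[, 1])))
        if (ov_seg > 0 && ov_seg < e - s) junction <- TRUE
      }
      if (nrow(seg) > 1) {
        istart <- seg[-nrow(seg), 2]
        iend <- seg[-1, 1]
        if (any(istart <= s & e <= iend)) in_intron <- TRUE
      }
    }
  }
  if (in_single_segment) "exon"
  else if (junction) "exon_intron"
  else if (in_intron) "intron"
  else "intergenic"
}

#' Assign linkage groups to scaffolds
#'
#' @param scaffold character vector of scaffold names
#' @param lg_map data.frame from [read_lg_map()]
#' @return character vector of linkage-group labels; scaffolds absent from
#'   the map are "Un" (unplaced)
#' @export
assign_linkage_group <- function(scaffold, lg_map) {
  stopifnot(is.data.frame(lg_map), all(c("scaffold", "lg") %in% names(lg_map)))
  lab <- lg_map$lg[match(scaffold, lg_map$scaffold)]
  lab[is.na(lab)] <- "Un"
  lab
}

#' Fraction of genes carrying at least one genic repeat
#'
#' @param atlas data.frame from [build_atlas()]
#' @param annotation the `ssr_annotation` the atlas was classified against
#' @return list with `n_genes_with_ssr`, `n_genes` and `percent` (whole
#'   percent, rounded half-up)
#' @export
genes_with_ssr_fraction <- function(atlas, annotation) {
  stopifnot(inherits(annotation, "ssr_annotation"))
  n_genes <- length(annotation$genes)
  if (n_genes == 0) stop("annotation contains no genes")
  genic <- atlas$location %in% c("exon", "exon_intron", "intron")
  with_ssr <- unique(unlist(strsplit(atlas$gene_ids[genic], ",", fixed = TRUE)))
  with_ssr <- intersect(with_ssr, names(annotation$genes))
  list(n_genes_with_ssr = length(with_ssr), n_genes = n_genes,
       percent = percent_of(length(with_ssr), n_genes))
}
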
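# The atlas: joined marker records and summary statistics.
#
# An atlas record is one detected repeat joined with its canonical motif
# class, length class (I: >= 20 bases, II: 12-19 bases), genomic context,
# gene annotation, linkage group and (optionally) a designed primer pair.
# Summaries are cross-tabulations over the atlas dimensions with
# percentage columns rounded half-up to one decimal, the convention used
# in marker survey tables.

#' Length class of a repeat array
#'
#' Class I arrays (>= 20 bases) are typically hypervariable and the
#' preferred markers for diversity studies; class II covers 12-19 bases.
#'
#' @param size array size(s) in bases, all >= 12
#' @return character vector of "I" / "II"
#' @export
bin_length_class <- function(size) {
  if (any(size < 12)) stop("length class is defined for sizes >= 12")
  ifelse(size >= 20, "I", "II")
}

#' Deterministic repeat identifier
#'
#' `<scaffold>:<start1>-<end1>:<period>` with printed 1-based inclusive
#' coordinates; collision-free because maximal runs are unique per period.
#'
#' @param hits data.frame from [find_repeats()]
#' @return character vector of ids
#' @export
ssr_ids <- function(hits) {
  sprintf("%s:%d-%d:%d", hits$scaffold, hits$start + 1L, hits$end, hits$period)
}

#' Build the joined marker atlas
#'
#' @param hits data.frame from [find_repeats()] / [scan_genome()]
#' @param contexts data.frame from [classify_locations()], either aligned
#'   row-by-row with `hits` or carrying an `ssr_id` column
#' @param lg_map data.frame from [read_lg_map()] (NULL: all "Un")
#' @param gene_annotations optional data.frame from
#'   [read_gene_annotations()]
#' @param primers optional data.frame from [design_primers()], keyed by
#'   `ssr_id`; hits without a primer row are marked `no_primer` with
#'   reason `not_attempted`, failed designs keep their reported reason
#' @return data.frame with one row per hit: identification, motif class,
#'   length class, context, annotation, linkage group and primer fields
#' @export
build_atlas <- function(hits, contexts, lg_map = NULL,
                        gene_annotations = NULL, primers = NULL) {
  ids <- ssr_ids(hits)
  if (!is.null(contexts$ssr_id)) {
    orphan <- setdiff(contexts$ssr_id, ids)
    if (length(orphan) > 0) {
      stop("context rows with no matching hit: ", paste(orphan, collapse = ", "))
    }
    if (!setequal(contexts$ssr_id, ids)) {
      stop("hits with no context row: ",
           paste(setdiff(ids, contexts$ssr_id), collapse = ", "))
    }
    contexts <- contexts[match(ids, contexts$ssr_id), , drop = FALSE]
  } else if (nrow(contexts) != nrow(hits)) {
    stop("contexts must align with hits (", nrow(hits), " rows) or carry ssr_id")
  }
  n <- nrow(hits)
  atlas <- data.frame(
    ssr_id = ids,
    scaffold = hits$scaffold,
    start = hits$start, end = hits$end,
    motif = hits$motif,
    canonical_class = if (n) class_labels(hits$motif) else character(0),
    period = hits$period, size = hits$size, exponent = hits$exponent,
    length_class = if (n) bin_length_class(hits$size) else character(0),
    location = contexts$location,
    boundary = contexts$boundary,
    gene_id = contexts$gene_id,
    gene_ids = contexts$gene_ids,
    annotation = rep(NA_character_, n), go = rep(NA_character_, n),
    linkage_group = if (is.null(lg_map)) rep("Un", n) else
      assign_linkage_group(hits$scaffold, lg_map),
    primer_status = rep("no_primer", n),
    primer_reason = rep("not_attempted", n),
    fwd_primer = rep(NA_character_, n), rev_primer = rep(NA_character_, n),
    product_size = rep(NA_integer_, n), tm_fwd = rep(NA_real_, n),
    tm_rev = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(gene_annotations) && nrow(atlas) > 0) {
    j <- match(atlas$gene_id, gene_annotations$gene_id)
    atlas$annotation <- gene_annotations$annotation[j]
    atlas$go <- gene_annotations$go[j]
  }
  if (!is.null(primers) && nrow(primers) > 0) {
    orphan <- setdiff(primers$ssr_id, ids)
    if (length(orphan) > 0) {
      stop("primer rows with no matching hit: ", paste(orphan, collapse = ", "))
    }
    j <- match(atlas$ssr_id, primers$ssr_id)
    hit <- !is.na(j)
    atlas$primer_status[hit] <- primers$status[j[hit]]
    atlas$primer_reason[hit] <- primers$reason[j[hit]]
    ok <- hit & primers$status[j] == "ok"
    atlas$fwd_primer[ok] <- primers$fwd[j[ok]]
    atlas$rev_primer[ok] <- primers$rev[j[ok]]
    atlas$product_size[ok] <- primers$product_size[j[ok]]
    atlas$tm_fwd[ok] <- primers$tm_fwd[j[ok]]
    atlas$tm_rev[ok] <- primers$tm_rev[j[ok]]
  }
  rownames(atlas) <- NULL
  atlas
}

ATLAS_DIMS <- c("location", "period", "motif_class", "lg", "length_class")

atlas_dim_values <- function(atlas, dim) {
  switch(dim,
    location = factor(atlas$location, levels = LOCATION_LEVELS),
    period = factor(atlas$period, levels = sort(unique(atlas$period))),
    motif_class = factor(atlas$canonical_class),
    lg = factor(atlas$linkage_group),
    length_class = factor(atlas$length_class, levels = c("I", "II")),
    stop("unknown atlas dimension '", dim, "'; use one of: ",
         paste(ATLAS_DIMS, collapse = ", "))
  )
}

#' Cross-tabulate an atlas over two dimensions
#'
#' @param atlas data.frame from [build_atlas()]
#' @param row_dim,col_dim one of `"location"`, `"period"`,
#'   `"motif_class"`, `"lg"`, `"length_class"`
#' @param percent_margin `"col"` (default; each column of percentages sums
#'   to 100), `"row"`, or `"total"`
#' @return an `ssr_summary_table`; see [summary_table()]
#' @export
summarize_atlas <- function(atlas, row_dim, col_dim, percent_margin = "col") {
  counts <- table(atlas_dim_values(atlas, row_dim),
                  atlas_dim_values(atlas, col_dim))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  summary_table(counts, percent_margin)
}

#' Summary table with totals and percentage columns
#'
#' Builds the totals row/column and half-up one-decimal percentages from a
#' plain counts matrix, so that the same arithmetic can be applied to
#' counts produced by this package or to previously published count
#' tables.
#'
#' @param counts integer matrix of counts (no totals)
#' @param percent_margin `"col"`, `"row"` or `"total"`: which margin the
#'   cell percentages are normalized by
#' @return an `ssr_summary_table`: list with `counts` (with `Total`
#'   row/column), `percents` (cells), `row_pct` / `col_pct` (margin totals
#'   as percent of the grand total, one decimal), `grand` and
#'   `percent_margin`
#' @export
summary_table <- function(counts, percent_margin = c("col", "row", "total")) {
  percent_margin <- match.arg(percent_margin)
  counts <- as.matrix(counts)
  grand <- sum(counts)
  if (grand == 0) stop("summary_table(): all counts are zero")
  rs <- rowSums(counts); cs <- colSums(counts)
  denom <- switch(percent_margin,
    col = matrix(cs, nrow = nrow(counts), ncol = ncol(counts), byrow = TRUE),
    row = matrix(rs, nrow = nrow(counts), ncol = ncol(counts)),
    total = matrix(grand, nrow = nrow(counts), ncol = ncol(counts))
  )
  pct <- ifelse(denom > 0, round_half_up(100 * counts / denom, 1), 0)
  dimnames(pct) <- dimnames(counts)
  full <- rbind(cbind(counts, Total = rs), Total = c(cs, grand))
  structure(list(counts = full, percents = pct,
                 row_pct = round_half_up(100 * rs / grand, 1),
                 col_pct = round_half_up(100 * cs / grand, 1),
                 grand = grand, percent_margin = percent_margin),
            class = "ssr_summary_table")
}

#' @export
print.ssr_summary_table <- function(x, ...) {
  cat("ssr_summary_table (", x$grand, " repeats; percents per ",
      x$percent_margin, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Write a summary table as TSV (counts, then percentages)
#'
#' @param st an `ssr_summary_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_summary <- function(st, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(data.frame(dim = rownames(st$counts), st$counts,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  write.table(data.frame(dim = rownames(st$percents), st$percents,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker screen percentage
#'
#' Percentage of screened markers that were polymorphic (or amplified,
#' etc.), rounded half-up to the nearest whole percent.
#'
#' @param n_polymorphic markers with the outcome of interest
#' @param n_screened markers screened, > 0
#' @return integer percent
#' @export
#' @examples
#' screen_summary(19, 73)  # 26
screen_summary <- function(n_polymorphic, n_screened) {
  if (n_screened <= 0) stop("n_screened must be > 0")
  if (n_polymorphic < 0 || n_polymorphic > n_screened) {
    stop("n_polymorphic must be between 0 and n_screened")
  }
  as.integer(percent_of(n_polymorphic, n_screened, 0))
}

#' Mean markers per gene
#'
#' @param n_ssrs total repeats across the gene set
#' @param n_genes genes carrying at least one repeat, > 0
#' @return mean repeats per gene, rounded half-up to one decimal
#' @export
per_gene_mean <- function(n_ssrs, n_genes) {
  if (n_genes <= 0) stop("n_genes must be > 0")
  if (n_ssrs < 0) stop("n_ssrs must be >= 0")
  round_half_up(n_ssrs / n_genes, 1)
}

ATLAS_COLUMNS <- c("ssr_id", "scaffold", "start", "end", "motif",
                   "canonical_class", "period", "size", "exponent",
                   "length_class", "location", "gene_id", "annotation",
                   "GO", "linkage_group", "fwd_primer", "rev_primer",
                   "product_size", "Tm_fwd", "Tm_rev")

#' Write an atlas as TSV
#'
#' Coordinates are printed 1-based inclusive; internal half-open
#' `[99, 111)` prints as `100..111`.
#'
#' @param records data.frame from [build_atlas()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_atlas <- function(records, path) {
  out <- data.frame(
    ssr_id = records$ssr_id, scaffold = records$scaffold,
    start = records$start + 1L, end = records$end,
    motif = records$motif, canonical_class = records$canonical_class,
    period = records$period, size = records$size,
    exponent = records$exponent, length_class = records$length_class,
    location = records$location, gene_id = records$gene_id,
    annotation = records$annotation, GO = records$go,
    linkage_group = records$linkage_group,
    fwd_primer = records$fwd_primer, rev_primer = records$rev_primer,
    product_size = records$product_size,
    Tm_fwd = records$tm_fwd, Tm_rev = records$tm_rev,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an atlas TSV written by [write_atlas()]
#'
#' @param path path to the TSV
#' @return data.frame with internal 0-based half-open coordinates; columns
#'   as in [build_atlas()] minus the fields that are not serialized
#'   (`boundary`, `gene_ids`, primer status)
#' @export
read_atlas <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = c(
    ssr_id = "character", scaffold = "character", motif = "character",
    canonical_class = "character", length_class = "character",
    location = "character", gene_id = "character",
    annotation = "character", GO = "character",
    linkage_group = "character", fwd_primer = "character",
    rev_primer = "character"
  ))
  names(df)[names(df) == "GO"] <- "go"
  names(df)[names(df) == "Tm_fwd"] <- "tm_fwd"
  names(df)[names(df) == "Tm_rev"] <- "tm_rev"
  df$start <- as.integer(df$start) - 1L
  df
}
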
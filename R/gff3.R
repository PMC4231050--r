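# GFF3 annotation input.
#
# A deliberately small line-level reader: the pipeline needs gene / mRNA /
# exon (optionally CDS) features with Parent links, precise error messages
# carrying line numbers, and orphan-feature warnings. Coordinates are
# converted at this boundary from GFF3's 1-based inclusive convention to
# the package-internal 0-based half-open convention; interval queries
# downstream use GenomicRanges built from these values.

#' Read a GFF3 gene annotation
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon` and `CDS` features into gene
#' models. Exons (and CDS segments) are grouped per transcript per gene via
#' `Parent` attributes; an exon whose parent cannot be resolved is skipped
#' with a warning. Lines without 9 tab-separated columns are an error
#' reported with their line number.
#'
#' @param path path to a GFF3 file
#' @return an `ssr_annotation` object: list with `genes` (named list of
#'   gene models) and `index` (a [GenomicRanges::GRanges] of gene spans
#'   used for overlap lookup). Each gene model holds `gene_id`, `scaffold`,
#'   `strand`, `start`/`end` (0-based half-open span) and `transcripts`, a
#'   named list with per-transcript `exons` and `cds` interval matrices
#'   (columns `start`, `end`; 0-based half-open, sorted).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lnos <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 9)
  if (length(bad) > 0) {
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, found %d",
                 lnos[bad[1]], length(rows[[bad[1]]])))
  }
  if (length(rows) == 0) stop("GFF3 file has no feature lines: ", path)
  m <- do.call(rbind, rows)
  type   <- m[, 3]
  start0 <- as.integer(m[, 4]) - 1L   # 1-based inclusive -> 0-based half-open
  end    <- as.integer(m[, 5])
  attr_id     <- gff3_attr(m[, 9], "ID")
  attr_parent <- gff3_attr(m[, 9], "Parent")

  is_gene <- type == "gene"
  is_tx   <- type %in% c("mRNA", "transcript")
  genes <- list()
  for (i in which(is_gene)) {
    gid <- attr_id[i]
    if (is.na(gid)) gid <- sprintf("gene_%d", i)
    if (!is.na(m[i, 7]) && !(m[i, 7] %in% c("+", "-"))) {
      stop("gene ", gid, ": strand must be '+' or '-', got '", m[i, 7], "'")
    }
    genes[[gid]] <- list(
      gene_id = gid, scaffold = m[i, 1], strand = m[i, 7],
      start = start0[i], end = end[i],
      transcripts = list(), annotation = NA_character_, go = NA_character_
    )
  }
  tx2gene <- character(0)
  for (i in which(is_tx)) {
    tid <- attr_id[i]
    par <- attr_parent[i]
    if (is.na(tid)) tid <- sprintf("tx_%d", i)
    if (is.na(par) || is.null(genes[[par]])) {
      warning("transcript '", tid, "' has no resolvable gene parent; skipped")
      next
    }
    tx2gene[tid] <- par
    genes[[par]]$transcripts[[tid]] <- list(
      exons = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))),
      cds   = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
    )
  }
  for (i in which(type %in% c("exon", "CDS"))) {
    slot <- if (type[i] == "exon") "exons" else "cds"
    resolved <- FALSE
    for (par in strsplit(attr_parent[i], ",", fixed = TRUE)[[1]]) {
      if (is.na(par)) break
      gid <- tx2gene[par]
      tid <- par
      if (is.na(gid) && !is.null(genes[[par]])) {
        # exon attached directly to a gene: use an implicit transcript
        gid <- par
        tid <- paste0(par, ".t0")
        if (is.null(genes[[gid]]$transcripts[[tid]])) {
          genes[[gid]]$transcripts[[tid]] <- list(
            exons = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))),
            cds   = matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
          )
          tx2gene[tid] <- gid
        }
      }
      if (is.na(gid)) next
      genes[[gid]]$transcripts[[tid]][[slot]] <-
        rbind(genes[[gid]]$transcripts[[tid]][[slot]],
              c(start = start0[i], end = end[i]))
      resolved <- TRUE
    }
    if (!resolved) {
      warning(type[i], " at ", m[i, 1], ":", m[i, 4], "-", m[i, 5],
              " has no resolvable parent transcript; skipped")
    }
  }
  genes <- lapply(genes, validate_gene_model)
  new_annotation_set(genes)
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

validate_gene_model <- function(g) {
  for (tid in names(g$transcripts)) {
    for (slot in c("exons", "cds")) {
      iv <- g$transcripts[[tid]][[slot]]
      if (nrow(iv) == 0) next
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
        stop("gene ", g$gene_id, " transcript ", tid, ": overlapping ", slot)
      }
      if (any(iv[, 1] < g$start) || any(iv[, 2] > g$end)) {
        stop("gene ", g$gene_id, " transcript ", tid, ": ", slot,
             " outside gene span")
      }
      g$transcripts[[tid]][[slot]] <- iv
    }
  }
  g
}

#' Construct an annotation set from gene models
#'
#' @param genes named list of gene models (see [read_gff3()] for fields)
#' @return an `ssr_annotation` object
#' @export
new_annotation_set <- function(genes) {
  genes <- lapply(genes, validate_gene_model)
  if (length(genes) > 0) {
    index <- GenomicRanges::GRanges(
      seqnames = vapply(genes, `[[`, "", "scaffold"),
      ranges = IRanges::IRanges(
        start = vapply(genes, function(g) g$start + 1L, 1L),
        end   = vapply(genes, function(g) g$end, 1L)
      ),
      gene_id = names(genes)
    )
  } else {
    index <- GenomicRanges::GRanges()
  }
  structure(list(genes = genes, index = index), class = "ssr_annotation")
}

#' @export
print.ssr_annotation <- function(x, ...) {
  ntx <- sum(vapply(x$genes, function(g) length(g$transcripts), 0L))
  cat("ssr_annotation:", length(x$genes), "gene(s),", ntx, "transcript(s)\n")
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()] for the feature types this package uses;
#' coordinates are printed 1-based inclusive.
#'
#' @param annotation an `ssr_annotation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "ssr_annotation"))
  out <- c("##gff-version 3")
  for (g in annotation$genes) {
    out <- c(out, sprintf("%s\tssratlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          g$scaffold, g$start + 1L, g$end, g$strand, g$gene_id))
    for (tid in names(g$transcripts)) {
      tx <- g$transcripts[[tid]]
      ex <- tx$exons
      if (nrow(ex) > 0) {
        tspan <- c(min(ex[, 1]), max(ex[, 2]))
      } else {
        tspan <- c(g$start, g$end)
      }
      out <- c(out, sprintf("%s\tssratlas\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            g$scaffold, tspan[1] + 1L, tspan[2], g$strand, tid, g$gene_id))
      for (k in seq_len(nrow(ex))) {
        out <- c(out, sprintf("%s\tssratlas\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                              g$scaffold, ex[k, 1] + 1L, ex[k, 2], g$strand, tid))
      }
      cd <- tx$cds
      for (k in seq_len(nrow(cd))) {
        out <- c(out, sprintf("%s\tssratlas\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                              g$scaffold, cd[k, 1] + 1L, cd[k, 2], g$strand, tid))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a scaffold-to-linkage-group map
#'
#' Two-column tab-separated file: `scaffold<TAB>LG_label`, no header.
#' Duplicate rows are collapsed; a scaffold mapped to two different labels
#' is an error.
#'
#' @param path path to the TSV
#' @return data.frame with columns `scaffold`, `lg`
#' @export
read_lg_map <- function(path) {
  if (!file.exists(path)) stop("linkage-group map not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("scaffold", "lg"),
                   colClasses = "character")
  df <- unique(df)
  dup <- unique(df$scaffold[duplicated(df$scaffold)])
  if (length(dup) > 0) {
    stop("conflicting linkage-group labels for scaffold(s): ",
         paste(dup, collapse = ", "))
  }
  df
}

#' Read a gene annotation / GO term table
#'
#' Tab-separated with header columns `gene_id`, `annotation`, `go`
#' (missing columns are filled with NA).
#'
#' @param path path to the TSV
#' @return data.frame with columns `gene_id`, `annotation`, `go`
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) stop("gene annotation table not found: ", path)
  df <- read.delim(path, header = TRUE, colClasses = "character")
  if (!"gene_id" %in% names(df)) stop("gene annotation table needs a 'gene_id' column")
  for (col in c("annotation", "go")) if (!col %in% names(df)) df[[col]] <- NA_character_
  df[, c("gene_id", "annotation", "go")]
}
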
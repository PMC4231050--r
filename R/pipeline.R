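# Pipeline driver: binds the stages into the atlas workflow.
#
# Every stage reads the previous stage's TSV so stages are independently
# runnable; outputs carry no timestamps, so re-running a stage with
# unchanged inputs is byte-identical. A JSON manifest records the
# configuration, its hash, package/R versions and the seed.

#' Pipeline configuration
#'
#' @param fasta path to the genome FASTA (required by most stages)
#' @param gff3 path to the GFF3 annotation (classification stage)
#' @param lg_map path to the scaffold-to-linkage-group TSV
#' @param hits path to an extended tabular alignment hit table
#'   (ortholog stage)
#' @param gene_annotations path to a gene annotation/GO TSV
#' @param out_dir output directory
#' @param mode classification mode, `"exon"` or `"cds"`
#' @param scan a [scan_params()] object
#' @param primer a [primer_params()] object
#' @param ortholog an [ortholog_filter()] object
#' @param seed integer seed recorded in the manifest and used by
#'   simulation stages
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(fasta = NULL, gff3 = NULL, lg_map = NULL,
                            hits = NULL, gene_annotations = NULL,
                            out_dir = "ssratlas_out",
                            mode = c("exon", "cds"),
                            scan = scan_params(),
                            primer = primer_params(),
                            ortholog = ortholog_filter(),
                            seed = 1L) {
  mode <- match.arg(mode)
  for (p in c(fasta, gff3, lg_map, hits, gene_annotations)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(fasta = fasta, gff3 = gff3, lg_map = lg_map, hits = hits,
                 gene_annotations = gene_annotations, out_dir = out_dir,
                 mode = mode, scan = scan, primer = primer,
                 ortholog = ortholog, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value` (\code{#} comments allowed). File keys:
#' `fasta`, `gff3`, `lg_map`, `hits`, `gene_annotations`, `out_dir`,
#' `mode`, `seed`; scan keys `scan.min_size`, `scan.min_period`,
#' `scan.max_period`, `scan.min_exponent`; primer keys `primer.<field>`
#' for any [primer_params()] scalar field; ortholog keys
#' `ortholog.<field>` for [ortholog_filter()] fields. Unknown keys are an
#' error. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path path to the configuration file
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9._]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3)) {
    stop("config line not of the form key = value: ",
         lines[which(lengths(kv) != 3)[1]])
  }
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  base_dir <- dirname(normalizePath(path))
  args <- list()
  scan_args <- list(); primer_args <- list(); orth_args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% c("fasta", "gff3", "lg_map", "hits", "gene_annotations")) {
      args[[k]] <- if (file.exists(v)) v else file.path(base_dir, v)
    } else if (k %in% c("out_dir", "mode")) {
      args[[k]] <- v
    } else if (k == "seed") {
      args[[k]] <- as.integer(v)
    } else if (startsWith(k, "scan.")) {
      scan_args[[sub("^scan\\.", "", k)]] <- as.numeric(v)
    } else if (startsWith(k, "primer.")) {
      primer_args[[sub("^primer\\.", "", k)]] <- as.numeric(v)
    } else if (startsWith(k, "ortholog.")) {
      orth_args[[sub("^ortholog\\.", "", k)]] <- as.numeric(v)
    } else {
      stop("unknown config key: ", k)
    }
  }
  if (length(scan_args)) args$scan <- do.call(scan_params, scan_args)
  if (length(primer_args)) args$primer <- do.call(primer_params, primer_args)
  if (length(orth_args)) args$ortholog <- do.call(ortholog_filter, orth_args)
  do.call(pipeline_config, args)
}

cfg_path <- function(config, name) file.path(config$out_dir, name)

require_stage_input <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs ", path,
         "; run the '", producer, "' stage first")
  }
  path
}

#' Run pipeline stages
#'
#' Stages: `scan` (detect repeats), `classify` (context + linkage
#' groups), `design-primers`, `filter-orthologs`, `report` (atlas +
#' summary tables), `simulate` (write the canned synthetic fixture into
#' `out_dir` and point the config at it), and `all`.
#'
#' @param config a [pipeline_config()]
#' @param stages character vector of stage names, or `"all"`
#' @return the (possibly updated) config, invisibly
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) {
    stages <- c("scan", "classify", "design-primers",
                if (!is.null(config$hits)) "filter-orthologs", "report")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in stages) {
    message("[ssratlas] stage: ", stage)
    config <- switch(stage,
      "simulate" = stage_simulate(config),
      "scan" = stage_scan(config),
      "classify" = stage_classify(config),
      "design-primers" = stage_design_primers(config),
      "filter-orthologs" = stage_filter_orthologs(config),
      "report" = stage_report(config),
      stop("unknown stage: ", stage)
    )
  }
  write_manifest(config)
  invisible(config)
}

stage_simulate <- function(config) {
  fixture_dir <- cfg_path(config, "fixture")
  sim <- simulate_genome(example_sim_spec(seed = config$seed), dir = fixture_dir)
  config$fasta <- file.path(fixture_dir, "genome.fasta")
  config$gff3 <- file.path(fixture_dir, "annotation.gff3")
  config$lg_map <- file.path(fixture_dir, "lg_map.tsv")
  config$gene_annotations <- file.path(fixture_dir, "gene_annotations.tsv")
  config
}

stage_scan <- function(config) {
  if (is.null(config$fasta)) stop("stage 'scan' needs a genome FASTA")
  genome <- read_fasta(config$fasta)
  hits <- scan_genome(genome, config$scan)
  write_repeats(hits, cfg_path(config, "repeats.tsv"))
  message("[ssratlas] ", nrow(hits), " repeats detected")
  config
}

stage_classify <- function(config) {
  hits <- read_repeats(require_stage_input(cfg_path(config, "repeats.tsv"),
                                           "classify", "scan"))
  ann <- if (is.null(config$gff3)) new_annotation_set(list()) else
    read_gff3(config$gff3)
  ctx <- classify_locations(hits, ann, config$mode)
  ctx$ssr_id <- ssr_ids(hits)
  lg <- if (is.null(config$lg_map)) NULL else read_lg_map(config$lg_map)
  ctx$linkage_group <- if (is.null(lg)) rep("Un", nrow(hits)) else
    assign_linkage_group(hits$scaffold, lg)
  write.table(ctx[, c("ssr_id", "location", "boundary", "gene_id",
                      "gene_ids", "linkage_group")],
              cfg_path(config, "contexts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  config
}

stage_design_primers <- function(config) {
  if (is.null(config$fasta)) stop("stage 'design-primers' needs a genome FASTA")
  hits <- read_repeats(require_stage_input(cfg_path(config, "repeats.tsv"),
                                           "design-primers", "scan"))
  genome <- read_fasta(config$fasta)
  primers <- design_primers(genome, hits, config$primer)
  write_primers(primers, cfg_path(config, "primers.tsv"))
  message("[ssratlas] primers designed for ",
          sum(primers$status == "ok"), "/", nrow(primers), " repeats")
  config
}

stage_filter_orthologs <- function(config) {
  if (is.null(config$hits)) stop("stage 'filter-orthologs' needs a hit table")
  hits <- read_hit_table(config$hits)
  kept <- filter_hits(hits, config$ortholog)
  write.table(kept, cfg_path(config, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  atlas_path <- cfg_path(config, "atlas_genic.tsv")
  if (file.exists(atlas_path)) {
    atlas <- read_atlas(atlas_path)
    atlas$primer_status <- ifelse(is.na(atlas$fwd_primer), "no_primer", "ok")
    nom <- nominate_genes(kept, atlas)
    write.table(nom, cfg_path(config, "candidate_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  config
}

stage_report <- function(config) {
  hits <- read_repeats(require_stage_input(cfg_path(config, "repeats.tsv"),
                                           "report", "scan"))
  ctx_path <- require_stage_input(cfg_path(config, "contexts.tsv"),
                                  "report", "classify")
  ctx <- read.delim(ctx_path, header = TRUE, colClasses = c(
    ssr_id = "character", location = "character", gene_id = "character",
    gene_ids = "character", linkage_group = "character"))
  for (col in c("gene_id", "gene_ids")) ctx[[col]][is.na(ctx[[col]])] <- ""
  primers_path <- cfg_path(config, "primers.tsv")
  primers <- if (file.exists(primers_path)) read_primers(primers_path) else NULL
  gene_ann <- if (is.null(config$gene_annotations)) NULL else
    read_gene_annotations(config$gene_annotations)
  lg <- if (is.null(config$lg_map)) NULL else read_lg_map(config$lg_map)
  atlas <- build_atlas(hits, ctx, lg, gene_ann, primers)
  genic <- atlas$location %in% c("exon", "exon_intron", "intron")
  write_atlas(atlas[genic, , drop = FALSE], cfg_path(config, "atlas_genic.tsv"))
  write_atlas(atlas[!genic, , drop = FALSE],
              cfg_path(config, "atlas_intergenic.tsv"))
  if (nrow(atlas) > 0) {
    write_summary(summarize_atlas(atlas, "location", "period"),
                  cfg_path(config, "summary_location_by_period.tsv"))
    write_summary(summarize_atlas(atlas, "length_class", "location"),
                  cfg_path(config, "summary_class_by_location.tsv"))
    write_summary(summarize_atlas(atlas, "location", "lg"),
                  cfg_path(config, "summary_location_by_lg.tsv"))
  } else {
    for (f in c("summary_location_by_period.tsv",
                "summary_class_by_location.tsv",
                "summary_location_by_lg.tsv")) {
      writeLines("dim", cfg_path(config, f))
    }
  }
  message("[ssratlas] atlas written: ", sum(genic), " genic, ",
          sum(!genic), " intergenic records")
  config
}

write_manifest <- function(config) {
  flat <- list(
    fasta = config$fasta, gff3 = config$gff3, lg_map = config$lg_map,
    hits = config$hits, gene_annotations = config$gene_annotations,
    out_dir = config$out_dir, mode = config$mode, seed = config$seed,
    scan = unclass(config$scan),
    primer = unclass(config$primer[setdiff(names(config$primer),
                                           "repeat_params")]),
    ortholog = unclass(config$ortholog)
  )
  canon <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  writeLines(canon, tmp)
  manifest <- list(
    config = flat,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(packageVersion("ssratlas")),
    r_version = R.version.string,
    seed = config$seed
  )
  unlink(tmp)
  jsonlite::write_json(manifest, cfg_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(config)
}
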
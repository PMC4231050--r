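# FASTA input with a soft-mask track.
#
# Sequences are uppercased on read; the positions that were lowercase in
# the file (soft-masked, e.g. by a repeat masker) are recorded per record
# as 0-based positions. Repeat scanning deliberately ignores this track --
# the genome is scanned in full -- but primer design may consult masking
# it computes itself (see dust_mask()).

#' Read a multi-record FASTA file
#'
#' @param path path to a FASTA file
#' @return an object of class `ssr_genome`: a named list of sequence
#'   records, each a list with elements `id`, `sequence` (uppercase),
#'   `length`, and `softmask` (0-based integer positions that were
#'   lowercase in the input).
#' @details Record ids are taken as the first whitespace-delimited token of
#'   the header. Duplicate ids and empty files are errors.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgtACGT"), fa)
#' g <- read_fasta(fa)
#' g$s1$sequence   # "ACGTACGT"
#' g$s1$softmask   # 0 1 2 3
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)  # BStringSet preserves case
  if (length(raw) == 0) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA record id(s): ", paste(dup, collapse = ", "))
  }
  recs <- lapply(seq_along(raw), function(i) {
    s <- as.character(raw[[i]])
    up <- toupper(s)
    mask <- which(strsplit(s, "", fixed = TRUE)[[1]] !=
                  strsplit(up, "", fixed = TRUE)[[1]]) - 1L
    new_sequence_record(ids[i], up, softmask = mask)
  })
  names(recs) <- ids
  structure(recs, class = "ssr_genome")
}

#' Construct a sequence record
#'
#' @param id scaffold identifier (non-empty string)
#' @param sequence nucleotide string; uppercased on construction
#' @param softmask 0-based integer positions that are soft-masked
#' @return a list with class `ssr_seqrec`
#' @export
new_sequence_record <- function(id, sequence, softmask = integer(0)) {
  if (!is_scalar_string(id) || !nzchar(id)) stop("record id must be a non-empty string")
  sequence <- toupper(sequence)
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         softmask = as.integer(softmask)),
    class = "ssr_seqrec"
  )
}

#' @export
print.ssr_genome <- function(x, ...) {
  cat("ssr_genome with", length(x), "record(s):\n")
  for (r in x) cat(sprintf("  %s (%d bp, %d soft-masked)\n",
                           r$id, r$length, length(r$softmask)))
  invisible(x)
}

#' Write sequence records to FASTA
#'
#' @param genome an `ssr_genome` or named character vector of sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path) {
  if (inherits(genome, "ssr_genome")) {
    seqs <- vapply(genome, `[[`, "", "sequence")
    names(seqs) <- vapply(genome, `[[`, "", "id")
  } else {
    seqs <- genome
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# coerce find_repeats()-style input: a record, a genome element, or a string
as_seqrec <- function(record, id = "seq1") {
  if (inherits(record, "ssr_seqrec")) return(record)
  if (is_scalar_string(record)) return(new_sequence_record(id, record))
  stop("expected an ssr_seqrec or a single sequence string")
}
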
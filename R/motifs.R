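# Canonical motif classes.
#
# Two motifs describe the same microsatellite if one is a circular
# permutation of the other or of its reverse complement (the same array
# read from a different phase or from the opposite strand). Motifs are
# therefore grouped into equivalence classes closed under rotation and
# reverse complement; each class is named by its lexicographically
# smallest member (alphabet order A < C < G < T), e.g. dinucleotide
# classes AT/TA, AC/CA/GT/TG, AG/GA/CT/TC and CG/GC.

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k) - 1L, function(i) {
    paste0(substring(m, i + 1L, k), substring(m, 1L, i))
  }, "")
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a proper power of a shorter motif:
#' "ATAT" = (AT)^2 is not primitive, while "ATGCAT" is (a hexanucleotide
#' array of ATGCAT never reduces to a shorter repeat unit). This cyclic
#' notion differs from the string period used by [primitive_period()] for
#' repeat runs: only divisors of the motif length matter here.
#'
#' @param motif ACGT string
#' @return TRUE/FALSE
#' @export
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && strrep(substring(motif, 1, d), k / d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical class of a motif
#'
#' @param motif an ACGT string of length 2-6 whose primitive period equals
#'   its length (non-primitive motifs such as "ATAT" are rejected: reduce
#'   the repeat to its primitive period first)
#' @return a `motif_class` object: list with `k` (motif length),
#'   `representative` (lexicographically smallest member), `members`
#'   (rotations of the representative followed by their reverse
#'   complements, deduplicated) and `label` (members joined by "/")
#' @export
#' @examples
#' canonical_motif("GA")$label    # "AG/GA/CT/TC"
#' canonical_motif("GTC")$label   # "ACG/CGA/GAC/CGT/TCG/GTC"
canonical_motif <- function(motif) {
  stopifnot(is_scalar_string(motif))
  k <- nchar(motif)
  if (k < 2 || k > 6) stop("motif length must be 2-6, got ", k)
  if (!grepl("^[ACGT]+$", motif)) {
    stop("motif must contain only A/C/G/T: ", motif)
  }
  if (!is_primitive_motif(motif)) {
    stop("motif '", motif, "' is not primitive (a power of a shorter ",
         "motif); reduce the repeat to its primitive period first")
  }
  all_members <- unique(c(rotations(motif), rotations(revcomp(motif))))
  rep <- min(all_members)
  fwd <- rotations(rep)
  members <- unique(c(fwd, revcomp(fwd)))
  structure(list(k = k, representative = rep, members = members,
                 label = paste(members, collapse = "/")),
            class = "motif_class")
}

#' @export
print.motif_class <- function(x, ...) {
  cat(sprintf("motif_class k=%d: %s\n", x$k, x$label))
  invisible(x)
}

#' Enumerate all canonical motif classes for a motif length
#'
#' Partitions the primitive k-mers (those whose primitive period equals k)
#' into classes under rotation and reverse complement. There are 4
#' dinucleotide and 10 trinucleotide classes.
#'
#' @param k motif length, 2-6
#' @return list of `motif_class` objects sorted by representative
#' @export
enumerate_classes <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 6L) stop("k must be between 2 and 6")
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), k),
                                       stringsAsFactors = FALSE))
  primitive <- kmers[vapply(kmers, is_primitive_motif, TRUE)]
  seen <- character(0)
  classes <- list()
  for (m in sort(primitive)) {
    if (m %in% seen) next
    cl <- canonical_motif(m)
    classes[[length(classes) + 1L]] <- cl
    seen <- c(seen, cl$members)
  }
  classes[order(vapply(classes, `[[`, "", "representative"))]
}

#' Canonical class of a repeat hit's observed motif
#'
#' @param hit one row of a [find_repeats()] data.frame, or a motif string
#' @return a `motif_class` object
#' @export
class_of_hit <- function(hit) {
  motif <- if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1)
    hit$motif
  } else {
    hit
  }
  canonical_motif(motif)
}

# vectorized: class label for each motif (used when building the atlas)
class_labels <- function(motifs) {
  u <- unique(motifs)
  lab <- vapply(u, function(m) {
    if (nchar(m) == 1) return(paste0(m, "/", revcomp(m)))  # homopolymers, if kept
    canonical_motif(m)$label
  }, "")
  unname(lab[match(motifs, u)])
}

#' Write the full motif class table for a motif length
#'
#' @param k motif length, 2-6
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_class_table <- function(k, path) {
  cls <- enumerate_classes(k)
  df <- data.frame(representative = vapply(cls, `[[`, "", "representative"),
                   n_members = vapply(cls, function(c) length(c$members), 0L),
                   label = vapply(cls, `[[`, "", "label"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
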
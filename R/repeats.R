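# Perfect maximal tandem repeat detection.
#
# A repeat run of period p is a stretch where sequence[k] == sequence[k+p]
# for every k in [start, end-p). Runs are maximal (extending one base in
# either direction breaks the equality or leaves the sequence / enters a
# non-ACGT character) and are reported once, at their primitive (smallest)
# period. Homopolymer runs (primitive period 1) are excluded by default:
# mononucleotide arrays are not part of the marker catalog even though
# they satisfy the period-2 equality.
#
# find_repeats() is the production scanner (vectorized equality + run
# length encoding per period). oracle_find_repeats() re-derives the same
# contract by explicit per-position extension loops and is kept
# intentionally independent so the two can cross-check each other.

#' Scan parameters for repeat detection
#'
#' Defaults mirror a stringent genome-wide microsatellite survey: perfect
#' repeats of period 2-6, total array size at least 12 bases, at least 2
#' repeat units. Size and exponent thresholds are applied independently.
#'
#' @param min_size minimum array size in bases (default 12)
#' @param min_period smallest motif length scanned (default 2)
#' @param max_period largest motif length scanned (default 6)
#' @param min_exponent minimum number of repeat units, fractional allowed
#'   (default 2)
#' @param exclude_homopolymers drop runs whose primitive period is 1
#'   (default TRUE). When FALSE, homopolymer arrays are reported with
#'   period 1.
#' @return a `scan_params` list
#' @export
scan_params <- function(min_size = 12L, min_period = 2L, max_period = 6L,
                        min_exponent = 2, exclude_homopolymers = TRUE) {
  min_size <- as.integer(min_size)
  min_period <- as.integer(min_period)
  max_period <- as.integer(max_period)
  if (min_period < 1L) stop("min_period must be >= 1")
  if (max_period < min_period) stop("max_period must be >= min_period")
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_exponent < 1) stop("min_exponent must be >= 1")
  structure(list(min_size = min_size, min_period = min_period,
                 max_period = max_period, min_exponent = min_exponent,
                 exclude_homopolymers = isTRUE(exclude_homopolymers)),
            class = "scan_params")
}

empty_hits <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
              period = integer(0), motif = character(0), size = integer(0),
              exponent = numeric(0), stringsAsFactors = FALSE)
}

hits_frame <- function(scaffold, start, end, period, seq) {
  if (length(start) == 0) return(empty_hits())
  size <- end - start
  motif <- substring(seq, start + 1L, start + period)
  data.frame(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), period = as.integer(period),
             motif = motif, size = as.integer(size),
             exponent = size / period, stringsAsFactors = FALSE)
}

finalize_hits <- function(df) {
  df <- unique(df)
  df[order(df$scaffold, df$start, df$period), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# 0-based [start,end) of maximal ACGT segments of a sequence
acgt_segments <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(matrix(integer(0), ncol = 2))
  bad <- gregexpr("[^ACGT]+", seq)[[1]]
  if (bad[1] == -1) return(matrix(c(0L, n), ncol = 2))
  bs <- as.integer(bad) - 1L
  be <- bs + attr(bad, "match.length")
  starts <- c(0L, be)
  ends <- c(bs, n)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

#' Find perfect maximal microsatellites in one sequence record
#'
#' @param record an `ssr_seqrec` (see [read_fasta()]) or a single
#'   uppercase sequence string
#' @param params a [scan_params()] object
#' @return data.frame of hits with columns `scaffold`, `start`, `end`
#'   (0-based half-open), `period` (primitive), `motif` (first `period`
#'   bases of the run), `size` and `exponent`, sorted by start then
#'   period. Runs never span a non-ACGT character.
#' @export
#' @examples
#' find_repeats("GGATCGATCGATCGTT")  # one period-4 run, size 13
find_repeats <- function(record, params = scan_params()) {
  rec <- as_seqrec(record)
  stopifnot(inherits(params, "scan_params"))
  seq <- rec$sequence
  segs <- acgt_segments(seq)
  h_start <- integer(0); h_end <- integer(0); h_period <- integer(0)
  periods <- params$min_period:params$max_period
  if (!params$exclude_homopolymers) periods <- union(1L, periods)
  for (si in seq_len(nrow(segs))) {
    s0 <- segs[si, 1]; s1 <- segs[si, 2]
    n <- s1 - s0
    if (n < params$min_size) next
    x <- chars(substring(seq, s0 + 1L, s1))
    for (p in periods) {
      if (n < p + 1L) next
      eq <- x[seq_len(n - p)] == x[seq_len(n - p) + p]
      r <- rle(eq)
      len <- r$lengths
      ends <- cumsum(len)
      starts <- ends - len
      ok <- which(r$values & (len + p >= params$min_size) &
                    ((len + p) / p >= params$min_exponent))
      for (i in ok) {
        st <- starts[i]            # 0-based within segment
        sz <- len[i] + p
        # report only at the primitive period of the run
        if (run_has_smaller_period(x, st, st + sz, p)) next
        h_start <- c(h_start, s0 + st)
        h_end <- c(h_end, s0 + st + sz)
        h_period <- c(h_period, p)
      }
    }
  }
  finalize_hits(hits_frame(rec$id, h_start, h_end, h_period, seq))
}

# TRUE if the 0-based run [st,en) of char vector x has a period q < p
run_has_smaller_period <- function(x, st, en, p) {
  if (p == 1L) return(FALSE)
  for (q in seq_len(p - 1L)) {
    i <- (st + 1L):(en - q)
    if (all(x[i] == x[i + q])) return(TRUE)
  }
  FALSE
}

#' Primitive period of a repeat run
#'
#' The smallest p >= 1 such that `run[k] == run[k+p]` for all valid k.
#'
#' @param run_sequence non-empty ACGT string
#' @return integer period
#' @export
#' @examples
#' primitive_period("GATCGATCGATCG")  # 4
primitive_period <- function(run_sequence) {
  stopifnot(is_scalar_string(run_sequence), nchar(run_sequence) > 0)
  x <- chars(run_sequence)
  if (!all(x %in% c("A", "C", "G", "T"))) {
    stop("primitive_period(): sequence must contain only A/C/G/T")
  }
  n <- length(x)
  for (p in seq_len(n)) {
    if (p == n) return(p)
    if (all(x[seq_len(n - p)] == x[seq_len(n - p) + p])) return(p)
  }
  n
}

#' Reference repeat scanner (exhaustive, loop-based)
#'
#' An independent re-derivation of [find_repeats()]'s contract used for
#' cross-validation: for every period it walks the sequence position by
#' position, grows each maximal run explicitly, then applies the size,
#' exponent and primitivity rules. Intended for sequences up to ~100 kb.
#'
#' @inheritParams find_repeats
#' @return same shape as [find_repeats()]
#' @export
oracle_find_repeats <- function(record, params = scan_params()) {
  rec <- as_seqrec(record)
  stopifnot(inherits(params, "scan_params"))
  seq <- rec$sequence
  x <- chars(seq)
  n <- length(x)
  valid <- x %in% c("A", "C", "G", "T")
  periods <- params$min_period:params$max_period
  if (!params$exclude_homopolymers) periods <- union(1L, periods)
  h_start <- integer(0); h_end <- integer(0); h_period <- integer(0)
  for (p in periods) {
    i <- 1L
    while (i <= n - p) {
      if (valid[i] && valid[i + p] && x[i] == x[i + p]) {
        j <- i
        while (j < n - p && valid[j + 1L + p] && x[j + 1L] == x[j + 1L + p]) {
          j <- j + 1L
        }
        sz <- j - i + 1L + p
        if (sz >= params$min_size && sz / p >= params$min_exponent) {
          run <- substring(seq, i, i + sz - 1L)
          if (primitive_period(run) == p) {
            h_start <- c(h_start, i - 1L)
            h_end <- c(h_end, i - 1L + sz)
            h_period <- c(h_period, p)
          }
        }
        i <- j + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  finalize_hits(hits_frame(rec$id, h_start, h_end, h_period, seq))
}

#' Scan every record of a genome
#'
#' @param genome an `ssr_genome` from [read_fasta()]
#' @param params a [scan_params()] object
#' @return row-bound hits from [find_repeats()] over all records
#' @export
scan_genome <- function(genome, params = scan_params()) {
  stopifnot(inherits(genome, "ssr_genome"))
  finalize_hits(do.call(rbind, c(list(empty_hits()),
                                 lapply(genome, find_repeats, params = params))))
}

#' Write repeat hits as TSV (1-based printed coordinates)
#'
#' @param hits data.frame from [find_repeats()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_repeats <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a repeat hit TSV written by [write_repeats()]
#'
#' @param path path to the TSV
#' @return hits data.frame with internal 0-based half-open coordinates
#' @export
read_repeats <- function(path) {
  df <- read.delim(path, header = TRUE,
                   colClasses = c(scaffold = "character", motif = "character"))
  df$start <- as.integer(df$start) - 1L
  df
}
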
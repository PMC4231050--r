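# Stringent PCR primer design for repeat markers.
#
# Self-contained approximation of a classical primer-design configuration:
# repeat flanks are extracted (250 bp either side), low-complexity
# sequence is masked with a windowed triplet (DUST-style) score, and every
# candidate primer must clear explicit gates -- length 18-25 nt, melting
# temperature 57-63 C (nearest-neighbor thermodynamics), GC 20-60%, no
# ambiguous bases, 3' end off masked sequence, at most half its bases
# masked, no qualifying microsatellite run inside the primer (the
# mispriming-library rule), and no self-complementary stem longer than 6
# bp (hairpin score 4 points per stem pair, ceiling 24). The best passing
# pair per repeat minimizes a penalty over length, Tm and product size.
# Hairpins are scored by stem length, not full secondary-structure
# thermodynamics; see the methods vignette for the divergences.

#' Primer design parameters
#'
#' Defaults encode the stringent marker-design configuration: primer
#' length 18/20/25 (min/opt/max), Tm 57/60/63 C, product 250/300/350 bp,
#' GC 20-60%, hairpin score ceiling 24 (stems of at most 6 bp at 4 points
#' per pair), 250 bp flanks, and rejection of primers whose two 3'-terminal
#' bases fall in masked sequence or that contain a qualifying repeat run.
#'
#' @param flank flank length extracted either side of the repeat (bases)
#' @param len_min,len_opt,len_max primer length bounds (nt)
#' @param tm_min,tm_opt,tm_max melting temperature bounds (degrees C)
#' @param product_min,product_opt,product_max PCR product size bounds (bp)
#' @param gc_min,gc_max GC content bounds (percent)
#' @param hairpin_max hairpin score ceiling (4 x longest stem pair count)
#' @param masked3_window number of 3'-terminal bases that must be unmasked
#' @param max_tm_diff largest allowed Tm difference within a pair (C)
#' @param max_masked_frac largest allowed masked fraction of a primer
#' @param na_mM monovalent cation concentration for Tm (mM)
#' @param oligo_nM oligo concentration for Tm (nM)
#' @param dust_window,dust_threshold low-complexity masking parameters,
#'   see [dust_mask()]
#' @param repeat_params [scan_params()] defining a "qualifying repeat run"
#'   for the mispriming rule
#' @return a `primer_params` list
#' @export
primer_params <- function(flank = 250L,
                          len_min = 18L, len_opt = 20L, len_max = 25L,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          product_min = 250L, product_opt = 300L,
                          product_max = 350L,
                          gc_min = 20, gc_max = 60,
                          hairpin_max = 24, masked3_window = 2L,
                          max_tm_diff = 3, max_masked_frac = 0.5,
                          na_mM = 50, oligo_nM = 50,
                          dust_window = 64L, dust_threshold = 2.0,
                          repeat_params = scan_params()) {
  triple <- function(lo, opt, hi, what) {
    if (!(lo <= opt && opt <= hi)) stop(what, ": need min <= opt <= max")
  }
  triple(len_min, len_opt, len_max, "primer length")
  triple(tm_min, tm_opt, tm_max, "melting temperature")
  triple(product_min, product_opt, product_max, "product size")
  if (gc_min > gc_max) stop("GC bounds: need min <= max")
  structure(as.list(environment())[c(
    "flank", "len_min", "len_opt", "len_max", "tm_min", "tm_opt", "tm_max",
    "product_min", "product_opt", "product_max", "gc_min", "gc_max",
    "hairpin_max", "masked3_window", "max_tm_diff", "max_masked_frac",
    "na_mM", "oligo_nM", "dust_window", "dust_threshold", "repeat_params"
  )], class = "primer_params")
}

#' Extract a repeat template with flanks
#'
#' @param record an `ssr_seqrec` (or sequence string)
#' @param hit single-row hit data.frame (0-based half-open coordinates)
#' @param flank flank length in bases (default 250)
#' @return a `primer_template`: list with `sequence`, `ssr` (0-based
#'   interval of the repeat within the template), `offset` (genome
#'   coordinate of template position 0), `clipped_left`/`clipped_right`
#'   (flank truncated at a sequence end) and `masked` (NULL until set,
#'   e.g. by [dust_mask()])
#' @export
extract_template <- function(record, hit, flank = 250L) {
  rec <- as_seqrec(record)
  s <- hit$start[1]; e <- hit$end[1]
  stopifnot(s >= 0, e <= rec$length, s < e)
  t0 <- max(0L, s - as.integer(flank))
  t1 <- min(rec$length, e + as.integer(flank))
  structure(list(
    sequence = substring(rec$sequence, t0 + 1L, t1),
    ssr = c(s - t0, e - t0),
    offset = t0,
    clipped_left = t0 > s - flank,
    clipped_right = t1 < e + flank,
    masked = NULL
  ), class = "primer_template")
}

#' Low-complexity masking by windowed triplet score
#'
#' For every sliding window of `window` bases the score is
#' `sum(c_t * (c_t - 1) / 2) / (w - 3)` over the counts `c_t` of the
#' overlapping 3-mers in the window (3-mers containing non-ACGT bases are
#' not counted). All positions of every window scoring above `threshold`
#' are masked. A 64-base homopolymer scores 62*61/2/61 = 31.
#'
#' @param sequence ACGTN string
#' @param window window width in bases (default 64; sequences shorter than
#'   the window are scored as a single window)
#' @param threshold score above which a window is masked (default 2.0)
#' @return integer matrix of merged masked intervals, columns `start`,
#'   `end` (0-based half-open); zero rows when nothing is masked
#' @export
dust_mask <- function(sequence, window = 64L, threshold = 2.0) {
  n <- nchar(sequence)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (n < 4) return(empty)
  w <- min(as.integer(window), n)
  x <- match(chars(sequence), c("A", "C", "G", "T")) - 1L
  tri <- x[seq_len(n - 2L)] * 16L + x[seq_len(n - 2L) + 1L] * 4L +
    x[seq_len(n - 2L) + 2L] + 1L          # 1..64, NA where any base non-ACGT
  ntri_win <- w - 2L                       # 3-mers per window
  counts <- integer(64)
  pairsum <- 0                             # sum over c*(c-1)/2
  add <- function(t) {
    if (!is.na(t)) {
      pairsum <<- pairsum + counts[t]
      counts[t] <<- counts[t] + 1L
    }
  }
  drop <- function(t) {
    if (!is.na(t)) {
      counts[t] <<- counts[t] - 1L
      pairsum <<- pairsum - counts[t]
    }
  }
  for (i in seq_len(ntri_win)) add(tri[i])
  nwin <- n - w + 1L
  hot <- logical(nwin)
  hot[1] <- pairsum / (w - 3) > threshold
  if (nwin > 1) {
    for (j in 2:nwin) {
      drop(tri[j - 1L])
      add(tri[j + ntri_win - 2L])
      hot[j] <- pairsum / (w - 3) > threshold
    }
  }
  if (!any(hot)) return(empty)
  iv <- IRanges::reduce(IRanges::IRanges(start = which(hot), width = w))
  cbind(start = IRanges::start(iv) - 1L, end = IRanges::end(iv))
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), per duplex dinucleotide step.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_H <- c(GC = 0.1, AT = 2.3)   # per terminal base pair
NN_INIT_S <- c(GC = -2.8, AT = 4.1)
GAS_R <- 1.9872                       # cal/(mol K)

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from the unified nearest-neighbor thermodynamic parameter
#' set, with the entropic salt correction `0.368 (N-1) ln[Na+]` and oligo
#' concentration term `R ln(CT/4)` for a non-self-complementary duplex in
#' primer excess.
#'
#' @param primer character vector of ACGT sequences, each at least 8 nt
#' @param na_mM monovalent cation concentration in mM (default 50)
#' @param oligo_nM total oligo concentration in nM (default 50)
#' @return numeric vector of melting temperatures in degrees C
#' @export
melting_temp <- function(primer, na_mM = 50, oligo_nM = 50) {
  vapply(primer, function(p) {
    if (is.na(p) || !grepl("^[ACGT]+$", p)) {
      stop("melting_temp(): primer must contain only A/C/G/T")
    }
    n <- nchar(p)
    if (n < 8) stop("melting_temp(): primer must be at least 8 nt")
    steps <- substring(p, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    ends <- substring(p, c(1L, n), c(1L, n))
    term <- ifelse(ends %in% c("G", "C"), "GC", "AT")
    dh <- sum(NN_DH[steps]) + sum(NN_INIT_H[term])
    ds <- sum(NN_DS[steps]) + sum(NN_INIT_S[term]) +
      0.368 * (n - 1) * log(na_mM / 1000)
    1000 * dh / (ds + GAS_R * log(oligo_nM * 1e-9 / 4)) - 273.15
  }, 0, USE.NAMES = FALSE)
}

#' Longest self-complementary hairpin stem of a primer
#'
#' Longest stem length s for which two s-mers of the primer can base-pair
#' as a hairpin stem (the downstream arm reverse-complements the upstream
#' arm) with an unpaired loop of at least `min_loop` bases between them.
#' The hairpin score used by the design gates is 4 points per stem pair,
#' i.e. `4 * hairpin_stem(p)`.
#'
#' @param primer ACGT string
#' @param min_loop minimum loop length in bases (default 3)
#' @return integer stem length (0 when no stem of length >= 2 exists)
#' @export
hairpin_stem <- function(primer, min_loop = 3L) {
  x <- match(chars(primer), c("A", "C", "G", "T")) - 1L
  smax <- (length(x) - min_loop) %/% 2L
  if (smax < 2L || anyNA(x)) return(0L)
  for (s in smax:2L) {
    if (stem_exists(x, s, min_loop)) return(s)
  }
  0L
}

# any hairpin stem of length exactly s in base-code vector x? Arms are
# compared through exact base-4 integer codes of the upstream arm and of
# the reverse complement of the downstream arm.
stem_exists <- function(x, s, min_loop = 3L) {
  L <- length(x)
  m <- L - s + 1L
  if (m < 1L || L < 2L * s + min_loop) return(FALSE)
  comp <- 3L - x
  idx <- seq_len(m)
  code <- numeric(m)
  rcode <- numeric(m)
  for (t in seq_len(s)) {
    code <- code * 4 + x[idx + t - 1L]
    rcode <- rcode * 4 + comp[idx + s - t]
  }
  for (v in unique(code)) {
    i_min <- idx[code == v][1]
    j <- idx[rcode == v]
    if (length(j) > 0 && max(j) >= i_min + s + min_loop) return(TRUE)
  }
  FALSE
}

# hairpin gate: a stem of length >= s exists iff a stem of exactly s
# exists (trim the inner pairs; the loop only grows), so the score gate
# 4*stem > ceiling tests one stem length.
hairpin_fails <- function(seq, params) {
  x <- match(chars(seq), c("A", "C", "G", "T")) - 1L
  if (anyNA(x)) return(FALSE)
  stem_exists(x, params$hairpin_max %/% 4L + 1L)
}

# does the ACGT string contain a qualifying repeat run? Mirrors the
# find_repeats() reporting rule (maximal run, size/exponent thresholds,
# primitive period in range) without assembling a hit table.
has_qualifying_run <- function(seq, params) {
  x <- chars(seq)
  n <- length(x)
  periods <- params$min_period:params$max_period
  if (!params$exclude_homopolymers) periods <- union(1L, periods)
  for (p in periods) {
    if (n < p + 1L) next
    eq <- x[seq_len(n - p)] == x[seq_len(n - p) + p]
    r <- rle(eq)
    len <- r$lengths
    ends <- cumsum(len)
    starts <- ends - len
    for (i in which(r$values & (len + p >= params$min_size) &
                      ((len + p) / p >= params$min_exponent))) {
      if (!run_has_smaller_period(x, starts[i], starts[i] + len[i] + p, p)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# positions pos (0-based) falling in a masked interval matrix
in_masked <- function(pos, masked) {
  if (is.null(masked) || nrow(masked) == 0) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(masked[, 1] <= p & p < masked[, 2]), TRUE)
}

masked_overlap <- function(a, b, masked) {
  if (is.null(masked) || nrow(masked) == 0) return(0)
  as.numeric(sum(pmax(0L, pmin(b, masked[, 2]) - pmax(a, masked[, 1]))))
}

#' Evaluate one primer candidate against all design gates
#'
#' @param candidate list with `start` (0-based position in the template),
#'   `length`, and `strand` (`"+"` forward, `"-"` reverse; a reverse
#'   primer is the reverse complement of the template substring)
#' @param template a `primer_template` (with `masked` set; see
#'   [dust_mask()])
#' @param params a [primer_params()] object
#' @return list with `pass` (logical), `reasons` (character vector of
#'   failed gate codes, empty when passing), `seq`, `tm`, `gc`
#' @details Gate codes: `length`, `ambiguous_base`, `gc`, `tm`,
#'   `masked_3prime`, `low_complexity`, `ssr_content`, `hairpin`,
#'   `overlaps_ssr`.
#' @export
evaluate_primer <- function(candidate, template, params = primer_params()) {
  a <- candidate$start; len <- candidate$length
  b <- a + len
  L <- nchar(template$sequence)
  stopifnot(a >= 0, b <= L)
  sub <- substring(template$sequence, a + 1L, b)
  seq <- if (candidate$strand == "-") revcomp(sub) else sub
  reasons <- character(0)
  tm <- NA_real_
  gc <- NA_real_
  if (len < params$len_min || len > params$len_max) reasons <- c(reasons, "length")
  if (a < template$ssr[2] && template$ssr[1] < b) reasons <- c(reasons, "overlaps_ssr")
  if (grepl("[^ACGT]", sub)) {
    reasons <- c(reasons, "ambiguous_base")
  } else {
    gc <- gc_percent(sub)
    if (gc < params$gc_min || gc > params$gc_max) reasons <- c(reasons, "gc")
    if (len >= 8) {
      tm <- melting_temp(sub, params$na_mM, params$oligo_nM)
      if (tm < params$tm_min || tm > params$tm_max) reasons <- c(reasons, "tm")
    }
    if (has_qualifying_run(sub, params$repeat_params)) {
      reasons <- c(reasons, "ssr_content")
    }
    if (hairpin_fails(sub, params)) {
      reasons <- c(reasons, "hairpin")
    }
  }
  w <- params$masked3_window
  three_prime <- if (candidate$strand == "-") a + seq_len(w) - 1L else b - seq_len(w)
  if (any(in_masked(three_prime, template$masked))) {
    reasons <- c(reasons, "masked_3prime")
  }
  if (masked_overlap(a, b, template$masked) > params$max_masked_frac * len) {
    reasons <- c(reasons, "low_complexity")
  }
  list(pass = length(reasons) == 0, reasons = reasons, seq = seq,
       tm = tm, gc = gc)
}

# Vectorized per-candidate statistics over template substrings.
# Candidates given as 0-based starts `a` and lengths `len`; returns Tm,
# GC percent and non-ACGT counts computed via template-wide cumulative
# sums (the nearest-neighbor sum of a substring is a difference of
# cumsums; terminal and salt terms are added per candidate).
candidate_stats <- function(seq, a, len, params) {
  x <- chars(seq)
  n <- length(x)
  steps <- paste0(x[-n], x[-1])
  dh <- unname(NN_DH[steps]); dh[is.na(dh)] <- 0
  ds <- unname(NN_DS[steps]); ds[is.na(ds)] <- 0
  cumH <- c(0, cumsum(dh)); cumS <- c(0, cumsum(ds))
  isgc <- cumsum(x %in% c("G", "C"))
  isbad <- cumsum(!(x %in% c("A", "C", "G", "T")))
  cg0 <- c(0L, isgc); bad0 <- c(0L, isbad)
  b <- a + len
  sumH <- cumH[b] - cumH[a + 1L]
  sumS <- cumS[b] - cumS[a + 1L]
  term <- function(pos) ifelse(x[pos] %in% c("G", "C"), 1L, 2L)
  th <- c(NN_INIT_H["GC"], NN_INIT_H["AT"])
  ts <- c(NN_INIT_S["GC"], NN_INIT_S["AT"])
  dh_tot <- sumH + th[term(a + 1L)] + th[term(b)]
  ds_tot <- sumS + ts[term(a + 1L)] + ts[term(b)] +
    0.368 * (len - 1) * log(params$na_mM / 1000)
  tm <- 1000 * dh_tot / (ds_tot + GAS_R * log(params$oligo_nM * 1e-9 / 4)) - 273.15
  list(tm = tm,
       gc = 100 * (cg0[b + 1L] - cg0[a + 1L]) / len,
       n_bad = bad0[b + 1L] - bad0[a + 1L])
}

#' Design the best primer pair for one template
#'
#' Enumerates every candidate forward primer in the left flank and reverse
#' primer in the right flank, applies all [evaluate_primer()] gates, keeps
#' pairs whose product covers the repeat with size within bounds and Tm
#' difference within `max_tm_diff`, and returns the pair minimizing
#' `|len-20| + |Tm-60|` (both primers) `+ |product-300|/10`. Ties break to
#' the leftmost forward primer, then the shortest product. Deterministic.
#'
#' @param template a `primer_template`; if its `masked` slot is NULL it is
#'   filled with [dust_mask()] first
#' @param params a [primer_params()] object
#' @return a `primer_pair` list: `status` `"ok"` with primer sequences,
#'   template positions, Tm, GC, product size and penalty -- or `status`
#'   `"no_primer"` with `reasons`, a named count of the gate failures seen
#' @export
design_pair <- function(template, params = primer_params()) {
  stopifnot(inherits(template, "primer_template"))
  if (is.null(template$masked)) {
    template$masked <- dust_mask(template$sequence,
                                 params$dust_window, params$dust_threshold)
  }
  seq <- template$sequence
  L <- nchar(seq)
  ssr <- template$ssr
  lens <- params$len_min:params$len_max

  enumerate <- function(lo, hi) {   # all candidates within [lo, hi)
    out <- list()
    for (len in lens) {
      if (hi - lo < len) next
      a <- lo:(hi - len)
      out[[length(out) + 1L]] <- data.frame(a = a, len = len)
    }
    if (length(out) == 0) {
      return(data.frame(a = integer(0), len = integer(0)))
    }
    do.call(rbind, out)
  }
  fails <- character(0)
  gate_side <- function(cand, side) {
    if (nrow(cand) == 0) return(cand)
    st <- candidate_stats(seq, cand$a, cand$len, params)
    cand$tm <- st$tm
    reasons <- list(
      ambiguous_base = st$n_bad > 0,
      gc = st$gc < params$gc_min | st$gc > params$gc_max,
      tm = st$tm < params$tm_min | st$tm > params$tm_max
    )
    b <- cand$a + cand$len
    w <- params$masked3_window
    three_prime_hot <- rep(FALSE, nrow(cand))
    for (k in seq_len(w)) {
      pos <- if (side == "fwd") b - k else cand$a + k - 1L
      three_prime_hot <- three_prime_hot | in_masked(pos, template$masked)
    }
    reasons$masked_3prime <- three_prime_hot
    reasons$low_complexity <- vapply(seq_len(nrow(cand)), function(i)
      masked_overlap(cand$a[i], b[i], template$masked),
      0) > params$max_masked_frac * cand$len
    bad <- Reduce(`|`, reasons)
    for (nm in names(reasons)) {
      fails <<- c(fails, rep(nm, sum(reasons[[nm]])))
    }
    surv <- cand[!bad, , drop = FALSE]
    if (nrow(surv) == 0) return(surv)
    # expensive gates on survivors only
    subs <- substring(seq, surv$a + 1L, surv$a + surv$len)
    has_run <- vapply(subs, function(s) {
      has_qualifying_run(s, params$repeat_params)
    }, TRUE, USE.NAMES = FALSE)
    hp <- vapply(subs, hairpin_fails, TRUE, USE.NAMES = FALSE,
                 params = params)
    fails <<- c(fails, rep("ssr_content", sum(has_run)),
                rep("hairpin", sum(!has_run & hp)))
    surv[!has_run & !hp, , drop = FALSE]
  }

  fwd <- gate_side(enumerate(0L, ssr[1]), "fwd")
  rev <- gate_side(enumerate(ssr[2], L), "rev")
  no_pair <- function(extra = character(0)) {
    structure(list(status = "no_primer",
                   reasons = c(sort(table(fails), decreasing = TRUE),
                               setNames(rep(1L, length(extra)), extra))),
              class = "primer_pair")
  }
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(no_pair("no_candidates"))

  rend <- rev$a + rev$len
  product <- outer(rend, fwd$a, `-`)            # rows: rev, cols: fwd
  tmdiff <- abs(outer(rev$tm, fwd$tm, `-`))
  okpair <- product >= params$product_min & product <= params$product_max &
    tmdiff <= params$max_tm_diff
  if (!any(okpair)) return(no_pair("no_valid_pairing"))
  pen <- outer(abs(rev$len - params$len_opt) + abs(rev$tm - params$tm_opt),
               abs(fwd$len - params$len_opt) + abs(fwd$tm - params$tm_opt), `+`) +
    abs(product - params$product_opt) / 10
  pen[!okpair] <- Inf
  idx <- which(okpair, arr.ind = TRUE)
  ord <- order(pen[idx], fwd$a[idx[, 2]], product[idx], rev$a[idx[, 1]])
  ri <- idx[ord[1], 1]; fi <- idx[ord[1], 2]

  fwd_seq <- substring(seq, fwd$a[fi] + 1L, fwd$a[fi] + fwd$len[fi])
  rev_sub <- substring(seq, rev$a[ri] + 1L, rev$a[ri] + rev$len[ri])
  pair <- structure(list(
    status = "ok",
    fwd_seq = fwd_seq, rev_seq = revcomp(rev_sub),
    fwd_start = fwd$a[fi], fwd_len = fwd$len[fi],
    rev_start = rev$a[ri], rev_len = rev$len[ri],
    tm_fwd = fwd$tm[fi], tm_rev = rev$tm[ri],
    gc_fwd = gc_percent(fwd_seq), gc_rev = gc_percent(rev_sub),
    product_size = as.integer(product[ri, fi]),
    penalty = pen[ri, fi]
  ), class = "primer_pair")
  # re-verify every gate on the returned pair
  chk_f <- evaluate_primer(list(start = pair$fwd_start, length = pair$fwd_len,
                                strand = "+"), template, params)
  chk_r <- evaluate_primer(list(start = pair$rev_start, length = pair$rev_len,
                                strand = "-"), template, params)
  stopifnot(chk_f$pass, chk_r$pass)
  pair
}

#' @export
print.primer_pair <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("primer_pair: %s / %s (product %d bp, Tm %.1f/%.1f C, penalty %.2f)\n",
                x$fwd_seq, x$rev_seq, x$product_size, x$tm_fwd, x$tm_rev, x$penalty))
  } else {
    cat("primer_pair: no primer (",
        paste(names(x$reasons), unname(x$reasons), sep = "=", collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Design primer pairs for a set of repeat hits
#'
#' @param genome an `ssr_genome`
#' @param hits data.frame from [scan_genome()]
#' @param params a [primer_params()] object
#' @return data.frame with one row per hit: `ssr_id`, `status`, `reason`
#'   (top failure reasons, ";"-joined), primer sequences, genome
#'   coordinates (0-based starts), Tm, GC, product size and penalty
#' @export
design_primers <- function(genome, hits, params = primer_params()) {
  stopifnot(inherits(genome, "ssr_genome"))
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    hit <- hits[i, , drop = FALSE]
    rec <- genome[[hit$scaffold]]
    if (is.null(rec)) stop("hit on unknown scaffold: ", hit$scaffold)
    tpl <- extract_template(rec, hit, params$flank)
    tpl$masked <- dust_mask(tpl$sequence, params$dust_window,
                            params$dust_threshold)
    pair <- design_pair(tpl, params)
    if (pair$status == "ok") {
      data.frame(ssr_id = ssr_ids(hit), status = "ok", reason = "",
                 fwd = pair$fwd_seq, rev = pair$rev_seq,
                 fwd_start = tpl$offset + pair$fwd_start,
                 rev_start = tpl$offset + pair$rev_start,
                 tm_fwd = pair$tm_fwd, tm_rev = pair$tm_rev,
                 gc_fwd = pair$gc_fwd, gc_rev = pair$gc_rev,
                 product_size = pair$product_size, penalty = pair$penalty,
                 stringsAsFactors = FALSE)
    } else {
      top <- names(pair$reasons)
      data.frame(ssr_id = ssr_ids(hit), status = "no_primer",
                 reason = paste(top[seq_len(min(3, length(top)))], collapse = ";"),
                 fwd = NA_character_, rev = NA_character_,
                 fwd_start = NA_integer_, rev_start = NA_integer_,
                 tm_fwd = NA_real_, tm_rev = NA_real_,
                 gc_fwd = NA_real_, gc_rev = NA_real_,
                 product_size = NA_integer_, penalty = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ssr_id = character(0), status = character(0),
                      reason = character(0), fwd = character(0),
                      rev = character(0), fwd_start = integer(0),
                      rev_start = integer(0), tm_fwd = numeric(0),
                      tm_rev = numeric(0), gc_fwd = numeric(0),
                      gc_rev = numeric(0), product_size = integer(0),
                      penalty = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write designed primers as TSV (1-based printed coordinates)
#'
#' @param primers data.frame from [design_primers()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_primers <- function(primers, path) {
  out <- primers
  out$fwd_start <- out$fwd_start + 1L
  out$rev_start <- out$rev_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer TSV written by [write_primers()]
#'
#' @param path path to the TSV
#' @return data.frame with internal 0-based coordinates
#' @export
read_primers <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = c(
    ssr_id = "character", status = "character", reason = "character",
    fwd = "character", rev = "character"
  ))
  df$reason[is.na(df$reason)] <- ""
  df$fwd_start <- as.integer(df$fwd_start) - 1L
  df$rev_start <- as.integer(df$rev_start) - 1L
  df
}
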
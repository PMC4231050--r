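test_that("templates carry the repeat with clipped flanks recorded", {
  rec <- new_sequence_record("s1", random_dna(1000))
  tpl <- extract_template(rec, hit_row("s1", 300L, 320L), flank = 250L)
  expect_equal(tpl$offset, 50L)
  expect_equal(nchar(tpl$sequence), 520L)
  expect_equal(tpl$ssr, c(250L, 270L))
  expect_false(tpl$clipped_left || tpl$clipped_right)
  edge <- extract_template(rec, hit_row("s1", 5L, 25L), flank = 250L)
  expect_equal(edge$offset, 0L)
  expect_equal(edge$ssr, c(5L, 25L))
  expect_true(edge$clipped_left)
  expect_false(edge$clipped_right)
})

test_that("the triplet score masks homopolymers and spares high-entropy windows", {
  m <- dust_mask(strrep("A", 64))          # window score 62*61/2/61 = 31
  expect_equal(nrow(m), 1L)
  expect_equal(unname(m[1, ]), c(0L, 64L))
  s <- distinct_triplet_64mer()
  tri <- substring(s, 1:62, 3:64)
  expect_equal(anyDuplicated(tri), 0L)     # construction check
  expect_equal(nrow(dust_mask(s)), 0L)     # all c_t <= 1 -> score 0
})

test_that("raising the threshold never grows the masked area", {
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- paste0(random_dna(150, 0.5), strrep("AT", 20), random_dna(100, 0.2))
      areas <- vapply(c(0.5, 1, 2, 4), function(th) {
        m <- dust_mask(s, threshold = th)
        if (nrow(m) == 0) 0L else sum(m[, 2] - m[, 1])
      }, 0L)
      expect_true(all(diff(areas) <= 0))
    }
  })
})

test_that("nearest-neighbor Tm matches a hand-summed duplex and its symmetries", {
  # CGTTGAGG: steps CG GT TT TG GA AG GG, both ends G/C
  dh <- (-10.6) + (-8.4) + (-7.9) + (-8.5) + (-8.2) + (-7.8) + (-8.0) +
    0.1 + 0.1
  ds <- (-27.2) + (-22.4) + (-22.2) + (-22.7) + (-22.2) + (-21.0) + (-19.9) +
    (-2.8) + (-2.8) + 0.368 * 7 * log(0.05)
  tm_hand <- 1000 * dh / (ds + 1.9872 * log(50e-9 / 4)) - 273.15
  expect_equal(melting_temp("CGTTGAGG"), tm_hand, tolerance = 0.5)
  # duplex symmetry: a primer and its reverse complement share a Tm
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- random_dna(sample(18:25, 1))
      expect_equal(melting_temp(p), melting_temp(revcomp(p)),
                   tolerance = 1e-9)
    }
  })
  # stability monotonicity: appending G to an A/T-rich 20-mer raises Tm
  base <- "ATTATAATTTATAATATTAA"
  expect_gt(melting_temp(paste0(base, "G")), melting_temp(base))
  expect_error(melting_temp("ATATNATATATA"), "A/C/G/T")
  expect_error(melting_temp("ACGTACG"), "at least 8")
})

test_that("every primer gate is independently falsifiable", {
  run <- strrep("ACGT", 5)
  hairpin_seq <- "GACGTACAAAGTACGTCT"     # 7 bp stem, 3 nt loop
  expect_equal(hairpin_stem(hairpin_seq), 7L)
  withr::with_seed(21, {
    left <- random_dna(250)
    right <- random_dna(100)
    special <- paste0(strrep("A", 20), random_dna(10), hairpin_seq,
                      random_dna(10), "ACGNNGTACGTACGAATGCA", random_dna(60))
    rec <- new_sequence_record("s1", paste0(left, run, right, special))
  })
  tpl <- extract_template(rec, hit_row("s1", 250L, 270L, 4L, "ACGT"),
                          flank = 250L)
  tpl$masked <- matrix(integer(0), ncol = 2)   # isolate gates from masking
  ev <- function(start, len, strand = "+") {
    evaluate_primer(list(start = start, length = len, strand = strand),
                    tpl, primer_params())
  }
  expect_true("length" %in% ev(0L, 17L)$reasons)
  expect_true("length" %in% ev(0L, 26L)$reasons)
  # a candidate lying on the repeat contains a qualifying run
  on_ssr <- ev(250L, 20L)
  expect_true(all(c("overlaps_ssr", "ssr_content") %in% on_ssr$reasons))
  # pure-AT 20-mer in the left flank fails the run gate too
  at_tpl <- tpl
  at_tpl$sequence <- paste0(strrep("TA", 10), substring(tpl$sequence, 21))
  expect_true("ssr_content" %in%
                evaluate_primer(list(start = 0L, length = 20L, strand = "+"),
                                at_tpl, primer_params())$reasons)
  # homopolymer stretch: GC and Tm out of range (not an SSR by definition)
  a20 <- ev(270L + 100L, 20L, "-")
  expect_true(all(c("gc", "tm") %in% a20$reasons))
  expect_false("ssr_content" %in% a20$reasons)
  # hairpin stem of 7 pairs scores 28 > 24
  hp <- ev(270L + 130L, 18L)
  expect_true("hairpin" %in% hp$reasons)
  # ambiguity codes are rejected outright
  amb <- ev(270L + 158L, 20L)
  expect_true("ambiguous_base" %in% amb$reasons)
  # 3'-terminal masking and low-complexity fraction use the mask track
  pass0 <- ev(10L, 20L)
  mask_tpl <- tpl
  mask_tpl$masked <- matrix(c(28L, 31L), ncol = 2)    # covers position 29 = 3' end
  m3 <- evaluate_primer(list(start = 10L, length = 20L, strand = "+"),
                        mask_tpl, primer_params())
  expect_true("masked_3prime" %in% m3$reasons)
  frac_tpl <- tpl
  frac_tpl$masked <- matrix(c(10L, 21L), ncol = 2)    # 11 of 20 bases
  lc <- evaluate_primer(list(start = 10L, length = 20L, strand = "+"),
                        frac_tpl, primer_params())
  expect_true("low_complexity" %in% lc$reasons)
  expect_false("masked_3prime" %in% lc$reasons)
})

test_that("a constructed clean candidate passes every gate", {
  found <- FALSE
  for (seed in 1:10) {
    tpl <- planted_template(seed)
    for (a in seq(0L, 225L, by = 5L)) {
      ev <- evaluate_primer(list(start = a, length = 20L, strand = "+"),
                            tpl, primer_params())
      if (ev$pass) {
        expect_gte(ev$tm, 57); expect_lte(ev$tm, 63)
        expect_gte(ev$gc, 20); expect_lte(ev$gc, 60)
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("pair design is deterministic and respects every pair constraint", {
  params <- primer_params()
  n_ok <- 0
  for (seed in 101:115) {
    tpl <- planted_template(seed)
    pair <- design_pair(tpl, params)
    expect_identical(pair, design_pair(tpl, params))   # determinism
    if (pair$status != "ok") next
    n_ok <- n_ok + 1
    # primers never overlap the repeat; the product always contains it
    expect_lte(pair$fwd_start + pair$fwd_len, tpl$ssr[1])
    expect_gte(pair$rev_start, tpl$ssr[2])
    expect_gte(pair$product_size, params$product_min)
    expect_lte(pair$product_size, params$product_max)
    expect_equal(pair$product_size,
                 pair$rev_start + pair$rev_len - pair$fwd_start)
    expect_lte(abs(pair$tm_fwd - pair$tm_rev), params$max_tm_diff)
    expect_equal(pair$penalty,
                 abs(pair$fwd_len - 20) + abs(pair$rev_len - 20) +
                   abs(pair$tm_fwd - 60) + abs(pair$tm_rev - 60) +
                   abs(pair$product_size - 300) / 10,
                 tolerance = 1e-9)
    # gates re-verified through the single-candidate path
    for (cand in list(list(start = pair$fwd_start, length = pair$fwd_len,
                           strand = "+"),
                      list(start = pair$rev_start, length = pair$rev_len,
                           strand = "-"))) {
      expect_true(evaluate_primer(cand, tpl, params)$pass)
    }
  }
  expect_gt(n_ok, 10)
})

test_that("clean-flank templates nearly always yield a pair; masked flanks never do", {
  withr::with_seed(77, {
    motifs <- c("AT", "AAG", "ACGT", "AATGC", "AAGCGT")
    n_ok <- 0
    for (i in 1:200) {
      run <- substring(strrep(motifs[i %% 5 + 1], 12), 1, 14 + (i %% 10))
      tpl <- planted_template(1000 + i, run = run)
      if (design_pair(tpl)$status == "ok") n_ok <- n_ok + 1
    }
    expect_gte(n_ok / 200, 0.95)
    for (i in 1:10) {
      tpl <- planted_template(2000 + i)
      tpl$masked <- matrix(c(0L, 250L), ncol = 2)    # left flank fully masked
      res <- design_pair(tpl)
      expect_equal(res$status, "no_primer")
      expect_true(length(res$reasons) > 0)
    }
  })
})
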
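# Stem-loop scanner: planted structures, oracle equivalence, invariants.

test_that("a planted perfect inverted repeat is found exactly", {
  set.seed(101)
  seq <- generate_sequence(220, data.frame(position = 101, stem = 10,
                                           loop = 8), seed = 101)
  hits <- scan_stem_loops(seq, max_mismatch = 0)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_lte(top$start, 101)
  expect_gte(top$end, 101 + 2 * 10 + 8 - 1)
  expect_gte(top$stem_len, 10L)
  expect_equal(top$mismatches, 0L)
  # span bookkeeping invariant
  expect_equal(top$end - top$start + 1L, 2L * top$stem_len + top$loop_len)
})

test_that("one stem mutation is tolerated iff the budget allows it", {
  # all-A background cannot pair, so the planted hairpin is the only hit
  arm <- "GGCGGCGGCG"
  seq <- paste0(strrep("A", 100), arm, strrep("A", 8), revcomp(arm),
                strrep("A", 100))
  clean <- scan_stem_loops(seq, max_mismatch = 0)
  expect_equal(nrow(clean), 1L)
  expect_equal(clean$start, 101L)
  expect_equal(clean$stem_len, 10L)
  expect_equal(clean$loop_len, 8L)
  expect_equal(clean$mismatches, 0L)

  mut <- seq
  substr(mut, 105, 105) <- "A"  # break one stem pair
  strict <- scan_stem_loops(mut, max_mismatch = 0)
  expect_true(nrow(strict) == 0L || max(strict$stem_len) < 10L)
  lax <- scan_stem_loops(mut, max_mismatch = 1)
  expect_equal(nrow(lax), 1L)
  expect_equal(lax$mismatches, 1L)
  expect_equal(lax$start, 101L)
  # score decreases with the added mismatch at fixed stem length
  expect_lt(lax$score, clean$score)
})

test_that("wobble pairs count as half-score pairs, not mismatches", {
  arm <- "GGCGGCGGCG"
  # G opposite T at one position: wobble under default, mismatch otherwise
  arm3 <- revcomp(arm)
  substr(arm3, 6, 6) <- "T"  # pairs with the G at stem position 5
  seq <- paste0(strrep("A", 50), arm, strrep("C", 0), "TTTTT", arm3,
                strrep("A", 50))
  wob <- scan_stem_loops(seq, max_mismatch = 0, allow_wobble = TRUE)
  expect_equal(nrow(wob), 1L)
  expect_equal(wob$wobbles, 1L)
  expect_equal(wob$mismatches, 0L)
  no_wob <- scan_stem_loops(seq, max_mismatch = 0, allow_wobble = FALSE)
  expect_true(nrow(no_wob) == 0L || max(no_wob$stem_len) < 10L)
})

test_that("production scanner equals the brute-force oracle", {
  set.seed(500)
  for (i in 1:12) {
    seq <- random_dna(300)
    got <- scan_stem_loops(seq, min_stem = 6, collapse = FALSE)
    want <- oracle_scan(seq, min_stem = 6, collapse = FALSE)
    expect_equal(as.data.frame(got)[hit_cols], want[hit_cols],
                 ignore_attr = TRUE)
  }
})

test_that("reverse-complement symmetry (wobble disabled)", {
  set.seed(77)
  for (i in 1:8) {
    seq <- generate_sequence(250,
                             data.frame(position = 80, stem = 9, loop = 6))
    fwd <- scan_stem_loops(seq, min_stem = 7, allow_wobble = FALSE,
                           collapse = FALSE)
    rev <- scan_stem_loops(revcomp(seq), min_stem = 7, allow_wobble = FALSE,
                           collapse = FALSE)
    L <- nchar(seq)
    mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                           stem_len = rev$stem_len, loop_len = rev$loop_len,
                           mismatches = rev$mismatches)
    o1 <- do.call(order, as.data.frame(fwd)[c("start", "end")])
    o2 <- do.call(order, mirrored[c("start", "end")])
    expect_equal(as.data.frame(fwd)[o1, c("start", "end", "stem_len",
                                          "loop_len", "mismatches")],
                 mirrored[o2, ], ignore_attr = TRUE)
  }
})

test_that("relaxing thresholds never loses a locus", {
  set.seed(88)
  for (i in 1:6) {
    seq <- random_dna(300)
    strict <- scan_stem_loops(seq, min_stem = 7, max_mismatch = 0,
                              loop_range = c(4, 10), collapse = FALSE)
    lax <- scan_stem_loops(seq, min_stem = 7, max_mismatch = 1,
                           loop_range = c(3, 20), collapse = FALSE)
    if (!nrow(strict)) next
    for (j in seq_len(nrow(strict))) {
      covered <- any(lax$start <= strict$start[j] &
                       lax$end >= strict$end[j] &
                       lax$stem_len >= strict$stem_len[j])
      expect_true(covered)
    }
  }
})

test_that("scan_region restricts hits to annotated regions", {
  cfg <- simulation_config(seed = 5)
  ann <- generate_annotation(gene_order(reference_order()), config = cfg)
  f <- ann$features
  cr <- f[f$name == "CR", ]
  w <- f[f$name == "W", ]
  plant_pos <- cr$start + 50
  seq <- generate_sequence(ann, data.frame(position = plant_pos, stem = 11,
                                           loop = 7), seed = 6)
  in_cr <- scan_region(ann, seq, "CR_flank", max_mismatch = 0)
  expect_gte(nrow(in_cr), 1L)
  expect_true(any(in_cr$start <= plant_pos & in_cr$end >= plant_pos))
  expect_true(all(in_cr$start >= cr$start - 100))

  in_wancy <- scan_region(ann, seq, "WANCY", max_mismatch = 0,
                          allow_wobble = FALSE)
  expect_equal(nrow(in_wancy), 0L)

  custom <- scan_region(ann, seq, c(plant_pos - 30, plant_pos + 60),
                        max_mismatch = 0)
  expect_gte(nrow(custom), 1L)
  expect_error(scan_region(ann, substr(seq, 1, 100), "WANCY"), "length")
})

test_that("hairpin hits render to dot-bracket of matching width", {
  arm <- "GGCGGCGGCG"
  seq <- paste0(strrep("A", 30), arm, "TTTTT", revcomp(arm), strrep("A", 30))
  hit <- scan_stem_loops(seq, max_mismatch = 0)[1, ]
  db <- render_hairpin(hit)
  expect_equal(nchar(db[1]), nchar(db[2]))
  expect_equal(db[2], paste0(strrep("(", hit$stem_len),
                             strrep(".", hit$loop_len),
                             strrep(")", hit$stem_len)))
})
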
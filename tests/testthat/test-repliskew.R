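test_that("window skew arithmetic matches direct counts", {
  p <- gc_skew("GGGGCC", window = 6, step = 6)
  expect_equal(p$skew, (4 - 2) / (4 + 2))
  # equal G and C per window: flat zero profile
  flat <- gc_skew(strrep("GC", 500), window = 10, step = 10)
  expect_true(all(flat$skew == 0))
  expect_true(all(flat$cumulative == 0))
  # window with no G or C at all has skew 0, not NaN
  expect_equal(gc_skew("ATATAT", window = 6, step = 6)$skew, 0)
  # N is excluded from both counts
  expect_equal(gc_skew("GGNNCC", window = 6, step = 6)$skew, 0)
  expect_error(gc_skew("ACGT", window = 10, step = 1), "exceeds sequence length")
  expect_error(gc_skew("ACGT", window = 0, step = 1), ">= 1")
})

test_that("skew matches a brute-force recount and negates on complement", {
  seq <- random_dna(5000, seed = 3)
  p <- gc_skew(seq, window = 200, step = 37)
  expect_equal(p$skew, skew_oracle(seq, 200, 37))
  expect_true(all(abs(p$skew) <= 1))
  expect_true(all(diff(p$position) > 0))
  comp <- chartr("ACGT", "TGCA", seq)
  expect_equal(gc_skew(comp, window = 200, step = 37)$skew, -p$skew)
})

test_that("cumulative skew of the reverse complement mirrors the original", {
  seq <- random_dna(4000, seed = 9)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  a <- gc_skew(seq, window = 400, step = 400)$skew
  b <- gc_skew(rc, window = 400, step = 400)$skew
  expect_equal(b, -rev(a))
})

test_that("origin and terminus are called from constructed strand bias", {
  g <- simulate_genome(1e5, gc = 0.5, skew_amplitude = 0.1, seed = 1)
  call <- predict_ori_ter(gc_skew(g$sequence, 1000, 10, circular = TRUE))
  expect_lt(abs(call$ori_pos - g$ori_true), 2000)
  L <- 1e5
  ter_err <- min(call$ter_pos - 1, L - call$ter_pos + 1)
  expect_lt(ter_err, 2000)
  expect_gt(call$amplitude, 0)
  # invariant to uniform scaling of the skew values
  p <- gc_skew(g$sequence, 1000, 10, circular = TRUE)
  scaled <- p; scaled$cumulative <- 10 * p$cumulative
  call2 <- predict_ori_ter(scaled)
  expect_equal(call2$ori_pos, call$ori_pos)
  expect_equal(call2$ter_pos, call$ter_pos)
})

test_that("rotating the genome shifts both calls by the rotation", {
  g <- simulate_genome(5e4, gc = 0.5, skew_amplitude = 0.1, seed = 4)
  L <- 5e4; r <- 12000
  call0 <- predict_ori_ter(gc_skew(g$sequence, 1000, 10, circular = TRUE))
  rot <- rotate_to_origin(g$sequence, r + 1)  # new coords: x -> x - r
  call1 <- predict_ori_ter(gc_skew(rot, 1000, 10, circular = TRUE))
  shift_err <- function(a, b) {
    d <- (a - b) %% L
    min(d, L - d)
  }
  expect_lt(shift_err(call1$ori_pos, call0$ori_pos - r), 1000)
  expect_lt(shift_err(call1$ter_pos, call0$ter_pos - r), 1000)
})

test_that("flat profiles refuse an origin call", {
  expect_error(predict_ori_ter(gc_skew(strrep("GC", 1000), 100, 10)),
               "flat cumulative")
})

test_that("rotation preserves length and circular content", {
  expect_equal(rotate_to_origin("ABCDEF", 3), "CDEFAB")
  expect_equal(rotate_to_origin("ABCDEF", 1), "ABCDEF")
  seq <- random_dna(300, seed = 2)
  r <- 137
  rot <- rotate_to_origin(seq, r)
  expect_equal(nchar(rot), nchar(seq))
  # doubled original contains the rotation; rotating back is the identity
  expect_true(grepl(rot, paste0(seq, seq), fixed = TRUE))
  expect_equal(rotate_to_origin(rot, nchar(seq) - r + 2), seq)
  expect_error(rotate_to_origin(seq, 0), "outside sequence")
  expect_error(rotate_to_origin(seq, 301), "outside sequence")
  # DNAString input round-trips through the same rotation
  d <- Biostrings::DNAString("ACGGT")
  expect_equal(as.character(rotate_to_origin(d, 3)), "GGTAC")
})

test_that("terminal repeats circularize and trim exactly once", {
  core <- random_dna(9500, seed = 5)
  seq <- paste0(core, substr(core, 1, 500))
  res <- circularize(seq, min_overlap = 50)
  expect_true(res$circular)
  expect_equal(res$overlap, overlap_oracle(seq, 50))
  expect_equal(res$overlap, 500)
  expect_equal(nchar(res$sequence), 9500)
  expect_equal(res$sequence, core)
})

test_that("random sequence is reported not circular", {
  seq <- random_dna(2000, seed = 6)
  expect_equal(overlap_oracle(seq, 50), 0L)  # oracle confirms no match
  res <- circularize(seq, min_overlap = 50)
  expect_false(res$circular)
})

test_that("bounded mismatches within the overlap are tolerated", {
  core <- random_dna(9500, seed = 8)
  rep_ <- strsplit(substr(core, 1, 500), "")[[1]]
  flip <- c(100, 200, 300, 400, 500)  # 1% planted mismatches
  rep_[flip] <- chartr("ACGT", "CAGT", rep_[flip])
  seq <- paste0(core, paste(rep_, collapse = ""))
  # exact matching rejects the degenerate repeat
  expect_false(circularize(seq, min_overlap = 50,
                           max_mismatch_rate = 0)$circular)
  res <- circularize(seq, min_overlap = 50, max_mismatch_rate = 0.02)
  expect_true(res$circular)
  expect_equal(res$overlap,
               overlap_oracle(seq, 50, max_mismatch_rate = 0.02))
  expect_gte(res$overlap, 500 - 5)
  expect_error(circularize(seq, min_overlap = 5), "at least 10")
})
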
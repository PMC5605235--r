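test_that("find_hits resolves the model and genomic example oligos", {
  # model C5T3: single full-span hit with 3-base loops
  h <- find_hits("CCCCCTTTCCCCCTTTCCCCCTTTCCCCC")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 29L))
  expect_equal(h$loop_lengths[[1]], c(3L, 3L, 3L))

  # no cytosines at all
  expect_equal(nrow(find_hits(strrep("A", 29))), 0L)

  # DAP: leftmost-greedy 1-base loops; the trailing C5 cannot seed a
  # second complete match
  h2 <- find_hits("CCCCCGCCCCCGCCCCCGCCCCCGCCCCC")
  expect_equal(nrow(h2), 1L)
  expect_equal(c(h2$start, h2$end), c(0L, 23L))
  expect_equal(h2$tract_starts[[1]], c(0L, 6L, 12L, 18L))
  expect_equal(h2$loop_lengths[[1]], c(1L, 1L, 1L))
})

test_that("rule constructor rejects invalid parameter combinations", {
  expect_error(motif_rule(loop_min = 0), "loop_min")
  expect_error(motif_rule(loop_max = 0), "loop_max")
  expect_error(motif_rule(n_tracts = 1), "n_tracts")
})

test_that("minus-strand hits are reported on the forward axis", {
  s <- paste0(strrep("A", 100), "GGGGGTGGGGGTGGGGGTGGGGG", strrep("A", 40))
  hits <- scan_sequences(tibble::tibble(id = "x", sequence = s),
                         strands = "both")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 100L)
  expect_equal(hits$end, 123L)
  # plus-only scan of the same record sees nothing
  expect_equal(
    nrow(scan_sequences(tibble::tibble(id = "x", sequence = s), strands = "plus")),
    0L
  )
  # empty record list
  expect_equal(
    nrow(scan_sequences(tibble::tibble(id = character(0), sequence = character(0)))),
    0L
  )
})

test_that("scanner equals the brute-force regex oracle on random sequences", {
  withr::local_seed(101)
  rules <- list(motif_rule(),
                motif_rule(tract_len = 3, loop_max = 7),
                motif_rule(tract_len = 2, n_tracts = 3, loop_max = 4))
  n_with_hits <- 0
  for (i in 1:1000) {
    rule <- rules[[(i %% length(rules)) + 1]]
    s <- random_dna(sample(30:200, 1), c_rich = (i %% 2 == 0))
    got <- find_hits(s, rule)
    want <- oracle_scan(s, rule)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    n_with_hits <- n_with_hits + (nrow(want) > 0)
  }
  # the comparison must actually exercise matches, not just empty sets
  expect_gt(n_with_hits, 200)
})

test_that("hit geometry invariants hold on every reported hit", {
  withr::local_seed(7)
  rule <- motif_rule(tract_len = 3, loop_max = 9)
  for (i in 1:50) {
    s <- random_dna(300, c_rich = TRUE)
    hits <- scan_sequences(tibble::tibble(id = "r", sequence = s), rule)
    for (j in seq_len(nrow(hits))) {
      loops <- hits$loop_lengths[[j]]
      starts <- hits$tract_starts[[j]]
      expect_length(loops, rule$n_tracts - 1)
      expect_true(all(loops >= rule$loop_min & loops <= rule$loop_max))
      expect_equal(hits$end[j] - hits$start[j],
                   rule$n_tracts * rule$tract_len + sum(loops))
      expect_equal(diff(starts), rule$tract_len + loops)
    }
    # hits on one strand never overlap
    for (st in c("+", "-")) {
      hs <- hits[hits$strand == st, ]
      if (nrow(hs) > 1) {
        expect_true(all(hs$start[-1] >= hs$end[-nrow(hs)]))
      }
    }
  }
})

test_that("scanning a reverse-complemented sequence mirrors the hit set", {
  withr::local_seed(11)
  for (i in 1:100) {
    s <- random_dna(sample(60:200, 1), c_rich = TRUE)
    L <- nchar(s)
    fwd <- scan_sequences(tibble::tibble(id = "s", sequence = s))
    rev <- scan_sequences(tibble::tibble(id = "s", sequence = revcomp_chr(s)))
    key_fwd <- sort(paste(fwd$start, fwd$end, fwd$strand))
    key_mirror <- sort(paste(L - rev$end, L - rev$start,
                             ifelse(rev$strand == "+", "-", "+")))
    expect_equal(key_fwd, key_mirror)
  }
})

test_that("N breaks tracts but is allowed inside loops", {
  # N inside a tract: no hit
  expect_equal(nrow(find_hits("CCNCCTCCCCCTCCCCCTCCCCC")), 0L)
  # N as the loop base: full hit
  h <- find_hits("CCCCCNCCCCCNCCCCCNCCCCC")
  expect_equal(nrow(h), 1L)
  expect_equal(h$loop_lengths[[1]], c(1L, 1L, 1L))
})

test_that("hit counts are monotone in loop_max and match the oracle", {
  withr::local_seed(5)
  seqs <- tibble::tibble(id = "g", sequence = random_dna(50000, c_rich = TRUE))
  counts <- count_vs_loopmax(seqs, motif_rule(), c(7, 13, 19))
  expect_gt(counts$n_hits[counts$loop_max == 19], 0)
  expect_true(all(diff(counts$n_hits) >= 0))
  for (k in seq_len(nrow(counts))) {
    rule <- motif_rule(loop_max = counts$loop_max[k])
    expect_equal(counts$n_hits[k], nrow(oracle_scan_both(seqs$sequence, rule)))
  }
  expect_error(count_vs_loopmax(seqs, motif_rule(), 0), "loop_min")
})
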
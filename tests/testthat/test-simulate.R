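test_that("simulate_genome plants are recovered exactly by the scanner", {
  g <- simulate_genome(10000, planted = list(
    list(loop_lengths = c(3, 3, 3), strand = "+"),
    list(loop_lengths = c(1, 5, 19), strand = "-"),
    list(loop_lengths = c(2, 2, 2), strand = "+")
  ), seed = 7)
  hits <- scan_sequences(g$record)
  expect_equal(hits$start, g$truth$start)
  expect_equal(hits$end, g$truth$end)
  expect_equal(hits$strand, g$truth$strand)
  # planted sequences are embedded verbatim
  for (i in seq_len(nrow(g$truth))) {
    expect_equal(substr(g$record$sequence, g$truth$start[i] + 1,
                        g$truth$end[i]),
                 g$truth$sequence[i])
  }
})

test_that("a C-free background with no plants yields no hits", {
  g <- simulate_genome(5000, base_probs = c(A = .5, C = 0, G = 0, T = .5),
                       seed = 1)
  expect_equal(nrow(scan_sequences(g$record)), 0L)
})

test_that("generators are deterministic in their seed", {
  g1 <- simulate_genome(3000, planted = list(
    list(loop_lengths = c(2, 2, 2), strand = "+")), seed = 5)
  g2 <- simulate_genome(3000, planted = list(
    list(loop_lengths = c(2, 2, 2), strand = "+")), seed = 5)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$truth, g2$truth)

  a1 <- simulate_annotation(10, 1e5, seed = 1)
  a2 <- simulate_annotation(10, 1e5, seed = 1)
  expect_identical(a1, a2)

  t1 <- simulate_titration(noise_sd = 0.2, seed = 9)
  expect_identical(t1, simulate_titration(noise_sd = 0.2, seed = 9))

  m1 <- simulate_melt_curve(two_state_params(tm = 40), seed = 3)
  expect_identical(m1, simulate_melt_curve(two_state_params(tm = 40), seed = 3))
})

test_that("infeasible plant packing is an error", {
  expect_error(
    simulate_genome(100, planted = list(
      list(loop_lengths = c(19, 19, 19), strand = "+"),
      list(loop_lengths = c(19, 19, 19), strand = "+")
    ), seed = 1),
    "infeasible"
  )
})

test_that("annotation TSS are distinct and promoters constructible", {
  ann <- simulate_annotation(10, 1e5, seed = 1)
  expect_equal(length(unique(ann$tss$tss)), 10L)
  w <- promoter_windows(ann$tss, 1000, ann$chrom_sizes)
  expect_true(all(w$end - w$start <= 1000))
  expect_true(all(w$start >= 0))
  expect_error(simulate_annotation(100, 1e5, seed = 1), "too many genes")
})

test_that("GO term pool sizes are honoured", {
  ann <- simulate_annotation(40, 5e5, seed = 2,
                             term_sizes = c("GO:X" = 25, "GO:Y" = 10))
  sizes <- table(ann$go_map$go_id)
  expect_equal(unname(sizes[["GO:X"]]), 25L)
  expect_equal(unname(sizes[["GO:Y"]]), 10L)
  # no gene assigned twice to one term
  expect_false(any(duplicated(ann$go_map)))
})

test_that("two-state folded fraction is exactly 0.5 at the midpoint", {
  p <- two_state_params(tm = 50, noise_sd = 0)
  cv <- simulate_melt_curve(p, t_grid = c(seq(20, 49, 1), 50, seq(51, 80, 1)),
                            seed = 0)
  a50 <- cv$absorbance[cv$temperature_C == 50]
  bf <- p$baseline_folded[1] + p$baseline_folded[2] * 50
  bu <- p$baseline_unfolded[1] + p$baseline_unfolded[2] * 50
  expect_equal(a50, (bf + bu) / 2, tolerance = 1e-12)
})

test_that("melt-curve argument validation", {
  expect_error(simulate_melt_curve(two_state_params(tm = 50),
                                   direction = "anneal", anneal_offset = -1),
               "anneal_offset")
  expect_error(simulate_melt_curve(two_state_params(tm = 50, weight = 0.4)),
               "sum to 1")
  expect_error(simulate_melt_curve(two_state_params(tm = 50),
                                   t_grid = seq(0, 120, 1)), "\\[0, 100\\]")
})

test_that("simulated anneal curves show the requested hysteresis", {
  m <- simulate_melt_curve(two_state_params(tm = 40), seed = 12)
  a <- simulate_melt_curve(two_state_params(tm = 40), direction = "anneal",
                           anneal_offset = 20, seed = 13)
  res <- analyze_melt(dplyr::bind_rows(m, a))
  expect_lt(abs(res$hysteresis - 20), 1)
})
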
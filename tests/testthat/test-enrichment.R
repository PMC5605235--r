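chrom1 <- c(chr1 = 100000)

test_that("promoter windows follow the strand-aware upstream definition", {
  tss <- tibble::tibble(
    gene_id = c("plus", "minus", "edge"),
    chrom = "chr1",
    tss = c(5000, 5000, 200),
    strand = c("+", "-", "+")
  )
  w <- promoter_windows(tss, 1000, chrom1)
  expect_equal(w$start[w$name == "plus"], 4000)
  expect_equal(w$end[w$name == "plus"], 5000)
  expect_equal(w$start[w$name == "minus"], 5001)
  expect_equal(w$end[w$name == "minus"], 6001)
  expect_equal(c(w$start[w$name == "edge"], w$end[w$name == "edge"]),
               c(0, 200))
  expect_error(promoter_windows(tss, 1000, c(chr2 = 1e5)), "chr1")
})

test_that("hit/window overlap uses >=1 bp with half-open adjacency", {
  windows <- tibble::tibble(chrom = "chr1", start = c(129, 20),
                            end = c(1129, 1020), name = c("gA", "gB"),
                            score = 0, strand = "+")
  # 1-bp overlap counts
  ov <- overlap_hits(tibble::tibble(chrom = "chr1", start = 100, end = 130),
                     windows[1, ])
  expect_equal(ov$n_overlapping, 1L)
  # touching end-to-start does not
  ov2 <- overlap_hits(tibble::tibble(chrom = "chr1", start = 0, end = 20),
                      windows[2, ])
  expect_equal(ov2$n_overlapping, 0L)
  expect_equal(ov2$per_gene$n_hits, 0L)
})

test_that("a hit spanning two windows counts once but credits both genes", {
  windows <- tibble::tibble(chrom = "chr1", start = c(100, 180),
                            end = c(200, 300), name = c("gA", "gB"),
                            score = 0, strand = "+")
  hits <- tibble::tibble(chrom = "chr1", start = 170, end = 190)
  ov <- overlap_hits(hits, windows)
  expect_equal(ov$n_overlapping, 1L)
  expect_equal(sort(ov$per_gene$n_hits), c(1L, 1L))
  want <- oracle_overlap(hits, windows)
  expect_equal(ov$n_overlapping, want$n_overlapping)
})

test_that("overlap counting equals the brute-force pairwise oracle", {
  withr::local_seed(20)
  for (rep in 1:10) {
    windows <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
      start = sample.int(5e4, 30), name = sprintf("g%02d", 1:30),
      score = 0, strand = "+"
    )
    windows$end <- windows$start + 1000
    hits <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
      start = sample.int(5e4, 50)
    )
    hits$end <- hits$start + sample(20:60, 50, replace = TRUE)
    got <- overlap_hits(hits, windows)
    want <- oracle_overlap(hits, windows)
    expect_equal(got$n_overlapping, want$n_overlapping)
    got_counts <- setNames(got$per_gene$n_hits, got$per_gene$gene_id)
    expect_equal(got_counts[names(want$per_gene)], want$per_gene)
  }
})

test_that("multi-hit gene counting", {
  expect_equal(genes_with_multiple_hits(c(a = 1, b = 2, c = 5)), 2L)
  expect_equal(genes_with_multiple_hits(tibble::tibble(gene_id = character(0),
                                                       n_hits = integer(0))),
               0L)
})

test_that("chance fraction is the union coverage of promoter windows", {
  w1 <- tibble::tibble(chrom = "chr1", start = 4000, end = 5000,
                       name = "g1", score = 0, strand = "+")
  expect_equal(chance_expected_fraction(w1, chrom1), 0.01)
  # duplicated window covers nothing extra
  expect_equal(chance_expected_fraction(rbind(w1, w1), chrom1), 0.01)

  withr::local_seed(33)
  toy <- c(chr1 = 1e6)
  w <- tibble::tibble(chrom = "chr1", start = sample.int(998000, 50),
                      name = sprintf("g%02d", 1:50), score = 0, strand = "+")
  w$end <- w$start + 1000
  expect_equal(chance_expected_fraction(w, toy),
               oracle_coverage_fraction(w, toy))
  expect_error(chance_expected_fraction(w1, c(chr1 = 0)), "genome length")
})

test_that("chi-squared goodness of fit matches the hand-worked example", {
  # (30 - 20)^2/20 + (70 - 80)^2/80 = 6.25
  res <- chi_squared_enrichment(30, 100, 0.2)
  expect_equal(res$chi_squared, 6.25)
  expect_equal(res$p_value, pchisq(6.25, 1, lower.tail = FALSE))

  # exact agreement with expectation: statistic 0, p 1
  res0 <- chi_squared_enrichment(20, 100, 0.2)
  expect_equal(res0$chi_squared, 0)
  expect_equal(res0$p_value, 1)

  # label swap invariance: swapping the two cells leaves the statistic
  res_swap <- chi_squared_enrichment(70, 100, 0.8)
  expect_equal(res_swap$chi_squared, res$chi_squared)

  expect_error(chi_squared_enrichment(30, 100, 0), "between 0 and 1")
  expect_warning(chi_squared_enrichment(1, 20, 0.01), "below 1")
  expect_equal(tidy(res)$chi_squared, 6.25)
})

test_that("GO enrichment filters small terms and adjusts with BH", {
  withr::local_seed(44)
  universe <- sprintf("g%03d", 1:300)
  go_map <- dplyr::bind_rows(
    tibble::tibble(gene_id = universe[1:120], go_id = "GO:BIG"),
    tibble::tibble(gene_id = universe[200:230], go_id = "GO:SMALL")
  )
  # hit genes drawn almost entirely from GO:BIG
  hits <- universe[1:40]
  res <- go_enrichment(hits, universe, go_map, min_genes = 100)
  expect_equal(res$go_id, "GO:BIG")          # GO:SMALL filtered out
  expect_equal(res$n_genes_with_term, 120L)
  expect_equal(res$n_hit_genes_with_term, 40L)
  expect_equal(res$direction, "enriched")
  expect_lt(res$q_value, 0.001)
  # q equals p when only one term is tested
  expect_equal(res$q_value, res$p_value)
  expect_error(go_enrichment(c("zz"), universe, go_map), "subset")
  expect_error(go_enrichment("g001", character(0), go_map), "empty|subset")
})

test_that("BH q-values are monotone in p-rank and tie-stable", {
  withr::local_seed(55)
  universe <- sprintf("g%03d", 1:400)
  terms <- lapply(1:6, function(i) {
    tibble::tibble(gene_id = sample(universe, 120),
                   go_id = sprintf("GO:%d", i))
  })
  go_map <- dplyr::bind_rows(terms)
  res <- go_enrichment(sample(universe, 50), universe, go_map,
                       min_genes = 100)
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_true(all(res$q_value <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("planted promoter enrichment is detected end to end", {
  # hits placed into promoters at 10x the background per-base rate must
  # light up the chi-squared test in nearly every replicate
  withr::local_seed(66)
  n_sig <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    ann <- simulate_annotation(20, 1e5, seed = 1000 + i)
    w <- promoter_windows(ann$tss, 1000, ann$chrom_sizes)
    f <- chance_expected_fraction(w, ann$chrom_sizes)
    p_prom <- 10 * f / (10 * f + (1 - f))
    starts <- vapply(runif(15) < p_prom, function(in_prom) {
      if (in_prom) {
        row <- w[sample.int(nrow(w), 1), ]
        sample(seq(row$start, row$end - 1), 1)
      } else {
        sample.int(1e5 - 30, 1)
      }
    }, numeric(1))
    hits <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 23)
    ov <- overlap_hits(hits, w)
    res <- chi_squared_enrichment(ov$n_overlapping, nrow(hits), f)
    if (res$p_value < 0.01) n_sig <- n_sig + 1
  }
  expect_gte(n_sig, 95)
})
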
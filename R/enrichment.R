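# Promoter-window enrichment of scanner hits, and GO over-representation.
# Interval arithmetic is delegated to GenomicRanges/IRanges; the statistics
# assembly (chance model, 1-df goodness of fit, Fisher + BH per GO term) is
# defined here.

# Internal: intervals tibble -> GRanges (strand ignored for overlap tests).
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Construct promoter windows upstream of transcription start sites
#'
#' A promoter is the `upstream` bases immediately 5' of a gene's TSS: for a
#' `+` gene the window is `[tss - upstream, tss)`, for a `-` gene
#' `[tss + 1, tss + 1 + upstream)` (0-based half-open). Windows are clipped
#' to the chromosome; windows clipped to zero width are dropped. One window
#' per annotation row (gene-level TSS).
#'
#' @param tss Tibble with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (`+`/`-`), e.g. from [read_tss()] or [simulate_annotation()].
#' @param upstream Window size in bp (default 1000, the 1-kb promoter).
#' @param chrom_sizes Named vector or `(chrom, size)` data frame; every
#'   chromosome in `tss` must be present.
#' @return Interval tibble (`chrom`, `start`, `end`, `name` = gene id,
#'   `score`, `strand`).
#' @export
promoter_windows <- function(tss, upstream = 1000, chrom_sizes) {
  if (upstream < 1) abort("`upstream` must be >= 1")
  sizes <- as_chrom_sizes(chrom_sizes)
  unknown <- setdiff(unique(tss$chrom), names(sizes))
  if (length(unknown) > 0) {
    abort(paste0("chromosome(s) missing from `chrom_sizes`: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(tss$tss < 0)) abort("TSS positions must be >= 0")
  start <- ifelse(tss$strand == "+", tss$tss - upstream, tss$tss + 1)
  end <- ifelse(tss$strand == "+", tss$tss, tss$tss + 1 + upstream)
  size <- unname(sizes[tss$chrom])
  out <- tibble(
    chrom = tss$chrom,
    start = pmax(0, pmin(start, size)),
    end = pmax(0, pmin(end, size)),
    name = tss$gene_id,
    score = 0,
    strand = tss$strand
  )
  out[out$end > out$start, ]
}

#' Count hits overlapping promoter windows
#'
#' A hit overlaps a promoter if it shares at least one base with the window,
#' regardless of the strand of either feature (half-open adjacency does not
#' count). Each hit contributes at most once to the overlapping-hit count
#' but increments the count of every gene whose window it touches.
#'
#' @param hits Interval tibble with `chrom`, `start`, `end` (e.g.
#'   [hits_to_bed()] output or a BED file via [read_bed()]).
#' @param windows Promoter windows from [promoter_windows()] (`name` holds
#'   the gene id).
#' @return List with `n_overlapping` (integer) and `per_gene` (tibble
#'   `gene_id`, `n_hits`, one row per window gene including zeros).
#' @export
overlap_hits <- function(hits, windows) {
  genes <- windows$name
  if (nrow(hits) == 0 || nrow(windows) == 0) {
    return(list(
      n_overlapping = 0L,
      per_gene = tibble(gene_id = unique(genes),
                        n_hits = rep(0L, length(unique(genes))))
    ))
  }
  ov <- GenomicRanges::findOverlaps(intervals_to_granges(hits),
                                    intervals_to_granges(windows),
                                    minoverlap = 1L)
  hit_gene <- distinct(tibble(
    hit = S4Vectors::queryHits(ov),
    gene_id = genes[S4Vectors::subjectHits(ov)]
  ))
  per_gene <- count(hit_gene, .data$gene_id, name = "n_hits")
  all_genes <- tibble(gene_id = unique(genes))
  per_gene <- left_join(all_genes, per_gene, by = "gene_id")
  per_gene$n_hits <- ifelse(is.na(per_gene$n_hits), 0L, per_gene$n_hits)
  list(
    n_overlapping = length(unique(hit_gene$hit)),
    per_gene = per_gene
  )
}

#' Number of genes with two or more promoter hits
#'
#' @param per_gene Tibble with columns `gene_id` and `n_hits`, as returned in
#'   `overlap_hits()$per_gene` (a named count vector is also accepted).
#' @return Integer count of genes whose promoter carries `>= 2` hits.
#' @export
genes_with_multiple_hits <- function(per_gene) {
  counts <- if (is.data.frame(per_gene)) per_gene$n_hits else per_gene
  if (length(counts) == 0) return(0L)
  if (any(counts < 0)) abort("hit counts must be >= 0")
  sum(counts >= 2)
}

#' Fraction of the genome covered by promoter windows
#'
#' The chance expectation for promoter overlap: the union coverage of all
#' promoter windows (overlapping windows merged before summing) divided by
#' the total genome length.
#'
#' @param windows Interval tibble of (clipped) promoter windows.
#' @param chrom_sizes Named vector or `(chrom, size)` data frame.
#' @return Number in `[0, 1]`.
#' @export
chance_expected_fraction <- function(windows, chrom_sizes) {
  sizes <- as_chrom_sizes(chrom_sizes)
  genome <- sum(as.numeric(sizes))
  if (genome <= 0) abort("total genome length must be > 0")
  if (nrow(windows) == 0) return(0)
  covered <- sum(IRanges::width(GenomicRanges::reduce(
    intervals_to_granges(windows))))
  covered / genome
}

#' Chi-squared test of promoter enrichment
#'
#' One-degree-of-freedom goodness-of-fit over the two cells (hits
#' overlapping a promoter, hits not overlapping) against the chance
#' expectation, without continuity correction:
#' `X^2 = sum((O - E)^2 / E)` with `E = (f, 1 - f) * total` and the p-value
#' from the chi-squared distribution with 1 df.
#'
#' @param observed Number of hits overlapping promoters.
#' @param total Total number of hits.
#' @param expected_fraction Chance overlap fraction, strictly inside (0, 1)
#'   (see [chance_expected_fraction()]).
#' @return An object of class `imotif_enrichment`; use [tidy()] or
#'   [glance()] for a one-row tibble. If an expected cell is below 1 a
#'   warning is attached (`$small_expected`).
#' @examples
#' chi_squared_enrichment(30, 100, 0.2)   # X^2 = 6.25
#' @export
chi_squared_enrichment <- function(observed, total, expected_fraction) {
  if (total <= 0) abort("`total` must be > 0")
  if (observed < 0 || observed > total) abort("need 0 <= observed <= total")
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    abort("`expected_fraction` must be strictly between 0 and 1")
  }
  O <- c(observed, total - observed)
  E <- c(expected_fraction, 1 - expected_fraction) * total
  chi_squared <- sum((O - E)^2 / E)
  small <- any(E < 1)
  if (small) {
    warn("an expected cell count is below 1; the chi-squared approximation is unreliable")
  }
  structure(
    list(observed = as.integer(observed), total = as.integer(total),
         expected_fraction = expected_fraction,
         expected = E[1], chi_squared = chi_squared,
         p_value = pchisq(chi_squared, df = 1, lower.tail = FALSE),
         small_expected = small),
    class = "imotif_enrichment"
  )
}

#' @export
print.imotif_enrichment <- function(x, ...) {
  cat(sprintf(
    "<imotif_enrichment> %d / %d hits in promoters (%.1f%%; %.1f%% expected)\n  chi-squared = %.4g (1 df), p = %.3g\n",
    x$observed, x$total, 100 * x$observed / x$total,
    100 * x$expected_fraction, x$chi_squared, x$p_value))
  invisible(x)
}

#' @method tidy imotif_enrichment
#' @export
tidy.imotif_enrichment <- function(x, ...) {
  tibble(observed = x$observed, total = x$total,
         observed_fraction = x$observed / x$total,
         expected_fraction = x$expected_fraction,
         chi_squared = x$chi_squared, p_value = x$p_value)
}

#' @method glance imotif_enrichment
#' @export
glance.imotif_enrichment <- function(x, ...) tidy(x)

#' Gene Ontology over-representation among promoter-hit genes
#'
#' For every GO term annotating at least `min_genes` genes of the universe,
#' tests the 2x2 association between carrying a promoter hit and carrying
#' the term (two-sided Fisher's exact test), then adjusts the tested terms
#' by the Benjamini-Hochberg step-up procedure. Terms below the size filter
#' are excluded before testing and do not consume multiple-testing budget.
#'
#' @param hit_genes Character vector of genes with at least one promoter
#'   hit (must be a subset of `universe_genes`).
#' @param universe_genes Character vector of all genes considered.
#' @param go_map Tibble with columns `gene_id`, `go_id`.
#' @param min_genes Minimum term size within the universe (default 100).
#' @return Tibble with one row per tested term: `go_id`,
#'   `n_genes_with_term`, `n_hit_genes_with_term`, `p_value`, `q_value`,
#'   `direction` (`enriched`/`depleted`), sorted by `q_value`.
#' @export
go_enrichment <- function(hit_genes, universe_genes, go_map,
                          min_genes = 100) {
  universe_genes <- unique(universe_genes)
  hit_genes <- unique(hit_genes)
  if (length(universe_genes) == 0) abort("empty gene universe")
  if (!all(hit_genes %in% universe_genes)) {
    abort("`hit_genes` must be a subset of `universe_genes`")
  }
  gm <- distinct(go_map[go_map$gene_id %in% universe_genes, ])
  term_sizes <- count(gm, .data$go_id, name = "n_genes_with_term")
  term_sizes <- term_sizes[term_sizes$n_genes_with_term >= min_genes, ]
  n_univ <- length(universe_genes)
  n_hit <- length(hit_genes)
  if (nrow(term_sizes) == 0) {
    return(tibble(go_id = character(), n_genes_with_term = integer(),
                  n_hit_genes_with_term = integer(), p_value = numeric(),
                  q_value = numeric(), direction = character()))
  }
  res <- map(seq_len(nrow(term_sizes)), function(i) {
    term <- term_sizes$go_id[[i]]
    n_term <- term_sizes$n_genes_with_term[[i]]
    term_genes <- gm$gene_id[gm$go_id == term]
    a <- sum(hit_genes %in% term_genes)          # hit & term
    b <- n_hit - a                               # hit & !term
    c_ <- n_term - a                             # !hit & term
    d <- n_univ - n_hit - c_                     # !hit & !term
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
    expected <- n_hit * n_term / n_univ
    tibble(go_id = term, n_genes_with_term = n_term,
           n_hit_genes_with_term = as.integer(a), p_value = p,
           direction = if (a > expected) "enriched" else "depleted")
  })
  out <- bind_rows(res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  arrange(out[, c("go_id", "n_genes_with_term", "n_hit_genes_with_term",
                  "p_value", "q_value", "direction")], .data$q_value)
}
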
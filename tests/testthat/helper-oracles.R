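# Independent oracles used across the suite. These deliberately take a
# different route than the package implementation: regular-expression
# matching with lazy quantifiers for the scanner, per-base accumulation for
# interval coverage, and O(n*m) pairwise checks for overlaps.

# Brute-force scanner oracle: leftmost, non-overlapping matches with
# shortest admissible loops, via a lazy-quantified PCRE pattern.
oracle_scan <- function(sequence, rule = motif_rule()) {
  pattern <- sprintf("%s{%d}(?:[ACGTN]{%d,%d}?%s{%d}){%d}",
                     rule$base, rule$tract_len, rule$loop_min, rule$loop_max,
                     rule$base, rule$tract_len, rule$n_tracts - 1)
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Both-strand oracle: C-rule matches plus G-rule matches on the stored
# strand, as (start, end, strand) keys.
oracle_scan_both <- function(sequence, rule = motif_rule()) {
  plus <- oracle_scan(sequence, rule)
  comp <- rule
  comp$base <- if (rule$base == "C") "G" else "C"
  minus <- oracle_scan(sequence, comp)
  out <- rbind(
    if (nrow(plus)) cbind(plus, strand = "+") else NULL,
    if (nrow(minus)) cbind(minus, strand = "-") else NULL
  )
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0))
  }
  out
}

# Random DNA sequence; `c_rich` biases composition toward C so that rule
# matches actually occur at test lengths.
random_dna <- function(n, c_rich = FALSE) {
  probs <- if (c_rich) c(A = .15, C = .45, G = .2, T = .2) else rep(.25, 4)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Per-base coverage oracle for the union fraction of windows on one genome.
oracle_coverage_fraction <- function(windows, chrom_sizes) {
  sizes <- if (is.data.frame(chrom_sizes)) {
    setNames(chrom_sizes$size, chrom_sizes$chrom)
  } else chrom_sizes
  covered <- 0
  for (chr in names(sizes)) {
    mask <- logical(sizes[[chr]])
    w <- windows[windows$chrom == chr, ]
    for (i in seq_len(nrow(w))) {
      if (w$end[i] > w$start[i]) mask[(w$start[i] + 1):w$end[i]] <- TRUE
    }
    covered <- covered + sum(mask)
  }
  covered / sum(as.numeric(sizes))
}

# O(n*m) pairwise interval-overlap oracle (0-based half-open).
oracle_overlap <- function(hits, windows) {
  n_overlapping <- 0L
  per_gene <- setNames(rep(0L, length(unique(windows$name))),
                       unique(windows$name))
  for (i in seq_len(nrow(hits))) {
    touched <- character(0)
    for (j in seq_len(nrow(windows))) {
      if (hits$chrom[i] == windows$chrom[j] &&
          hits$start[i] < windows$end[j] &&
          windows$start[j] < hits$end[i]) {
        touched <- c(touched, windows$name[j])
      }
    }
    if (length(touched) > 0) n_overlapping <- n_overlapping + 1L
    for (g in unique(touched)) per_gene[[g]] <- per_gene[[g]] + 1L
  }
  list(n_overlapping = n_overlapping, per_gene = per_gene)
}

# All-placements count of a mini rule in one sequence (used against the
# exhaustive i.i.d. expectation): counts (start, loop-combination) pairs.
oracle_placement_count <- function(sequence, rule) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  t <- rule$tract_len
  is_tract <- function(s) {
    s >= 1 && s + t - 1 <= L && all(chars[s:(s + t - 1)] == rule$base)
  }
  count <- 0L
  count_from <- function(pos_after, n_left) {
    if (n_left == 0) {
      count <<- count + 1L
      return(invisible(NULL))
    }
    for (l in rule$loop_min:rule$loop_max) {
      s <- pos_after + l
      if (is_tract(s)) count_from(s + t, n_left - 1)
    }
  }
  for (i in seq_len(L)) {
    if (is_tract(i)) count_from(i + t, rule$n_tracts - 1L)
  }
  count
}
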
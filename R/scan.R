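# Core folding-rule scanner.
#
# A match is n_tracts runs of exactly tract_len tract-base characters (runs
# may sit inside longer homopolymer runs; the tract anchors where the rule
# places them) separated by loops of loop_min..loop_max arbitrary bases.
# Canonicalization: hits are non-overlapping and found leftmost-first;
# within a hit each successive tract is placed at the earliest admissible
# position (shortest loops first, backtracking only when no completion
# exists). N never matches the tract base but is a legal loop base.

# Internal: logical vector ok[i] = a full tract fits starting at 1-based i.
tract_start_ok <- function(chars, base, tract_len) {
  L <- length(chars)
  n_start <- L - tract_len + 1
  if (n_start < 1) return(logical(0))
  cs0 <- c(0L, cumsum(chars == base))
  (cs0[(1:n_start) + tract_len] - cs0[1:n_start]) == tract_len
}

# Internal: earliest-loop completion of the remaining tracts.
# pos_after: 1-based position just after the previous tract; returns the
# 1-based start positions of the remaining tracts, or NULL.
place_tracts <- function(ok, pos_after, n_left, rule) {
  if (n_left == 0) return(integer(0))
  n_start <- length(ok)
  for (l in rule$loop_min:rule$loop_max) {
    s <- pos_after + l
    if (s > n_start) break
    if (ok[s]) {
      rest <- place_tracts(ok, s + rule$tract_len, n_left - 1, rule)
      if (!is.null(rest)) return(c(s, rest))
    }
  }
  NULL
}

# Internal: scan one character vector with one rule on the stored strand.
# Returns a tibble of hits with 0-based half-open coordinates.
scan_chars <- function(chars, rule, source_id, strand) {
  empty <- tibble(
    source_id = character(), start = integer(), end = integer(),
    strand = character(), tract_starts = list(), loop_lengths = list(),
    total_loop_length = integer(), matched_sequence = character()
  )
  ok <- tract_start_ok(chars, rule$base, rule$tract_len)
  if (length(ok) == 0 || !any(ok)) return(empty)
  cand <- which(ok)
  hits <- list()
  cursor <- 1L
  for (i in cand) {
    if (i < cursor) next
    rest <- place_tracts(ok, i + rule$tract_len, rule$n_tracts - 1L, rule)
    if (is.null(rest)) next
    starts <- c(i, rest)
    end1 <- starts[rule$n_tracts] + rule$tract_len - 1L
    loops <- diff(starts) - rule$tract_len
    hits[[length(hits) + 1L]] <- tibble(
      source_id = source_id,
      start = starts[1] - 1L, end = end1, strand = strand,
      tract_starts = list(starts - 1L), loop_lengths = list(as.integer(loops)),
      total_loop_length = as.integer(sum(loops)),
      matched_sequence = paste(chars[starts[1]:end1], collapse = "")
    )
    cursor <- end1 + 1L
  }
  if (length(hits) == 0) return(empty)
  bind_rows(hits)
}

#' Find folding-rule hits on the stored strand of one sequence
#'
#' Locates non-overlapping, leftmost-first matches of `rule` on the given
#' sequence as stored (no reverse-complement search; see [scan_sequences()]
#' for both-strand scanning). Within each hit, tracts are placed
#' leftmost-greedily: each successive tract starts at the earliest position
#' admitting a complete match, so loops are as short as possible. `N` never
#' matches the tract base but may appear in loops.
#'
#' @param sequence A character scalar, or a one-row data frame with columns
#'   `id` and `sequence` (as returned by [read_fasta()]).
#' @param rule A [motif_rule()].
#' @param id Identifier used in the output when `sequence` is a bare string.
#' @return A tibble with one row per hit: `source_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`), list-columns `tract_starts` and
#'   `loop_lengths`, `total_loop_length` and `matched_sequence`.
#' @examples
#' find_hits("CCCCCTTTCCCCCTTTCCCCCTTTCCCCC")   # one hit, loops 3/3/3
#' @export
find_hits <- function(sequence, rule = motif_rule(), id = NULL) {
  rec <- as_sequence_record(sequence, id)
  chars <- seq_chars(rec$sequence)
  if (length(chars) > 0 && !all(chars %in% DNA_ALPHABET)) {
    abort("sequence contains characters outside A/C/G/T/N")
  }
  scan_chars(chars, rule, rec$id, "+")
}

#' Scan a set of sequences for folding-rule hits on one or both strands
#'
#' Plus-strand hits match `rule` on the stored sequence. Minus-strand hits
#' match the complementary-base rule (G-runs for the default C rule) on the
#' stored sequence and are reported with strand `"-"` on the forward
#' coordinate axis; a minus-strand hit means the i-motif-forming C-rich
#' strand is the reverse complement of the stored sequence. Hits from the two
#' strands are reported independently, without cross-strand merging.
#'
#' @param sequences A data frame with columns `id` and `sequence` (e.g. from
#'   [read_fasta()] or [simulate_genome()]).
#' @param rule A [motif_rule()].
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return A hit tibble as in [find_hits()], ordered by source, start and
#'   strand.
#' @export
scan_sequences <- function(sequences, rule = motif_rule(),
                           strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  out <- map(seq_len(nrow(sequences)), function(i) {
    chars <- seq_chars(toupper(sequences$sequence[[i]]))
    id <- sequences$id[[i]]
    res <- list()
    if (strands %in% c("both", "plus")) {
      res$plus <- scan_chars(chars, rule, id, "+")
    }
    if (strands %in% c("both", "minus")) {
      res$minus <- scan_chars(chars, complement_rule(rule), id, "-")
    }
    bind_rows(res)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(scan_chars(character(0), rule, character(0), "+"))
  }
  arrange(out, .data$source_id, .data$start, .data$strand)
}

#' Hit counts as a function of the maximum loop length
#'
#' Re-scans the input for each candidate `loop_max` and tabulates the total
#' number of hits, the scaling curve used to contrast the observed
#' near-linear growth of genomic hit counts with the cubic growth expected
#' under an i.i.d. base model ([expected_hits_iid()]).
#'
#' @param sequences Sequence table as in [scan_sequences()].
#' @param rule Base rule; its `loop_max` is replaced by each candidate value.
#' @param loopmax_values Integer vector of `loop_max` values, each `>=`
#'   `rule$loop_min`.
#' @param strands Strand selection passed to [scan_sequences()].
#' @return Tibble with columns `loop_max` and `n_hits` (non-decreasing in
#'   `loop_max`).
#' @export
count_vs_loopmax <- function(sequences, rule = motif_rule(), loopmax_values,
                             strands = "both") {
  loopmax_values <- as.integer(loopmax_values)
  if (any(loopmax_values < rule$loop_min)) {
    abort("all `loopmax_values` must be >= the rule's `loop_min`")
  }
  tibble(
    loop_max = loopmax_values,
    n_hits = map_int(loopmax_values, function(L) {
      r <- rule
      r$loop_max <- L
      nrow(scan_sequences(sequences, r, strands = strands))
    })
  )
}

#' Expected number of rule-match placements in an i.i.d. sequence
#'
#' Computes the exact expected number of (start position, loop-length
#' combination) placements of `rule` in an i.i.d. random sequence: the sum
#' over all loop-length combinations of the probability that that
#' combination matches at a given start, times the number of admissible
#' starts. No clump/first-occurrence correction is applied -- this is the
#' "simple probability" expectation, which for a 4-tract rule with
#' `loop_min = 1` grows as the cube of `loop_max` (one factor per loop).
#'
#' @param rule A [motif_rule()].
#' @param base_probs Probability 4-vector named `A`, `C`, `G`, `T` (must sum
#'   to 1 within 1e-9).
#' @param length Sequence length.
#' @return Expected placement count (a number).
#' @examples
#' expected_hits_iid(motif_rule(), c(A = .25, C = .25, G = .25, T = .25), 2e5)
#' @export
expected_hits_iid <- function(rule, base_probs, length) {
  if (!all(c("A", "C", "G", "T") %in% names(base_probs))) {
    abort("`base_probs` must be named A, C, G, T")
  }
  base_probs <- base_probs[c("A", "C", "G", "T")]
  if (any(base_probs < 0) || any(base_probs > 1)) {
    abort("`base_probs` must lie in [0, 1]")
  }
  if (abs(sum(base_probs) - 1) > 1e-9) abort("`base_probs` must sum to 1")
  p <- unname(base_probs[rule$base])
  k <- rule$n_tracts
  t <- rule$tract_len
  # Distribution of total loop length: (k-1)-fold convolution of a uniform
  # indicator over loop_min..loop_max. counts[s] = number of combinations
  # with total loop length total_loops[s].
  unit <- rep(1, rule$loop_max - rule$loop_min + 1)
  counts <- 1
  for (i in seq_len(k - 1)) counts <- convolve_full(counts, unit)
  total_loops <- (k - 1) * rule$loop_min + seq_along(counts) - 1
  spans <- k * t + total_loops
  starts <- pmax(0, length - spans + 1)
  sum(counts * starts) * p^(k * t)
}

# Internal: full linear convolution of two coefficient vectors.
convolve_full <- function(a, b) {
  n <- length(a) + length(b) - 1
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Convert a hit table to BED6-style intervals
#'
#' The BED name field encodes the source id and the loop lengths of each hit
#' (`source|l1,l2,l3`); the score field carries the total loop length.
#'
#' @param hits Hit tibble from [scan_sequences()].
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, suitable for [write_bed()].
#' @export
hits_to_bed <- function(hits) {
  tibble(
    chrom = hits$source_id,
    start = hits$start,
    end = hits$end,
    name = paste0(hits$source_id, "|",
                  map_chr(hits$loop_lengths, paste, collapse = ",")),
    score = hits$total_loop_length,
    strand = hits$strand
  )
}
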
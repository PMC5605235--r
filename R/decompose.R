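#' Decompose an oligonucleotide into tracts and loops
#'
#' Produces the canonical tract/loop decomposition used to compute the total
#' loop length (the sum of all loop bases) of a candidate i-motif
#' oligonucleotide.
#'
#' If the strict folding rule matches anywhere in the sequence, the leftmost
#' greedy match is used (tracts of exactly `rule$tract_len`, shortest
#' admissible loops) and `fallback_used` is `FALSE`. Sequences that carry an
#' i-motif-like architecture without satisfying the strict rule (for example
#' fewer than `n_tracts` runs of length `>= tract_len`, or loops longer than
#' `loop_max`) are decomposed by a run-length fallback: the `n_tracts`
#' longest maximal runs of the tract base (ties broken leftmost), taken in
#' genomic order, with loops defined as the gaps between consecutive chosen
#' runs. In the fallback, tract intervals are whole runs and may be longer
#' than `tract_len`, and loops may fall outside `[loop_min, loop_max]`.
#'
#' @param sequence Character scalar or one-row sequence data frame.
#' @param rule A [motif_rule()].
#' @param id Identifier for the output row.
#' @return One-row tibble: `sequence_id`, list-columns `tract_starts`,
#'   `tract_ends` (0-based half-open) and `loop_lengths`,
#'   `total_loop_length`, `fallback_used`.
#' @examples
#' decompose_tracts("CCCCCTTTCCCCCTTTCCCCCTTTCCCCC")  # loops 3,3,3
#' @export
decompose_tracts <- function(sequence, rule = motif_rule(), id = NULL) {
  rec <- as_sequence_record(sequence, id)
  chars <- seq_chars(rec$sequence)
  hit <- scan_chars(chars, rule, rec$id, "+")
  if (nrow(hit) >= 1) {
    starts <- hit$tract_starts[[1]]
    return(tibble(
      sequence_id = rec$id,
      tract_starts = list(starts),
      tract_ends = list(starts + rule$tract_len),
      loop_lengths = hit$loop_lengths[1],
      total_loop_length = hit$total_loop_length[[1]],
      fallback_used = FALSE
    ))
  }
  # Fallback: n_tracts longest maximal runs of the tract base.
  r <- rle(chars == rule$base)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  keep <- r$values
  lens <- r$lengths[keep]
  starts1 <- run_starts[keep]
  eligible <- lens >= 2L
  if (sum(eligible) < rule$n_tracts) {
    abort(paste0("undecomposable: sequence '", rec$id, "' has fewer than ",
                 rule$n_tracts, " runs of ", rule$base, " with length >= 2"))
  }
  lens <- lens[eligible]
  starts1 <- starts1[eligible]
  ord <- order(-lens, starts1)[seq_len(rule$n_tracts)]
  pick <- sort(ord)
  t_start1 <- starts1[pick]
  t_end1 <- starts1[pick] + lens[pick]  # 1-based exclusive
  loops <- t_start1[-1] - t_end1[-length(t_end1)]
  tibble(
    sequence_id = rec$id,
    tract_starts = list(t_start1 - 1L),
    tract_ends = list(t_end1 - 1L),
    loop_lengths = list(as.integer(loops)),
    total_loop_length = as.integer(sum(loops)),
    fallback_used = TRUE
  )
}
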
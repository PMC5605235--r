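#' Define a tract/loop folding rule
#'
#' The i-motif folding rule used for genome screens: `n_tracts` runs of at
#' least `tract_len` consecutive `base` nucleotides, separated by
#' `n_tracts - 1` loops of `loop_min` to `loop_max` arbitrary bases (the loop
#' may itself contain the tract base). The default
#' `motif_rule()` is the C5(N1-19 C5)3 rule: four tracts of five cytosines
#' with loops of 1-19 bases. Setting `base = "G"` gives the rule applied on
#' the opposite strand.
#'
#' @param base Tract base, `"C"` or `"G"`.
#' @param tract_len Minimum run length per tract (>= 1).
#' @param n_tracts Number of tracts (>= 2).
#' @param loop_min,loop_max Inclusive loop-length bounds, `1 <= loop_min <=
#'   loop_max`.
#' @return An object of class `motif_rule`.
#' @examples
#' motif_rule()                  # C5(N1-19C5)3
#' motif_rule(loop_max = 7)      # stricter loops
#' @export
motif_rule <- function(base = "C", tract_len = 5, n_tracts = 4,
                       loop_min = 1, loop_max = 19) {
  base <- match.arg(base, c("C", "G"))
  tract_len <- as.integer(tract_len)
  n_tracts <- as.integer(n_tracts)
  loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max)
  if (tract_len < 1) abort("`tract_len` must be >= 1")
  if (n_tracts < 2) abort("`n_tracts` must be >= 2")
  if (loop_min < 1) abort("`loop_min` must be >= 1")
  if (loop_max < loop_min) abort("`loop_max` must be >= `loop_min`")
  structure(
    list(base = base, tract_len = tract_len, n_tracts = n_tracts,
         loop_min = loop_min, loop_max = loop_max),
    class = "motif_rule"
  )
}

#' @export
print.motif_rule <- function(x, ...) {
  cat(sprintf("<motif_rule> %s%d(N%d-%d%s%d)%d\n",
              x$base, x$tract_len, x$loop_min, x$loop_max,
              x$base, x$tract_len, x$n_tracts - 1))
  invisible(x)
}

# Internal: the complementary-base version of a rule (for minus-strand scans).
complement_rule <- function(rule) {
  rule$base <- if (rule$base == "C") "G" else "C"
  rule
}

# Internal: minimal span of a rule match.
rule_min_span <- function(rule) {
  rule$n_tracts * rule$tract_len + (rule$n_tracts - 1) * rule$loop_min
}
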
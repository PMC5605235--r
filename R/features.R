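# Per-sequence structural features and their correlation with measured
# stability (transitional pH, melting temperature).

#' Build a feature table joining loop lengths with measured stability
#'
#' For each measured oligonucleotide, computes the total loop length from
#' the canonical tract/loop decomposition ([decompose_tracts()]; strict rule
#' where it matches, longest-runs fallback otherwise) and joins the measured
#' transitional pH and melting temperature by id. When two melting
#' temperatures are reported for a sequence (`tm1`/`tm2` columns), the
#' larger -- the final unfolding transition -- is used.
#'
#' @param sequences Tibble with columns `id`, `sequence` (e.g. from
#'   [read_fasta()] or [genomic_oligo_library()]).
#' @param measurements Tibble with column `id` plus any of `ph_t`, `tm`, or
#'   the pair `tm1`/`tm2`. Every measurement id must have a sequence.
#' @param rule A [motif_rule()].
#' @return Tibble with columns `sequence_id`, `total_loop_length`,
#'   `fallback_used`, and the available measurement columns (`ph_t`, `tm`).
#' @export
build_feature_table <- function(sequences, measurements, rule = motif_rule()) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)),
            "id" %in% names(measurements))
  missing <- setdiff(measurements$id, sequences$id)
  if (length(missing) > 0) {
    abort(paste0("no sequence for measurement id(s): ",
                 paste(missing, collapse = ", ")))
  }
  seqs <- sequences[match(measurements$id, sequences$id), ]
  dec <- map(seq_len(nrow(seqs)), function(i) {
    decompose_tracts(seqs$sequence[[i]], rule, id = seqs$id[[i]])
  }) |> bind_rows()
  out <- tibble(
    sequence_id = measurements$id,
    total_loop_length = dec$total_loop_length,
    fallback_used = dec$fallback_used
  )
  if ("ph_t" %in% names(measurements)) out$ph_t <- measurements$ph_t
  if (all(c("tm1", "tm2") %in% names(measurements))) {
    out$tm <- pmax(measurements$tm1, measurements$tm2, na.rm = TRUE)
    out$tm[is.na(measurements$tm1) & is.na(measurements$tm2)] <- NA_real_
  } else if ("tm" %in% names(measurements)) {
    out$tm <- measurements$tm
  }
  out
}

#' Pearson correlation with pairwise deletion of missing values
#'
#' Thin wrapper around the product-moment correlation that enforces the
#' contracts used throughout the feature analysis: pairs with a missing
#' value in either variable are dropped, at least 3 complete pairs are
#' required, and zero variance is an error rather than `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble with columns `r` and `n` (complete pairs used).
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: zero variance in x or y")
  }
  tibble(r = cor(x, y, method = "pearson"), n = length(x))
}
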
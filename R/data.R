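# Bundled characterization tables for the model and genomic i-motif
# oligonucleotide libraries (plain-text TSV under inst/extdata).

#' Model CnTx oligonucleotide library with melting and titration data
#'
#' A library of model i-motif oligonucleotides, four cytosine tracts of
#' `n` cytosines separated by three loops of `x` thymines (notation
#' `CnTx`), plus the human telomeric i-motif sequence `hTeloC`. For each
#' oligonucleotide the table carries melting temperature(s) and annealing
#' temperature from UV melts at 295 nm at pH 5.5 and pH 7.4, and the
#' transitional pH from CD titration. `NA` marks transitions that were not
#' detected.
#'
#' @return Tibble with columns `notation`, `bases`, `sequence`,
#'   `tm1_ph55`, `tm2_ph55`, `ta_ph55`, `tm1_ph74`, `tm2_ph74`, `ta_ph74`,
#'   `ph_t`. Temperatures in degC.
#' @examples
#' model_oligo_library()
#' @export
model_oligo_library <- function() {
  readr::read_tsv(
    system.file("extdata", "model_oligo_library.tsv", package = "imotifr",
                mustWork = TRUE),
    col_types = readr::cols(notation = readr::col_character(),
                            sequence = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
}

#' Genomic i-motif candidate oligonucleotides with stability data
#'
#' Thirty-three putative i-motif-forming sequences drawn from human gene
#' promoters and other genomic loci (23-116 nt), with UV melting
#' temperature(s) `tm1`/`tm2` and annealing temperature `ta` measured at
#' pH 7.0 and the transitional pH `ph_t` from CD titration. Together with
#' [build_feature_table()] and [pearson_cor()] this table reproduces the
#' loop-length/stability correlation analysis.
#'
#' @return Tibble with columns `notation`, `bases`, `sequence`, `tm1`,
#'   `tm2`, `ta`, `ph_t`. Temperatures in degC; `tm2` is `NA` for
#'   single-transition melts.
#' @examples
#' genomic_oligo_library()
#' @export
genomic_oligo_library <- function() {
  readr::read_tsv(
    system.file("extdata", "genomic_oligo_library.tsv", package = "imotifr",
                mustWork = TRUE),
    col_types = readr::cols(notation = readr::col_character(),
                            sequence = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
}
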
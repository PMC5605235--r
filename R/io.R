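#' Read a FASTA file into a sequence table
#'
#' Parses a (possibly gzip-compressed) multi-record FASTA file and returns
#' one row per record. Sequences are canonicalized to upper case; the
#' original text as read is kept in the `raw` column. Only the DNA alphabet
#' `A, C, G, T, N` (either case) is accepted -- anything else (including `U`)
#' is an error that names the record and the offending position, so malformed
#' input is rejected rather than silently coerced.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (text before the first whitespace of
#'   each header), `sequence` (upper-case), `raw` (original case) and `width`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "CCCCC", "TTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("could not parse FASTA file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("FASTA file is empty: ", path))
  raw <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  upper <- toupper(raw)
  for (i in seq_along(upper)) {
    if (nchar(upper[[i]]) == 0) {
      abort(paste0("record '", ids[[i]], "' has an empty sequence"))
    }
    bad <- regexpr("[^ACGTN]", upper[[i]])
    if (bad != -1L) {
      abort(paste0(
        "illegal character '", substr(raw[[i]], bad, bad), "' in record '",
        ids[[i]], "' at position ", bad,
        " (alphabet is A/C/G/T/N, either case)"
      ))
    }
  }
  tibble(id = ids, sequence = unname(upper), raw = unname(raw),
         width = nchar(unname(upper)))
}

#' Write genomic intervals as BED6
#'
#' Writes a six-column BED file (chrom, start, end, name, score, strand) with
#' 0-based half-open coordinates, the same convention used internally, so the
#' file round-trips losslessly through [read_bed()].
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand` (defaults `"."`, `0`, `"."`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  x <- as_tibble(intervals)
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort("negative start coordinate in BED output")
    if (any(x$end <= x$start)) abort("interval with end <= start in BED output")
    if (!all(x$strand %in% c("+", "-", "."))) {
      abort("strand must be one of '+', '-', '.'")
    }
  }
  readr::write_tsv(x[, c("chrom", "start", "end", "name", "score", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file with at least 6 columns.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open coordinates, as on disk).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), name = readr::col_character(),
      score = readr::col_double(), strand = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(x) > 0 && (any(x$start < 0) || any(x$end <= x$start))) {
    abort("invalid interval coordinates in BED file")
  }
  x
}

curve_required_cols <- list(
  melt = c("series_id", "temperature_C", "absorbance", "direction", "replicate"),
  cd_titration = c("series_id", "pH", "ellipticity_288"),
  spectrum = c("series_id", "wavelength_nm", "value")
)

#' Read a curve CSV (UV melt, CD titration, or spectrum)
#'
#' Strictly-typed CSV reader for the three tabular curve formats used by the
#' spectroscopic analyses. The required columns depend on `kind`:
#' \describe{
#'   \item{melt}{`series_id, temperature_C, absorbance, direction, replicate`;
#'     `direction` must be `melt` or `anneal`.}
#'   \item{cd_titration}{`series_id, pH, ellipticity_288`.}
#'   \item{spectrum}{`series_id, wavelength_nm, value`.}
#' }
#' Rows are sorted by series and x value; duplicated design points (same
#' series/direction/replicate/x) and non-numeric cells are errors naming the
#' offending column or row, not silent coercions.
#'
#' @param path Path to a comma-separated file with a header line.
#' @param kind One of `"melt"`, `"cd_titration"`, `"spectrum"`.
#' @return A typed, sorted tibble.
#' @export
read_curves <- function(path, kind = c("melt", "cd_titration", "spectrum")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("curve file not found: ", path))
  req <- curve_required_cols[[kind]]
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(req, hdr)
  if (length(missing) > 0) {
    abort(paste0("curve file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  types <- switch(kind,
    melt = readr::cols(
      series_id = readr::col_character(), temperature_C = readr::col_double(),
      absorbance = readr::col_double(), direction = readr::col_character(),
      replicate = readr::col_integer()
    ),
    cd_titration = readr::cols(
      series_id = readr::col_character(), pH = readr::col_double(),
      ellipticity_288 = readr::col_double()
    ),
    spectrum = readr::cols(
      series_id = readr::col_character(), wavelength_nm = readr::col_double(),
      value = readr::col_double()
    )
  )
  # parsing problems are re-raised below as located errors
  x <- suppressWarnings(readr::read_csv(path, col_types = types,
                                        progress = FALSE,
                                        show_col_types = FALSE))
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(paste0("non-numeric or malformed cell in ", path, " at data row ",
                 prob$row[[1]] - 1, " (expected ", prob$expected[[1]], ")"))
  }
  x <- x[, req]
  num_cols <- setdiff(req, c("series_id", "direction"))
  for (col in num_cols) {
    if (anyNA(x[[col]])) {
      abort(paste0("missing or non-numeric value in column '", col,
                   "' at data row ", which(is.na(x[[col]]))[[1]]))
    }
  }
  xcol <- switch(kind, melt = "temperature_C", cd_titration = "pH",
                 spectrum = "wavelength_nm")
  if (kind == "melt") {
    if (!all(x$direction %in% c("melt", "anneal"))) {
      bad <- which(!x$direction %in% c("melt", "anneal"))[[1]]
      abort(paste0("invalid direction '", x$direction[[bad]], "' at data row ",
                   bad, " (must be 'melt' or 'anneal')"))
    }
    key <- paste(x$series_id, x$direction, x$replicate, x[[xcol]])
    x <- arrange(x, .data$series_id, .data$direction, .data$replicate,
                 .data$temperature_C)
  } else {
    key <- paste(x$series_id, x[[xcol]])
    x <- arrange(x, .data$series_id, .data[[xcol]])
  }
  if (anyDuplicated(key)) {
    abort(paste0("duplicated measurement at data row ",
                 which(duplicated(key))[[1]],
                 " (same series/direction/replicate/x)"))
  }
  x
}

#' Read a transcription start site table
#'
#' Reads a tab-separated annotation with columns
#' `gene_id, chrom, tss_position_1based, strand` and converts the TSS to the
#' package-internal 0-based convention.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_tss <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss_position_1based = readr::col_double(), strand = readr::col_character()
  ), progress = FALSE)
  if (!all(x$strand %in% c("+", "-"))) abort("TSS strand must be '+' or '-'")
  if (any(x$tss_position_1based < 1)) abort("1-based TSS positions must be >= 1")
  tibble(gene_id = x$gene_id, chrom = x$chrom,
         tss = x$tss_position_1based - 1, strand = x$strand)
}

#' Read a gene-to-GO mapping table
#'
#' @param path Path to a TSV with columns `gene_id`, `go_id`.
#' @return Tibble with one row per (gene, term) assignment, de-duplicated.
#' @export
read_go_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), go_id = readr::col_character()
  ), progress = FALSE)
  distinct(x, .data$gene_id, .data$go_id)
}
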
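# Seeded generators with known ground truth for every pipeline stage:
# genomes with planted motifs, TSS/GO annotations, two-state van't Hoff
# melting curves, folded/unfolded absorbance spectrum pairs, CD spectra and
# ellipticity-vs-pH titrations. All generators are pure functions of their
# arguments including `seed`.

GAS_CONSTANT <- 8.314      # J/(mol K)
CELSIUS_ZERO <- 273.15

uniform_base_probs <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

#' Build one planted motif sequence from a loop specification
#'
#' Constructs a rule-conforming motif: tracts of exactly `rule$tract_len`
#' copies of the tract base joined by the requested loops, with loop bases
#' drawn from the non-tract alphabet so a plant can never extend its own
#' tracts. For `strand = "-"` the stored (forward) sequence carries the
#' complementary G-run pattern.
#'
#' @param loop_lengths Integer vector of length `rule$n_tracts - 1`, each in
#'   `[rule$loop_min, rule$loop_max]`.
#' @param strand `"+"` or `"-"`.
#' @param rule A [motif_rule()].
#' @return Character scalar (the forward-strand sequence to embed).
#' @keywords internal
planted_motif_sequence <- function(loop_lengths, strand = "+",
                                   rule = motif_rule()) {
  stopifnot(length(loop_lengths) == rule$n_tracts - 1,
            all(loop_lengths >= rule$loop_min),
            all(loop_lengths <= rule$loop_max))
  base <- if (strand == "+") rule$base else
    if (rule$base == "C") "G" else "C"
  loop_alphabet <- setdiff(c("A", "C", "G", "T"), base)
  tract <- strrep(base, rule$tract_len)
  loops <- map_chr(loop_lengths, function(l) {
    paste(sample(loop_alphabet, l, replace = TRUE), collapse = "")
  })
  paste0(tract, paste0(loops, tract, collapse = ""))
}

#' Simulate an i.i.d. genome with planted motif instances
#'
#' Generates an i.i.d. background sequence and embeds rule-conforming motif
#' instances at random non-overlapping positions separated by at least
#' `min_gap` bases. After planting, the genome is re-scanned and any
#' background stretch that creates a spurious rule match -- or merges with a
#' plant into a match with different coordinates -- is re-drawn, so the
#' returned truth table is exactly what [scan_sequences()] should recover.
#'
#' @param length Genome length in bases.
#' @param base_probs Background base probabilities (named A/C/G/T vector).
#' @param planted List of plant specifications; each element is a list with
#'   `loop_lengths` (integer vector of `n_tracts - 1` loop lengths) and
#'   `strand` (`"+"` or `"-"`).
#' @param rule A [motif_rule()] describing the plants and the scan used for
#'   sanitation.
#' @param min_gap Minimum separation between plants and from the sequence
#'   ends (>= 1).
#' @param seed Integer seed; the same arguments and seed give a
#'   byte-identical genome.
#' @param id Record identifier (default `"synthetic_genome"`).
#' @return List with `record` (one-row tibble: `id`, `sequence`) and `truth`
#'   (tibble `chrom`, `start`, `end`, `strand`, `sequence`, 0-based
#'   half-open, sorted by start).
#' @examples
#' g <- simulate_genome(10000, planted = list(
#'   list(loop_lengths = c(3, 3, 3), strand = "+")), seed = 7)
#' nrow(g$truth)
#' @export
simulate_genome <- function(length, base_probs = uniform_base_probs,
                            planted = list(), rule = motif_rule(),
                            min_gap = 10, seed, id = "synthetic_genome") {
  stopifnot(length >= 1, min_gap >= 1)
  if (abs(sum(base_probs) - 1) > 1e-9) abort("`base_probs` must sum to 1")
  withr::with_seed(seed, {
    k <- base::length(planted)
    plant_seqs <- map_chr(planted, function(p) {
      planted_motif_sequence(p$loop_lengths, p$strand %||% "+", rule)
    })
    widths <- nchar(plant_seqs)
    free <- length - sum(widths) - min_gap * (k + 1)
    if (k > 0 && free < 0) {
      abort("infeasible packing: planted motifs plus gaps exceed the genome length")
    }
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = base_probs[c("A", "C", "G", "T")])
    truth <- tibble(chrom = character(), start = integer(), end = integer(),
                    strand = character(), sequence = character())
    if (k > 0) {
      extra <- as.vector(rmultinom(1, free, rep(1, k + 1)))
      gaps <- min_gap + extra
      starts0 <- cumsum(c(gaps[1], head(widths, -1) + gaps[-1][seq_len(k - 1)]))
      if (k == 1) starts0 <- gaps[1]
      for (i in seq_len(k)) {
        idx <- (starts0[i] + 1):(starts0[i] + widths[i])
        chars[idx] <- seq_chars(plant_seqs[i])
      }
      truth <- tibble(
        chrom = id,
        start = as.integer(starts0),
        end = as.integer(starts0 + widths),
        strand = map_chr(planted, function(p) p$strand %||% "+"),
        sequence = plant_seqs
      )
    }
    in_plant <- logical(length)
    for (i in seq_len(k)) in_plant[(truth$start[i] + 1):truth$end[i]] <- TRUE
    # Sanitation: redraw background near any discrepancy between the scan
    # and the truth table until the scan recovers exactly the plants.
    can_sanitize <- any(!in_plant) && any(base_probs[c("A", "C", "G", "T")] > 0)
    for (iter in seq_len(50)) {
      rec <- tibble(id = id, sequence = paste(chars, collapse = ""))
      hits <- scan_sequences(rec, rule, strands = "both")
      hit_key <- paste(hits$start, hits$end, hits$strand)
      truth_key <- paste(truth$start, truth$end, truth$strand)
      spurious <- hits[!hit_key %in% truth_key, ]
      missing <- truth[!truth_key %in% hit_key, ]
      if (nrow(spurious) == 0 && nrow(missing) == 0) break
      if (!can_sanitize) {
        abort("cannot sanitize genome: no background bases available to redraw")
      }
      pad <- rule$tract_len
      bad <- unique(unlist(c(
        map2(spurious$start, spurious$end,
             function(s, e) max(1, s + 1 - pad):min(length, e + pad)),
        map2(missing$start, missing$end,
             function(s, e) max(1, s + 1 - pad):min(length, e + pad))
      )))
      bad <- bad[!in_plant[bad]]
      if (base::length(bad) == 0) {
        abort("cannot sanitize genome: conflicting plants overlap")
      }
      chars[bad] <- sample(c("A", "C", "G", "T"), base::length(bad),
                           replace = TRUE,
                           prob = base_probs[c("A", "C", "G", "T")])
      if (iter == 50) abort("genome sanitation did not converge")
    }
    list(record = tibble(id = id, sequence = paste(chars, collapse = "")),
         truth = arrange(truth, .data$start))
  })
}

#' Simulate a TSS annotation and GO map
#'
#' Places `n_genes` transcription start sites uniformly at random (without
#' collision) on a single synthetic chromosome, with strands drawn
#' Bernoulli(0.5), and assigns GO terms from a configurable pool.
#'
#' @param n_genes Number of genes (>= 1). Placing more than
#'   `genome_length / 2000` genes is an error (non-overlapping 1-kb
#'   promoters could not be guaranteed).
#' @param genome_length Chromosome length in bases.
#' @param seed Integer seed.
#' @param chrom Chromosome name (default `"chr1"`).
#' @param term_sizes Named integer vector: GO term id -> number of genes
#'   annotated with that term. Default: five terms covering 30/25/20/15/10%
#'   of the genes.
#' @return List with `tss` (tibble `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`), `go_map` (tibble `gene_id`, `go_id`) and `chrom_sizes`
#'   (named vector).
#' @export
simulate_annotation <- function(n_genes, genome_length, seed, chrom = "chr1",
                                term_sizes = NULL) {
  stopifnot(n_genes >= 1)
  if (n_genes > genome_length / 2000) {
    abort("too many genes: cannot place non-overlapping promoters")
  }
  if (is.null(term_sizes)) {
    term_sizes <- setNames(
      pmax(1L, as.integer(round(n_genes * c(0.30, 0.25, 0.20, 0.15, 0.10)))),
      sprintf("GO:%07d", 1:5)
    )
  }
  if (any(term_sizes > n_genes)) abort("a GO term cannot cover more genes than exist")
  withr::with_seed(seed, {
    gene_id <- sprintf("gene%04d", seq_len(n_genes))
    tss <- tibble(
      gene_id = gene_id,
      chrom = chrom,
      tss = sort(sample.int(genome_length, n_genes) - 1L),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    go_map <- imap(as.list(term_sizes), function(size, term) {
      tibble(gene_id = sample(gene_id, size), go_id = term)
    }) |> bind_rows()
    list(tss = tss, go_map = arrange(go_map, .data$go_id, .data$gene_id),
         chrom_sizes = setNames(genome_length, chrom))
  })
}

#' Two-state van't Hoff melting-curve component
#'
#' Parameters for one folded/unfolded equilibrium contributing to a
#' simulated UV melting curve at 295 nm. The folded fraction is
#' `theta(T) = 1 / (1 + exp((dH/R) (1/Tm_eff - 1/T)))` with temperatures in
#' kelvin, so `theta(Tm_eff) = 0.5` exactly; `dh` is the apparent van't Hoff
#' enthalpy of unfolding in kJ/mol (positive: folding is exothermic).
#' Baselines are linear in temperature; the folded state absorbs more at
#' 295 nm, so melting appears as a hypochromic drop.
#'
#' @param tm Transition midpoint, degC.
#' @param dh Apparent van't Hoff unfolding enthalpy, kJ/mol (default 350).
#' @param baseline_folded,baseline_unfolded Length-2 vectors
#'   `(intercept AU, slope AU/degC)`.
#' @param noise_sd Gaussian noise standard deviation, AU (default 0.002).
#' @param weight Mixture weight (weights of all components must sum to 1).
#' @return A list of class `two_state_params`.
#' @export
two_state_params <- function(tm, dh = 350,
                             baseline_folded = c(0.92, 3e-4),
                             baseline_unfolded = c(0.78, 2e-4),
                             noise_sd = 0.002, weight = 1) {
  stopifnot(noise_sd >= 0, length(baseline_folded) == 2,
            length(baseline_unfolded) == 2)
  structure(
    list(tm = tm, dh = dh, baseline_folded = baseline_folded,
         baseline_unfolded = baseline_unfolded, noise_sd = noise_sd,
         weight = weight),
    class = "two_state_params"
  )
}

#' Simulate a UV melting or annealing curve
#'
#' Sums one or more two-state van't Hoff components and adds Gaussian
#' noise. Hysteresis is mimicked phenomenologically: on the annealing
#' branch each component's effective midpoint is shifted down by
#' `anneal_offset` degC (association kinetics slower than dissociation).
#'
#' @param components A [two_state_params()] object or a list of them (their
#'   `weight`s must sum to 1).
#' @param t_grid Temperature grid in degC, within \[0, 100\], step <= 1.
#' @param direction `"melt"` or `"anneal"`.
#' @param anneal_offset Midpoint depression on the annealing branch, degC
#'   (>= 0).
#' @param seed Integer seed.
#' @param series_id Series identifier for the output table.
#' @return Curve tibble (`series_id`, `temperature_C`, `absorbance`,
#'   `direction`, `replicate = 1`), ready for [detect_transitions()] /
#'   [analyze_melt()].
#' @examples
#' cv <- simulate_melt_curve(two_state_params(tm = 50, noise_sd = 0),
#'                           seed = 0)
#' detect_transitions(cv)
#' @export
simulate_melt_curve <- function(components, t_grid = seq(2, 98, by = 1),
                                direction = c("melt", "anneal"),
                                anneal_offset = 0, seed = 0,
                                series_id = "sim") {
  direction <- match.arg(direction)
  if (anneal_offset < 0) abort("`anneal_offset` must be >= 0")
  if (inherits(components, "two_state_params")) components <- list(components)
  if (any(t_grid < 0 | t_grid > 100)) abort("`t_grid` must lie in [0, 100] degC")
  if (any(diff(sort(t_grid)) > 1 + 1e-9)) abort("`t_grid` step must be <= 1 degC")
  w <- map_dbl(components, "weight")
  if (abs(sum(w) - 1) > 1e-9) abort("component weights must sum to 1")
  t_grid <- sort(t_grid)
  tk <- t_grid + CELSIUS_ZERO
  withr::with_seed(seed, {
    absorbance <- numeric(length(t_grid))
    for (cmp in components) {
      tm_eff <- cmp$tm - if (direction == "anneal") anneal_offset else 0
      tm_k <- tm_eff + CELSIUS_ZERO
      theta <- 1 / (1 + exp((cmp$dh * 1000 / GAS_CONSTANT) * (1 / tm_k - 1 / tk)))
      bf <- cmp$baseline_folded[1] + cmp$baseline_folded[2] * t_grid
      bu <- cmp$baseline_unfolded[1] + cmp$baseline_unfolded[2] * t_grid
      absorbance <- absorbance + cmp$weight * (bf * theta + bu * (1 - theta))
    }
    noise_sd <- sum(w * map_dbl(components, "noise_sd"))
    if (noise_sd > 0) {
      absorbance <- absorbance + rnorm(length(t_grid), 0, noise_sd)
    }
    tibble(series_id = series_id, temperature_C = t_grid,
           absorbance = absorbance, direction = direction, replicate = 1L)
  })
}

# Internal: unit Gaussian band on a wavelength grid.
gaussian_band <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

#' Simulate folded/unfolded absorbance spectrum pairs
#'
#' Gaussian-band templates on a 1-nm grid over 220-320 nm. For
#' `kind = "i_motif"` the hot-minus-cold difference has its positive
#' extremum at 240 nm and its negative extremum at 295 nm (the i-motif TDS
#' signature); for `kind = "random_coil"` the difference is non-negative
#' over 280-320 nm with its main band at 275 nm. Small seeded Gaussian
#' noise is added to each spectrum independently.
#'
#' @param kind `"i_motif"` or `"random_coil"`.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation in AU (default 0.002).
#' @return List with `hot` and `cold` spectrum tibbles
#'   (`wavelength_nm`, `value`), for [compute_tds()].
#' @export
simulate_spectra <- function(kind = c("i_motif", "random_coil"), seed = 0,
                             noise_sd = 0.002) {
  kind <- match.arg(kind)
  wl <- 220:320
  cold_template <- 0.15 + 0.9 * gaussian_band(wl, 265, 22)
  diff_template <- switch(kind,
    i_motif = 0.28 * gaussian_band(wl, 240, 9) -
      0.20 * gaussian_band(wl, 295, 9),
    random_coil = 0.30 * gaussian_band(wl, 275, 11) +
      0.08 * gaussian_band(wl, 240, 9)
  )
  withr::with_seed(seed, {
    cold <- cold_template + rnorm(length(wl), 0, noise_sd)
    hot <- cold_template + diff_template + rnorm(length(wl), 0, noise_sd)
    list(hot = tibble(wavelength_nm = wl, value = hot),
         cold = tibble(wavelength_nm = wl, value = cold))
  })
}

#' Simulate a CD spectrum of a folded or unfolded i-motif
#'
#' Gaussian-band templates over 200-320 nm (0.5-nm grid): the folded
#' i-motif shows +288/-260 nm bands, the unfolded form +273/-250 nm.
#'
#' @param kind `"folded"` or `"unfolded"`.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation in mdeg (default 0.05).
#' @return Spectrum tibble (`wavelength_nm`, `value` in mdeg) for
#'   [classify_cd_spectrum()].
#' @export
simulate_cd_spectrum <- function(kind = c("folded", "unfolded"), seed = 0,
                                 noise_sd = 0.05) {
  kind <- match.arg(kind)
  wl <- seq(200, 320, by = 0.5)
  template <- switch(kind,
    folded = 8 * gaussian_band(wl, 288, 9) - 4 * gaussian_band(wl, 260, 8) +
      2 * gaussian_band(wl, 220, 8),
    unfolded = 5 * gaussian_band(wl, 273, 9) - 3 * gaussian_band(wl, 250, 8) +
      2 * gaussian_band(wl, 218, 8)
  )
  withr::with_seed(seed, {
    tibble(wavelength_nm = wl,
           value = template + rnorm(length(wl), 0, noise_sd))
  })
}

#' Simulate an ellipticity-vs-pH titration
#'
#' Evaluates the four-parameter logistic titration model (the model fitted
#' by [fit_titration()]) on a pH grid and adds Gaussian noise. With
#' `noise_sd = 0` the ellipticity at `ph = ph_t` is exactly
#' `(e_folded + e_unfolded) / 2`.
#'
#' @param ph_t Transitional pH (inflection).
#' @param slope Steepness (dimensionless, positive).
#' @param e_folded,e_unfolded Plateau ellipticities in mdeg (acid/alkaline).
#' @param ph_grid pH grid (default 4.0-8.0 in 0.5 steps); >= 4 points.
#' @param noise_sd Noise standard deviation in mdeg.
#' @param seed Integer seed.
#' @param series_id Series identifier.
#' @return Titration tibble (`series_id`, `ph`, `ellipticity_288`).
#' @export
simulate_titration <- function(ph_t = 7.2, slope = 2, e_folded = 8,
                               e_unfolded = -1, ph_grid = seq(4, 8, by = 0.5),
                               noise_sd = 0, seed = 0, series_id = "sim") {
  if (length(ph_grid) < 4) abort("`ph_grid` needs at least 4 points")
  withr::with_seed(seed, {
    y <- titration_model(ph_grid, e_folded, e_unfolded, slope, ph_t)
    if (noise_sd > 0) y <- y + rnorm(length(ph_grid), 0, noise_sd)
    tibble(series_id = series_id, ph = ph_grid, ellipticity_288 = y)
  })
}
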
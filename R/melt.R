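# UV melting-curve analysis at 295 nm: first-derivative Tm/Ta extraction,
# hysteresis, and thermal difference spectra.

# Internal: average replicate scans onto the common temperature grid.
average_replicates <- function(curve) {
  curve |>
    group_by(.data$temperature_C) |>
    summarise(absorbance = mean(.data$absorbance), .groups = "drop") |>
    arrange(.data$temperature_C)
}

# Internal: Savitzky-Golay smoothing (order 2, window 7) when the curve is
# long enough; shorter curves are left untouched.
smooth_absorbance <- function(y, window = 7, order = 2) {
  if (length(y) < window) return(y)
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

# Internal: local maxima of a numeric vector (interior points only).
local_maxima <- function(m) {
  n <- length(m)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[m[i] > m[i - 1] & m[i] >= m[i + 1] & m[i] > 0]
}

# Internal: parabolic refinement of a grid peak position.
refine_peak <- function(x, m, i) {
  if (i <= 1 || i >= length(m)) return(x[i])
  denom <- m[i - 1] - 2 * m[i] + m[i + 1]
  if (denom >= 0) return(x[i])  # not concave; keep grid point
  delta <- 0.5 * (m[i - 1] - m[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  # assume locally uniform spacing
  x[i] + delta * mean(diff(x[max(1, i - 1):min(length(x), i + 1)]))
}

#' Detect melting/annealing transitions by the first-derivative method
#'
#' Averages replicate scans, applies mild Savitzky-Golay smoothing
#' (window 7, order 2), differentiates the absorbance with respect to
#' temperature on the measurement grid, and reports the temperatures of up
#' to `max_transitions` extrema of `|dA/dT|`. Because an i-motif melt read
#' at 295 nm is a hypochromic drop, the magnitude of the derivative is used,
#' so the same code serves melting and annealing curves. Candidate extrema
#' whose magnitude is below `prominence` times the largest extremum are
#' discarded; the surviving peaks are refined by parabolic interpolation and
#' reported in ascending temperature order.
#'
#' @param curve Tibble with columns `temperature_C` and `absorbance`
#'   (optionally `series_id`, `direction`, `replicate`; replicates are
#'   averaged). At least 10 points spanning at least 20 degC.
#' @param max_transitions Maximum number of transitions to report
#'   (default 2).
#' @param prominence Acceptance threshold relative to the largest derivative
#'   extremum (default 0.25).
#' @param min_separation Minimum temperature separation between reported
#'   transitions in degC (default 4); closer derivative maxima are treated
#'   as one transition and only the largest is kept.
#' @return Tibble with one row per transition: `series_id`, `direction`,
#'   `temperature` (degC), `magnitude` (`|dA/dT|` at the peak), ascending in
#'   temperature. A curve with no acceptable extremum (e.g. constant
#'   absorbance) yields zero rows with a warning.
#' @export
detect_transitions <- function(curve, max_transitions = 2,
                               prominence = 0.25, min_separation = 4) {
  stopifnot(is.data.frame(curve),
            all(c("temperature_C", "absorbance") %in% names(curve)))
  series_id <- if ("series_id" %in% names(curve)) curve$series_id[[1]] else "curve"
  direction <- if ("direction" %in% names(curve)) curve$direction[[1]] else "melt"
  avg <- average_replicates(curve)
  if (nrow(avg) < 10) abort("melting curve needs at least 10 distinct temperatures")
  x <- avg$temperature_C
  if (diff(range(x)) < 20) abort("melting curve must span at least 20 degC")
  y <- smooth_absorbance(avg$absorbance)
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  m <- abs(d)
  # Floor against numerically flat curves: a derivative this small carries
  # no transition signal at instrument scale.
  floor_eps <- 1e-9 * max(1, diff(range(avg$absorbance)))
  peaks <- local_maxima(m)
  peaks <- peaks[m[peaks] >= prominence * max(m) & m[peaks] > floor_eps]
  if (length(peaks) == 0) {
    warn(paste0("no transition detected in series '", series_id, "'"))
    return(tibble(series_id = character(), direction = character(),
                  temperature = numeric(), magnitude = numeric()))
  }
  # Distinct transitions must be separated by more than the derivative-peak
  # resolution limit; closer local maxima are noise ripples on one
  # transition, so only the largest is kept.
  peaks <- peaks[order(-m[peaks])]
  kept <- integer(0)
  for (p in peaks) {
    if (all(abs(x[p] - x[kept]) >= min_separation)) kept <- c(kept, p)
  }
  keep <- kept[seq_len(min(max_transitions, length(kept)))]
  tibble(
    series_id = series_id,
    direction = direction,
    temperature = map_dbl(keep, ~ refine_peak(x, m, .x)),
    magnitude = m[keep]
  ) |> arrange(.data$temperature)
}

#' Hysteresis between melting and annealing temperatures
#'
#' @param tm Melting temperature(s), degC.
#' @param ta Annealing temperature(s), degC.
#' @return `tm - ta` (vectorized). Non-zero hysteresis indicates that
#'   association kinetics are slower than dissociation.
#' @examples
#' hysteresis(29.3, 5.3)  # 24.0
#' @export
hysteresis <- function(tm, ta) {
  if (any(!is.finite(tm)) || any(!is.finite(ta))) {
    abort("`tm` and `ta` must be finite")
  }
  tm - ta
}

#' Analyze a table of melt/anneal curves
#'
#' Runs [detect_transitions()] on the melting and annealing branches of each
#' series and summarises them in the conventional table layout: up to two
#' melting temperatures ascending (`tm1`, `tm2`), the primary annealing
#' temperature `ta`, and the hysteresis computed between the
#' largest-amplitude melt transition and the largest-amplitude anneal
#' transition.
#'
#' @param curves Curve table with columns `series_id`, `temperature_C`,
#'   `absorbance`, `direction` (`melt`/`anneal`), `replicate` (see
#'   [read_curves()] and [simulate_melt_curve()]).
#' @param max_transitions Per-branch transition cap (default 2).
#' @return Tibble with one row per series: `series_id`, `tm1`, `tm2`, `ta`,
#'   `hysteresis`, `n_transitions` (number of melt transitions).
#' @export
analyze_melt <- function(curves, max_transitions = 2) {
  stopifnot(all(c("series_id", "temperature_C", "absorbance", "direction")
                %in% names(curves)))
  out <- map(split(curves, curves$series_id), function(cv) {
    res <- list(melt = NULL, anneal = NULL)
    for (dir in intersect(c("melt", "anneal"), unique(cv$direction))) {
      branch <- cv[cv$direction == dir, ]
      res[[dir]] <- detect_transitions(branch, max_transitions)
    }
    tm <- res$melt
    ta <- res$anneal
    tm_primary <- if (!is.null(tm) && nrow(tm) > 0) {
      tm$temperature[[which.max(tm$magnitude)]]
    } else NA_real_
    ta_primary <- if (!is.null(ta) && nrow(ta) > 0) {
      ta$temperature[[which.max(ta$magnitude)]]
    } else NA_real_
    tibble(
      series_id = cv$series_id[[1]],
      tm1 = if (!is.null(tm) && nrow(tm) >= 1) tm$temperature[[1]] else NA_real_,
      tm2 = if (!is.null(tm) && nrow(tm) >= 2) tm$temperature[[2]] else NA_real_,
      ta = ta_primary,
      hysteresis = tm_primary - ta_primary,
      n_transitions = if (is.null(tm)) 0L else nrow(tm)
    )
  })
  bind_rows(out)
}

#' Compute a thermal difference spectrum (TDS)
#'
#' Subtracts the folded-state absorbance spectrum (low temperature, e.g.
#' 4 degC) from the unfolded-state spectrum (high temperature, e.g. 95 degC)
#' over 220-320 nm and normalizes so the maximum change in absorption is
#' exactly +1. The shape of the difference is a fingerprint of the folded
#' structure; an i-motif shows a positive band at 240 nm and a negative band
#' at 295 nm.
#'
#' @param spectrum_hot,spectrum_cold Tibbles with columns `wavelength_nm`
#'   and `value` on an identical grid covering \[220, 320\] nm.
#' @return Tibble of class `imotif_tds` with columns `wavelength_nm` and
#'   `delta_abs` (max exactly +1), restricted to 220-320 nm.
#' @export
compute_tds <- function(spectrum_hot, spectrum_cold) {
  stopifnot(all(c("wavelength_nm", "value") %in% names(spectrum_hot)),
            all(c("wavelength_nm", "value") %in% names(spectrum_cold)))
  hot <- arrange(as_tibble(spectrum_hot), .data$wavelength_nm)
  cold <- arrange(as_tibble(spectrum_cold), .data$wavelength_nm)
  if (nrow(hot) != nrow(cold) ||
      any(hot$wavelength_nm != cold$wavelength_nm)) {
    abort("hot and cold spectra must share the same wavelength grid")
  }
  if (min(hot$wavelength_nm) > 220 || max(hot$wavelength_nm) < 320) {
    abort("spectra must cover the 220-320 nm range")
  }
  inside <- hot$wavelength_nm >= 220 & hot$wavelength_nm <= 320
  wl <- hot$wavelength_nm[inside]
  delta <- hot$value[inside] - cold$value[inside]
  mx <- max(delta)
  if (mx <= 0 || abs(mx) < .Machine$double.eps * 100) {
    abort("no positive difference to normalize")
  }
  out <- tibble(wavelength_nm = wl, delta_abs = delta / mx)
  class(out) <- c("imotif_tds", class(out))
  out
}

#' Classify a thermal difference spectrum
#'
#' A normalized TDS is called `i_motif` when its global positive extremum
#' lies at 240 +/- 10 nm and a negative extremum of depth at least 0.2 lies
#' at 295 +/- 10 nm; `random_coil` when nothing dips below -0.2 anywhere in
#' 280-320 nm and the positive extremum sits in the unfolded-strand band at
#' 275 +/- 10 nm; anything else is `other`.
#'
#' @param tds A normalized TDS from [compute_tds()].
#' @param pos_window,neg_window Half-widths (nm) of the acceptance windows
#'   around 240 and 295 nm (default 10).
#' @param depth Minimum depth of the 295 nm trough (default 0.2).
#' @return One of `"i_motif"`, `"random_coil"`, `"other"`.
#' @export
classify_tds <- function(tds, pos_window = 10, neg_window = 10, depth = 0.2) {
  stopifnot(all(c("wavelength_nm", "delta_abs") %in% names(tds)))
  wl <- tds$wavelength_nm
  d <- tds$delta_abs
  pos_peak <- wl[which.max(d)]
  in_neg <- wl >= 295 - neg_window & wl <= 295 + neg_window
  has_imotif_trough <- any(in_neg) && min(d[in_neg]) <= -depth
  if (abs(pos_peak - 240) <= pos_window && has_imotif_trough) {
    return("i_motif")
  }
  in_long <- wl >= 280 & wl <= 320
  no_trough <- !any(d[in_long] <= -depth)
  if (no_trough && abs(pos_peak - 275) <= pos_window) {
    return("random_coil")
  }
  "other"
}
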
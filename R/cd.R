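# CD pH-titration analysis: sigmoidal fit of ellipticity at 288 nm versus
# pH, transitional pH (pHT) at the inflection, folded fraction, and
# classification of full CD spectra as folded i-motif vs unfolded.

# The titration model. With slope > 0 the low-pH plateau is e_folded
# (i-motif is favoured in acid) and the inflection is at ph = ph_t, where
# the sequence is 50% folded. Base-10 kernel, Henderson-Hasselbalch-like.
titration_model <- function(ph, e_folded, e_unfolded, slope, ph_t) {
  e_unfolded + (e_folded - e_unfolded) / (1 + 10^(slope * (ph - ph_t)))
}

#' Fit a CD pH titration and estimate the transitional pH
#'
#' Least-squares fit of the four-parameter logistic
#' `E(pH) = e_u + (e_f - e_u) / (1 + 10^(slope * (pH - pHT)))`
#' to ellipticity at 288 nm versus pH. The transitional pH `ph_t` is the
#' inflection point of the fitted curve, the pH at which the sequence is 50%
#' folded. Initialization: plateaus from the data means at the two extreme
#' pH values, `ph_t` from the pH whose ellipticity is nearest the midpoint,
#' and a multistart over slopes 1, 2 and 4; the fit with the lowest RMSE
#' wins, ties going to the smallest starting slope.
#'
#' @param series Tibble with columns `ph` and `ellipticity_288` (mdeg);
#'   `pH`/`series_id` column names from [read_curves()] are also accepted.
#'   At least 4 distinct pH points, and the ellipticity must actually vary
#'   (a flat series is an error, not a fit).
#' @return An object of class `titration_fit` with elements `ph_t`, `slope`,
#'   `e_folded`, `e_unfolded`, `rmse`, `n`, `series_id` and `data`. Methods:
#'   [tidy()], [glance()], [predict()], [autoplot()], [folded_fraction()].
#' @examples
#' s <- simulate_titration(ph_t = 7.2, noise_sd = 0, seed = 1)
#' fit <- fit_titration(s)
#' fit$ph_t
#' @export
fit_titration <- function(series) {
  stopifnot(is.data.frame(series))
  if ("pH" %in% names(series) && !"ph" %in% names(series)) {
    series <- rename(series, ph = "pH")
  }
  stopifnot(all(c("ph", "ellipticity_288") %in% names(series)))
  series_id <- if ("series_id" %in% names(series)) series$series_id[[1]] else "series"
  dat <- arrange(tibble(ph = series$ph, y = series$ellipticity_288), .data$ph)
  if (length(unique(dat$ph)) < 4) {
    abort("titration needs at least 4 distinct pH points")
  }
  if (any(dat$ph < 0 | dat$ph > 14)) abort("pH values must lie in [0, 14]")
  # Flat-series guard: the total excursion must stand clear of the
  # point-to-point scatter (a robust noise estimate from successive
  # differences), otherwise there is no transition to fit.
  spread <- diff(range(dat$y))
  noise <- mad(diff(dat$y)) / sqrt(2)
  if (spread < 1e-8 || spread < 3 * noise) {
    abort("no transition: ellipticity does not vary enough across the pH range")
  }
  lo <- mean(dat$y[dat$ph <= sort(dat$ph)[2]])
  hi <- mean(dat$y[dat$ph >= sort(dat$ph, decreasing = TRUE)[2]])
  mid <- (lo + hi) / 2
  ph_t0 <- dat$ph[[which.min(abs(dat$y - mid))]]
  ph_range <- range(dat$ph)
  best <- NULL
  for (s0 in c(1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ titration_model(ph, e_folded, e_unfolded, slope, ph_t),
        data = dat,
        start = list(e_folded = lo, e_unfolded = hi, slope = s0, ph_t = ph_t0),
        lower = c(-Inf, -Inf, 0.05, ph_range[1] - 1),
        upper = c(Inf, Inf, 100, ph_range[2] + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rmse <- sqrt(mean(residuals(fit)^2))
    if (is.null(best) || rmse < best$rmse - 1e-12) {
      best <- list(fit = fit, rmse = rmse)
    }
  }
  if (is.null(best)) abort("titration fit failed to converge from all starts")
  cf <- coef(best$fit)
  structure(
    list(ph_t = unname(cf["ph_t"]), slope = unname(cf["slope"]),
         e_folded = unname(cf["e_folded"]), e_unfolded = unname(cf["e_unfolded"]),
         rmse = best$rmse, n = nrow(dat), series_id = series_id, data = dat),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf(
    "<titration_fit> %s: pHT = %.2f, slope = %.2f, plateaus %.2f -> %.2f mdeg, RMSE %.3g (n = %d)\n",
    x$series_id, x$ph_t, x$slope, x$e_folded, x$e_unfolded, x$rmse, x$n))
  invisible(x)
}

#' @method tidy titration_fit
#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(term = c("ph_t", "slope", "e_folded", "e_unfolded"),
         estimate = c(x$ph_t, x$slope, x$e_folded, x$e_unfolded))
}

#' @method glance titration_fit
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(series_id = x$series_id, ph_t = x$ph_t, slope = x$slope,
         e_folded = x$e_folded, e_unfolded = x$e_unfolded,
         rmse = x$rmse, n = x$n)
}

#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$ph else newdata$ph
  titration_model(ph, object$e_folded, object$e_unfolded,
                  object$slope, object$ph_t)
}

#' Folded fraction at a given pH
#'
#' `theta(pH) = 1 / (1 + 10^(slope * (pH - pHT)))`: exactly 0.5 at the
#' transitional pH, approaching 1 in acid and 0 in alkali for positive
#' slope.
#'
#' @param fit A [fit_titration()] result.
#' @param ph pH value(s).
#' @return Folded fraction(s) in `[0, 1]`.
#' @export
folded_fraction <- function(fit, ph) {
  stopifnot(inherits(fit, "titration_fit"))
  1 / (1 + 10^(fit$slope * (ph - fit$ph_t)))
}

#' Classify a CD spectrum as folded i-motif or unfolded
#'
#' A folded i-motif CD spectrum has its positive global maximum at
#' 288 +/- 6 nm with a negative trough at 260 +/- 6 nm; the unfolded form
#' shifts these to 273 +/- 6 and 250 +/- 6 nm. The +/- 6 nm windows keep the
#' two positive bands (15 nm apart) disjoint. Anything matching neither
#' template is `other`.
#'
#' @param spectrum Tibble with columns `wavelength_nm` and `value`
#'   (ellipticity, mdeg) covering at least 240-320 nm.
#' @param window Half-width of the acceptance windows in nm (default 6).
#' @return One of `"folded_i_motif"`, `"unfolded"`, `"other"`.
#' @export
classify_cd_spectrum <- function(spectrum, window = 6) {
  stopifnot(all(c("wavelength_nm", "value") %in% names(spectrum)))
  wl <- spectrum$wavelength_nm
  v <- spectrum$value
  if (min(wl) > 240 || max(wl) < 320) {
    abort("CD spectrum must cover the 240-320 nm range")
  }
  pos_peak <- wl[which.max(v)]
  if (max(v) <= 0) return("other")
  trough_in <- function(center) {
    inw <- wl >= center - window & wl <= center + window
    any(inw) && min(v[inw]) < 0
  }
  if (abs(pos_peak - 288) <= window && trough_in(260)) return("folded_i_motif")
  if (abs(pos_peak - 273) <= window && trough_in(250)) return("unfolded")
  "other"
}
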
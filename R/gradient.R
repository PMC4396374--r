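# Quantification of spatial morphogen intensity profiles.

#' Construct a gradient profile
#'
#' A single section's fluorescence intensity profile along the dorsoventral
#' axis, measured from the ventral midline on a regular (typically 1 um)
#' grid, with its mesoderm background level and the section's total DV neural
#' tube length.
#'
#' @param positions positions (um from the ventral midline), strictly
#'   increasing.
#' @param intensity fluorescence intensities (arbitrary units).
#' @param dv_length total DV neural tube length (um); must cover the
#'   positions.
#' @param background scalar background intensity (a.u.).
#' @param channel channel label (e.g. "Shh", "GFP", "Ptch1").
#' @param embryo_id,section_id identifiers.
#' @return An object of class `gradient_profile`.
#' @export
gradient_profile <- function(positions, intensity, dv_length,
                             background = 0, channel = "Shh",
                             embryo_id = NA, section_id = NA) {
  stopifnot(length(positions) == length(intensity))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (dv_length < max(positions)) stop("dv_length must cover all positions")
  if (background < 0) stop("background must be nonnegative")
  structure(list(positions = as.numeric(positions),
                 intensity = as.numeric(intensity),
                 dv_length = dv_length, background = background,
                 channel = channel, embryo_id = embryo_id,
                 section_id = section_id),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("%s intensity profile: %d positions over [%g, %g] um (DV length %g um)\n",
              x$channel, length(x$positions), min(x$positions),
              max(x$positions), x$dv_length))
  invisible(x)
}

#' Subtract the mesoderm background from a profile
#'
#' Subtracts the profile's scalar background measurement from every
#' intensity, clamping at zero, and zeroes the stored background.
#'
#' @param profile a `gradient_profile`.
#' @return The background-corrected `gradient_profile`.
#' @export
subtract_background <- function(profile) {
  stopifnot(inherits(profile, "gradient_profile"))
  profile$intensity <- pmax(profile$intensity - profile$background, 0)
  profile$background <- 0
  profile
}

#' Stage sections by dorsoventral length
#'
#' DV neural tube length grows linearly with somite stage, so sections can be
#' staged objectively from their measured DV length. `stage_calibration`
#' fits the linear somite-stage ~ DV-length map from calibration pairs;
#' `stage_by_dv_length` applies it (and its inverse via
#' `dv_length_by_stage`). Predictions outside the calibrated length range
#' carry an `extrapolated` attribute.
#'
#' @param dv_lengths calibration DV lengths (um).
#' @param stages matching somite stages.
#' @return `stage_calibration` returns an object of class
#'   `stage_calibration`.
#' @export
stage_calibration <- function(dv_lengths, stages) {
  stopifnot(length(dv_lengths) == length(stages), length(stages) >= 2)
  fit <- stats::lm(stages ~ dv_lengths)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-10)
    stop("degenerate staging calibration: zero slope")
  structure(list(fit = fit, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 range = range(dv_lengths)),
            class = "stage_calibration")
}

#' @rdname stage_calibration
#' @param dv_length DV length(s) to stage (um).
#' @param calibration a `stage_calibration`.
#' @export
stage_by_dv_length <- function(dv_length, calibration) {
  stopifnot(inherits(calibration, "stage_calibration"))
  est <- calibration$intercept + calibration$slope * dv_length
  extra <- dv_length < calibration$range[1] | dv_length > calibration$range[2]
  if (any(extra))
    warning("staging outside the calibrated DV-length range (extrapolation)")
  attr(est, "extrapolated") <- extra
  est
}

#' @rdname stage_calibration
#' @param stage somite stage(s) to invert to DV length.
#' @export
dv_length_by_stage <- function(stage, calibration) {
  stopifnot(inherits(calibration, "stage_calibration"))
  (stage - calibration$intercept) / calibration$slope
}

#' Bin profiles by developmental stage and relative DV position
#'
#' Bins background-corrected profiles into stage bins of `stage_bin_width`
#' um of total DV length and relative-position bins of `position_bin_frac`
#' of DV length, and reports the per-bin mean intensity with its Student-t
#' 95% confidence interval (undefined for single-section bins).
#'
#' Each section contributes its mean intensity within a position bin; bin
#' statistics are computed across sections.
#'
#' @param profiles list of `gradient_profile`s.
#' @param stage_bin_width stage bin width (um of DV length).
#' @param position_bin_frac position bin width as a fraction of DV length.
#' @param conf confidence level.
#' @return Data frame with columns `stage_bin`, `stage_mid`, `position_bin`,
#'   `position_mid`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
bin_profiles <- function(profiles, stage_bin_width = 40,
                         position_bin_frac = 0.1, conf = 0.95) {
  if (!length(profiles)) stop("no profiles to bin")
  per_section <- do.call(rbind, lapply(profiles, function(p) {
    rel <- p$positions / p$dv_length
    pb <- pmin(floor(rel / position_bin_frac),
               round(1 / position_bin_frac) - 1)
    agg <- tapply(p$intensity, pb, mean)
    data.frame(stage_bin = floor(p$dv_length / stage_bin_width),
               position_bin = as.integer(names(agg)),
               value = as.numeric(agg))
  }))
  sp <- split(per_section$value,
              interaction(per_section$stage_bin, per_section$position_bin,
                          drop = TRUE))
  out <- do.call(rbind, lapply(names(sp), function(key) {
    v <- sp[[key]]
    parts <- as.numeric(strsplit(key, ".", fixed = TRUE)[[1]])
    n <- length(v)
    m <- mean(v)
    if (n > 1) {
      half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(v) / sqrt(n)
      ci <- c(m - half, m + half)
    } else ci <- c(NA_real_, NA_real_)
    data.frame(stage_bin = parts[1], position_bin = parts[2],
               n = n, mean = m, ci_lo = ci[1], ci_hi = ci[2])
  }))
  out$stage_mid <- (out$stage_bin + 0.5) * stage_bin_width
  out$position_mid <- (out$position_bin + 0.5) * position_bin_frac
  out[order(out$stage_bin, out$position_bin),
      c("stage_bin", "stage_mid", "position_bin", "position_mid",
        "n", "mean", "ci_lo", "ci_hi")]
}

#' Cubic-spline interpolation of a binned curve
#'
#' Interpolates bin means onto a fine regular grid (default 0.1 um) with a
#' cubic spline passing exactly through the knots; with fewer than 4 knots
#' it falls back to linear interpolation with a warning.
#'
#' @param x knot positions.
#' @param y knot values.
#' @param step output grid step.
#' @return Data frame with columns `x`, `y` on the fine grid.
#' @export
interp_spline <- function(x, y, step = 0.1) {
  stopifnot(length(x) == length(y))
  xout <- seq(min(x), max(x), by = step)
  if (length(x) < 4) {
    warning("fewer than 4 knots: using linear interpolation")
    yi <- stats::approx(x, y, xout = xout)$y
  } else {
    yi <- stats::spline(x, y, xout = xout, method = "fmm")$y
  }
  data.frame(x = xout, y = yi)
}

#' Locate the source-target boundary of a profile
#'
#' The boundary between the Shh-producing source and the responding target
#' tissue is defined as the position of maximum intensity; ties are broken
#' toward the ventral-most (smallest) position.
#'
#' @param positions positions (um).
#' @param intensity (smoothed) intensities.
#' @return Boundary position (um).
#' @export
locate_source_boundary <- function(positions, intensity) {
  stopifnot(length(positions) == length(intensity))
  if (all(intensity == 0)) stop("all-zero profile: no boundary")
  positions[which.max(intensity)]
}

#' Fit an exponential gradient
#'
#' Nonlinear least-squares fit of \eqn{C(x) = C_0 \exp(-x/\lambda)} to the
#' intensities dorsal to the source boundary, where `x` is distance from the
#' boundary. The fit is initialized from a log-linear regression of the
#' positive intensities (which already equals the exact solution for
#' noiseless data).
#'
#' @param profile a `gradient_profile` (background-corrected).
#' @param boundary source boundary position (um); located with
#'   [locate_source_boundary()] when missing.
#' @param dorsal_cutoff_frac dorsal end of the fit window as a fraction of
#'   DV length.
#' @return An object of class `exp_fit`: amplitude `C0` (a.u.), decay length
#'   `lambda` (um), `r_squared`, `boundary_position`, number of points `n`.
#' @examples
#' x <- 0:150
#' p <- gradient_profile(x, 100 * exp(-pmax(x - 8, 0) / 20), dv_length = 300)
#' fit_exponential(p, boundary = 8)
#' @export
fit_exponential <- function(profile, boundary = NULL,
                            dorsal_cutoff_frac = 0.5) {
  stopifnot(inherits(profile, "gradient_profile"))
  if (is.null(boundary)) {
    # locate the boundary on a 5-point moving average so single-point noise
    # spikes cannot masquerade as the source peak
    sm <- stats::filter(profile$intensity, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- profile$intensity[is.na(sm)]
    boundary <- locate_source_boundary(profile$positions, as.numeric(sm))
  }
  keep <- profile$positions >= boundary &
    profile$positions <= dorsal_cutoff_frac * profile$dv_length
  if (sum(keep & profile$intensity > 0) < 5)
    stop("need at least 5 positive points dorsal to the boundary")
  x <- profile$positions[keep] - boundary
  y <- profile$intensity[keep]
  # log-linear initialization uses the positive points only
  pos <- y > 0
  init <- stats::lm(log(y[pos]) ~ x[pos])
  start <- list(C0 = exp(unname(stats::coef(init)[1])),
                lambda = -1 / unname(stats::coef(init)[2]))
  if (!is.finite(start$lambda) || start$lambda <= 0)
    start$lambda <- max(x) / 3
  fit <- try(minpack.lm::nlsLM(y ~ C0 * exp(-x / lambda), start = start,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("exponential fit failed to converge: ",
         attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  if (cf[["lambda"]] <= 0) stop("rejected fit: nonpositive decay length")
  resid <- y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(C0 = unname(cf[["C0"]]), lambda = unname(cf[["lambda"]]),
                 r_squared = r2, boundary_position = boundary,
                 n = length(x), fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential gradient fit: C0 = %.4g a.u., lambda = %.4g um, R^2 = %.3f (boundary %.4g um, n = %d)\n",
    x$C0, x$lambda, x$r_squared, x$boundary_position, x$n))
  invisible(x)
}

#' Amplitude and decay-length trends against tissue size
#'
#' Ordinary least-squares regressions of the fitted gradient amplitudes and
#' decay lengths on DV neural tube length.
#'
#' @param fits list of `exp_fit`s.
#' @param dv_lengths matching DV lengths (um).
#' @return An object of class `gradient_trend`: data frame `table` with one
#'   row per response (`C0`, `lambda`) giving slope, intercept, R-squared and
#'   the slope p-value, plus the underlying `lm` fits.
#' @export
trend_vs_size <- function(fits, dv_lengths) {
  stopifnot(length(fits) == length(dv_lengths))
  if (length(fits) < 3) stop("need at least 3 fits for a trend")
  if (stats::var(dv_lengths) == 0) stop("constant regressor: dv_lengths")
  reg <- function(y) {
    fit <- stats::lm(y ~ dv_lengths)
    s <- summary(fit)
    list(fit = fit,
         row = data.frame(slope = unname(stats::coef(fit)[2]),
                          intercept = unname(stats::coef(fit)[1]),
                          r_squared = s$r.squared,
                          p_value = s$coefficients[2, 4]))
  }
  c0 <- reg(vapply(fits, `[[`, numeric(1), "C0"))
  la <- reg(vapply(fits, `[[`, numeric(1), "lambda"))
  tab <- rbind(C0 = c0$row, lambda = la$row)
  tab$response <- rownames(tab)
  structure(list(table = tab[, c("response", "slope", "intercept",
                                 "r_squared", "p_value")],
                 fits = list(C0 = c0$fit, lambda = la$fit)),
            class = "gradient_trend")
}

#' @export
print.gradient_trend <- function(x, ...) {
  cat("Gradient trends vs DV length:\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Stereotype ventral Shh time courses into linear fits
#'
#' Fits a least-squares line to the mean Shh intensity of the two ventral
#' position bands (0-10% and 10-20% of DV length) against embryo time, and
#' extrapolates each back to its zero-crossing. The two fits define the
#' normalized ramp inputs via [build_ramp_inputs()].
#'
#' @param timecourse data frame with columns `time_h`, `band` (factor/char,
#'   two levels, ventral first) and `intensity`.
#' @return List of two fits (one per band), each of class `stereo_fit` with
#'   `slope` (a.u./h), `intercept`, `t_zero` (h) and `band`.
#' @export
stereotype_timecourse <- function(timecourse) {
  stopifnot(all(c("time_h", "band", "intensity") %in% names(timecourse)))
  bands <- unique(as.character(timecourse$band))
  if (length(bands) != 2) stop("expected exactly two position bands")
  out <- lapply(bands, function(b) {
    d <- timecourse[timecourse$band == b, ]
    if (nrow(d) < 3) stop("need >= 3 stages per band")
    fit <- stats::lm(intensity ~ time_h, data = d)
    slope <- unname(stats::coef(fit)[2])
    if (slope <= 0)
      stop("band ", b, ": non-positive slope, no zero-crossing")
    intercept <- unname(stats::coef(fit)[1])
    structure(list(slope = slope, intercept = intercept,
                   t_zero = -intercept / slope, band = b, fit = fit),
              class = "stereo_fit")
  })
  names(out) <- bands
  out
}

#' @export
print.stereo_fit <- function(x, ...) {
  cat(sprintf("Stereotyped Shh time course (%s): slope %.4g a.u./h, zero-crossing %.4g h\n",
              x$band, x$slope, x$t_zero))
  invisible(x)
}
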
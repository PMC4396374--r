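# Shh input signals: ramps, pulses, constants.

#' Construct a Shh input signal
#'
#' Exogenous Shh time courses driving the pathway model. A `"ramp"` is zero
#' before `onset` and rises linearly with `slope` after it; a `"pulse"` equals
#' `level` on `[onset, onset + duration)` and zero outside; a `"constant"`
#' equals `level` everywhere. All signals are nonnegative.
#'
#' @param kind signal shape.
#' @param onset onset time (h).
#' @param slope ramp slope (conc/h); ramps only.
#' @param level amplitude (conc); pulse and constant only.
#' @param duration pulse duration (h).
#' @return An object of class `shh_signal`.
#' @examples
#' sig <- shh_signal("ramp", slope = 2 / 70)
#' signal_value(sig, c(0, 35, 70))
#' @export
shh_signal <- function(kind = c("constant", "ramp", "pulse"), onset = 0,
                       slope = NULL, level = NULL, duration = Inf) {
  kind <- match.arg(kind)
  if (kind == "ramp") {
    if (is.null(slope) || slope < 0) stop("ramp requires slope >= 0")
    level <- slope
  } else {
    if (is.null(level) || level < 0) stop(kind, " requires level >= 0")
  }
  if (kind == "pulse" && (!is.finite(duration) || duration <= 0))
    stop("pulse requires a finite positive duration")
  structure(list(kind = kind, onset = onset, level = level,
                 duration = duration),
            class = "shh_signal")
}

#' @rdname shh_signal
#' @param signal an `shh_signal`.
#' @param t time(s) in hours.
#' @return `signal_value` returns the signal evaluated at `t`.
#' @export
signal_value <- function(signal, t) {
  stopifnot(inherits(signal, "shh_signal"))
  switch(signal$kind,
    constant = rep(signal$level, length(t)),
    ramp = pmax(t - signal$onset, 0) * signal$level,
    pulse = ifelse(t >= signal$onset & t < signal$onset + signal$duration,
                   signal$level, 0)
  )
}

#' @export
print.shh_signal <- function(x, ...) {
  cat("Shh input signal: ", x$kind, sep = "")
  if (x$kind == "ramp")
    cat(sprintf(" (onset %g h, slope %g conc/h)\n", x$onset, x$level))
  else if (x$kind == "pulse")
    cat(sprintf(" (onset %g h, level %g, duration %g h)\n",
                x$onset, x$level, x$duration))
  else cat(sprintf(" (level %g)\n", x$level))
  invisible(x)
}

#' Build the two normalized Shh ramp inputs
#'
#' Converts two stereotyped linear Shh time-course fits (ventral 0-10% and
#' 10-20% DV bands) into the two ramp inputs used for parameter inference.
#' Each ramp starts at zero at the band's extrapolated zero-crossing, which is
#' taken as the start of the stimulation window, and is normalized so that
#' signal 1 reaches exactly 2.0 and signal 2 exactly 1.0 at the end of the
#' `t_stim`-hour window.
#'
#' @param fit1,fit2 linear fits for the two bands: any list with elements
#'   `slope` and `intercept` (e.g. a [stereotype_timecourse()] band fit).
#' @param t_stim stimulation window length (h).
#' @param max1,max2 normalized maxima of the two signals.
#' @return A list of two `shh_signal` ramps.
#' @examples
#' ramps <- build_ramp_inputs(list(slope = 3, intercept = -12),
#'                            list(slope = 1.5, intercept = -9))
#' signal_value(ramps[[1]], 70)  # 2
#' @export
build_ramp_inputs <- function(fit1, fit2, t_stim = 70, max1 = 2, max2 = 1) {
  mk <- function(fit, mx) {
    if (!is.numeric(fit$slope) || fit$slope <= 0)
      stop("stereotyped fit must have positive slope (no zero-crossing)")
    shh_signal("ramp", onset = 0, slope = mx / t_stim)
  }
  list(signal1 = mk(fit1, max1), signal2 = mk(fit2, max2))
}
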
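# Synthetic data generators: intensity-profile cohorts with recorded ground
# truth, and adapting reporter time courses.

#' Specification of a synthetic embryo cohort
#'
#' Defines the statistical structure of a synthetic cohort of Shh intensity
#' profiles: DV lengths spanning developmental stages, a linear stage-length
#' law, exponential gradients whose decay length is drawn around 19.6 +/- 4.2
#' um independent of size and whose amplitude grows linearly with DV length
#' (spanning more than 10-fold across the cohort, residual scatter tuned for
#' an amplitude-size correlation near R^2 = 0.8), a source peak offset 5-13
#' um from the ventral midline with a half-Gaussian ventral shoulder, and
#' additive plus multiplicative measurement noise over a background level.
#'
#' @param n_embryos number of profiles.
#' @param dv_range DV-length range (um) spanned uniformly by the cohort.
#' @param stage_slope,stage_intercept,stage_noise_sd linear DV-length =
#'   intercept + slope * somite-stage law and its scatter.
#' @param lambda_mean,lambda_sd decay-length distribution (um), truncated
#'   positive.
#' @param amp_slope,amp_intercept,amp_sd,amp_floor amplitude law
#'   `C0 = amp_slope * dv_length + amp_intercept + N(0, amp_sd)`, floored.
#' @param peak_range source-peak offset range (um from the ventral midline).
#' @param background_mean,background_sd background level (a.u.).
#' @param noise_add_frac additive noise sd as a fraction of the expected
#'   cohort-maximum amplitude.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_embryos = 30, dv_range = c(100, 300),
                        stage_slope = 8.75, stage_intercept = 50,
                        stage_noise_sd = 10,
                        lambda_mean = 19.6, lambda_sd = 4.2,
                        amp_slope = 1.4, amp_intercept = -110,
                        amp_sd = 40, amp_floor = 25,
                        peak_range = c(5, 13),
                        background_mean = 10, background_sd = 2,
                        noise_add_frac = 0.02, noise_cv = 0.05) {
  sds <- c(stage_noise_sd, lambda_sd, amp_sd, background_sd,
           noise_add_frac, noise_cv)
  if (any(sds < 0)) stop("all noise scales must be nonnegative")
  if (lambda_mean <= 0) stop("lambda_mean must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

# expected amplitude at the top of the DV range: the additive-noise scale
# reference (deterministic given the spec)
.cohort_max_amp <- function(spec) {
  max(spec$amp_slope * spec$dv_range[2] + spec$amp_intercept, spec$amp_floor)
}

.rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate one synthetic intensity profile
#'
#' Draws one embryo's gradient truth (amplitude, decay length, peak offset,
#' background) from the cohort spec and renders the noisy profile on a 1-um
#' grid: an exponential decay dorsal to the peak, a half-Gaussian shoulder
#' (width 4 um) ventral to it, plus background and noise. The ground truth
#' is attached as `attr(, "truth")`.
#'
#' @param spec a [cohort_spec()].
#' @param dv_length this embryo's DV length (um).
#' @param embryo_id identifier.
#' @return A `gradient_profile` with a `truth` attribute.
#' @export
generate_profile <- function(spec, dv_length, embryo_id = NA) {
  stopifnot(inherits(spec, "cohort_spec"))
  C0 <- max(spec$amp_slope * dv_length + spec$amp_intercept +
              stats::rnorm(1, 0, spec$amp_sd), spec$amp_floor)
  lambda <- .rtruncnorm_pos(1, spec$lambda_mean, spec$lambda_sd)
  x_peak <- stats::runif(1, spec$peak_range[1], spec$peak_range[2])
  background <- max(stats::rnorm(1, spec$background_mean,
                                 spec$background_sd), 0)
  x <- seq(0, floor(dv_length), by = 1)
  shoulder <- ifelse(x < x_peak, exp(-(x - x_peak)^2 / (2 * 4^2)), 1)
  signal <- C0 * exp(-pmax(x - x_peak, 0) / lambda) * shoulder
  add_sd <- spec$noise_add_frac * .cohort_max_amp(spec)
  intensity <- pmax(signal * (1 + stats::rnorm(length(x), 0, spec$noise_cv)) +
                      background + stats::rnorm(length(x), 0, add_sd), 0)
  prof <- gradient_profile(x, intensity, dv_length = dv_length,
                           background = background, channel = "Shh",
                           embryo_id = embryo_id, section_id = 1)
  attr(prof, "truth") <- data.frame(embryo_id = embryo_id,
                                    dv_length = dv_length, C0 = C0,
                                    lambda = lambda, x_peak = x_peak,
                                    background = background)
  prof
}

#' Generate a synthetic cohort of profiles
#'
#' Draws `n_embryos` DV lengths uniformly over the spec's range (so the
#' expected amplitude spans more than 10-fold) and renders one profile per
#' embryo, returning the profiles together with the full ground-truth table.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional RNG seed for a reproducible cohort.
#' @return List with `profiles` (list of `gradient_profile`) and `truth`
#'   (data frame, one row per profile).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_embryos < 3) stop("need at least 3 embryos")
  if (!is.null(seed)) set.seed(seed)
  dv <- stats::runif(spec$n_embryos, spec$dv_range[1], spec$dv_range[2])
  profiles <- lapply(seq_len(spec$n_embryos), function(i)
    generate_profile(spec, dv[i], embryo_id = i))
  truth <- do.call(rbind, lapply(profiles, attr, "truth"))
  list(profiles = profiles, truth = truth)
}

#' Generate an adapting reporter time course
#'
#' Smooth rise-peak-decay curve with prescribed landmarks, emulating the
#' pulse-like net Gli activity of the reporter: rises from `basal` to `peak`
#' at `peak_time`, relaxes to `adapted_level` by `settle_time`, and stays
#' there, with optional additive noise. On the noiseless curve the
#' adaptation ratio recovered by [compute_metrics()] is exactly
#' `peak / adapted_level` when `settle_time` is at or before the adapted
#' window.
#'
#' @param basal pre-stimulation level (> 0).
#' @param peak peak level (> adapted_level).
#' @param peak_time time of the peak (h).
#' @param adapted_level late plateau level (> 0).
#' @param noise_sd additive Gaussian noise sd.
#' @param times output grid (h).
#' @param settle_time time at which the plateau is reached (h).
#' @return Data frame with columns `time_h`, `value`.
#' @export
generate_adapting_timecourse <- function(basal, peak, peak_time,
                                         adapted_level, noise_sd = 0,
                                         times = seq(0, 70, by = 0.5),
                                         settle_time = 40) {
  if (!(peak > adapted_level && adapted_level > 0 && basal > 0))
    stop("landmarks must satisfy peak > adapted_level > 0 and basal > 0")
  if (peak <= basal) stop("peak must exceed basal")
  if (!(peak_time > 0 && peak_time < settle_time))
    stop("need 0 < peak_time < settle_time")
  v <- ifelse(times <= peak_time,
    basal + (peak - basal) * sin(pi / 2 * times / peak_time)^2,
    ifelse(times < settle_time,
      adapted_level + (peak - adapted_level) *
        cos(pi / 2 * (times - peak_time) / (settle_time - peak_time))^2,
      adapted_level))
  if (noise_sd > 0) v <- v + stats::rnorm(length(times), 0, noise_sd)
  data.frame(time_h = times, value = v)
}
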
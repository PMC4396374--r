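# Adaptation metrics and the integer distance-scoring ladder.

# mean of a piecewise-linear trajectory over [a, b] (trapezoid rule with
# interpolated endpoints)
.window_mean <- function(t, y, a, b) {
  keep <- t > a & t < b
  tt <- c(a, t[keep], b)
  yy <- c(stats::approx(t, y, xout = a)$y, y[keep],
          stats::approx(t, y, xout = b)$y)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2) / (b - a)
}

#' Induction, sensitivity and adaptation metrics of a readout
#'
#' Summarizes one readout's response to the two Shh signals: the maximum
#' level within the first `window_peak` hours of stimulation relative to the
#' pre-stimulation basal level (`induction1`, `induction2`), the ratio of the
#' two peaks (`sensitivity = max1/max2`), and the ratio of each peak to the
#' trapezoidal mean over the late `window_adapted` window (`adaptation1`,
#' `adaptation2`). Non-adapting trajectories are allowed (adaptation ratios
#' can fall at or below 1).
#'
#' @param times output time grid (h), covering the full adapted window.
#' @param values1,values2 readout trajectories under signals 1 and 2.
#' @param basal pre-stimulation steady-state level of the readout (floored at
#'   1e-12 to guard division).
#' @param window_peak peak-search window end (h).
#' @param window_adapted two-element adapted window (h).
#' @return An object of class `adaptation_metrics`.
#' @examples
#' t <- seq(0, 70, 0.5)
#' y <- ifelse(t <= 20, 1 + 59 * t / 20, ifelse(t < 40, 60 - 50 * (t - 20) / 20, 10))
#' m <- compute_metrics(t, y, y, basal = 1)
#' m$adaptation1  # 6
#' @export
compute_metrics <- function(times, values1, values2, basal,
                            window_peak = 40, window_adapted = c(40, 70)) {
  if (max(times) < window_adapted[2] || min(times) > 0)
    stop("trajectories must cover [0, ", window_adapted[2], "] h")
  stopifnot(length(values1) == length(times),
            length(values2) == length(times))
  basal <- max(basal, 1e-12)
  pk <- times <= window_peak
  max1 <- max(values1[pk])
  max2 <- max(values2[pk])
  adapted1 <- .window_mean(times, values1, window_adapted[1], window_adapted[2])
  adapted2 <- .window_mean(times, values2, window_adapted[1], window_adapted[2])
  structure(list(
    basal = basal, max1 = max1, max2 = max2,
    induction1 = max1 / basal, induction2 = max2 / basal,
    sensitivity = max1 / max(max2, 1e-12),
    adapted1 = adapted1, adapted2 = adapted2,
    adaptation1 = max1 / max(adapted1, 1e-12),
    adaptation2 = max2 / max(adapted2, 1e-12)
  ), class = "adaptation_metrics")
}

#' @export
print.adaptation_metrics <- function(x, ...) {
  cat(sprintf(
    "induction %.3g / %.3g, sensitivity %.3g, adaptation %.3g / %.3g (basal %.3g)\n",
    x$induction1, x$induction2, x$sensitivity, x$adaptation1, x$adaptation2,
    x$basal))
  invisible(x)
}

#' Incremental scoring ladder for a behavioural ratio
#'
#' Integer penalty measuring how far a ratio falls short of its required
#' minimum. For the adaptation requirement of 2.5 the ladder is: ratio < 1
#' scores 10, < 1.1 scores 5, < 1.5 scores 2, < 2.5 scores 1, and >= 2.5
#' scores 0 (exceeding the requirement never penalizes). For other
#' requirements R the breakpoints scale proportionally
#' (R * c(1, 1.1, 1.5) / 2.5) with the same penalties.
#'
#' @param ratio observed ratio (> 0); vectorized.
#' @param required required minimum ratio (> 0).
#' @return Integer penalty (0, 1, 2, 5 or 10).
#' @examples
#' score_ratio(c(0.9, 1.05, 1.3, 1.8, 3.0), 2.5)  # 10 5 2 1 0
#' @export
score_ratio <- function(ratio, required = 2.5) {
  if (any(ratio <= 0) || required <= 0)
    stop("ratio and required must be positive")
  br <- required * c(1, 1.1, 1.5) / 2.5
  ifelse(ratio >= required, 0L,
    ifelse(ratio < br[1], 10L,
      ifelse(ratio < br[2], 5L,
        ifelse(ratio < br[3], 2L, 1L))))
}

.default_requirements <- function() {
  list(induction1 = 50, induction2 = 30, sensitivity = 1.5,
       adaptation1 = 2.5, adaptation2 = 2.5)
}

#' Total ABC distance from adaptation metrics
#'
#' Sums the scoring-ladder penalties over the readouts a model variant is
#' held to. The gfp reporter is scored for every variant; ptch1 mRNA is
#' scored additionally for the `"full"` and `"ptch1_feedback"` variants (the
#' variants in which ptch1 transcription remains coupled to Gli). Each
#' transcriptional readout is scored on five criteria: induction under
#' signals 1 and 2 (required 50- and 30-fold), sensitivity (max1/max2 >= 1.5)
#' and adaptation under both signals (>= 2.5). An auxiliary GliA
#' respond-and-adapt requirement (induction and adaptation >= `gliA_required`
#' under both signals) completes the distance.
#'
#' @param gfp `adaptation_metrics` for gfp mRNA (always required).
#' @param ptc `adaptation_metrics` for ptch1 mRNA; required for the full and
#'   ptch1_feedback variants.
#' @param gliA `adaptation_metrics` for the GliA protein.
#' @param variant one of [model_variants()].
#' @param requirements named list of required ratios for transcriptional
#'   readouts.
#' @param gliA_required required GliA induction and adaptation ratio.
#' @return An object of class `distance_score`: list with the per-criterion
#'   `table` and integer `total` (0 iff every requirement is met).
#' @export
total_distance <- function(gfp, ptc = NULL, gliA, variant = "full",
                           requirements = .default_requirements(),
                           gliA_required = 2) {
  variant <- match.arg(variant, .variant_names)
  needs_ptc <- variant %in% c("full", "ptch1_feedback")
  if (is.null(gfp)) stop("gfp metrics are required for every variant")
  if (needs_ptc && is.null(ptc))
    stop("ptc metrics are required for the ", variant, " variant")
  if (is.null(gliA)) stop("GliA metrics are required (auxiliary criterion)")

  score_one <- function(m, req, readout) {
    ratios <- unlist(m[names(req)])
    data.frame(readout = readout, criterion = names(req),
               ratio = unname(ratios), required = unname(unlist(req)),
               penalty = mapply(score_ratio, unname(ratios),
                                unname(unlist(req))))
  }
  gliA_req <- list(induction1 = gliA_required, induction2 = gliA_required,
                   adaptation1 = gliA_required, adaptation2 = gliA_required)
  tab <- rbind(
    score_one(gfp, requirements, "gfp_mRNA"),
    if (needs_ptc) score_one(ptc, requirements, "ptc_mRNA"),
    score_one(gliA, gliA_req, "GliA")
  )
  rownames(tab) <- NULL
  structure(list(table = tab, total = as.integer(sum(tab$penalty))),
            class = "distance_score")
}

#' @export
print.distance_score <- function(x, ...) {
  cat("Adaptation distance score: total =", x$total, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
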
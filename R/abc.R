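# ABC-SMC inference of pathway parameters against the adaptation distance.

# Free (sampled) parameter names per variant. gfp promoter parameters are
# tied to the ptch1 promoter except K_Pol_gfp, which is sampled on its own.
.free_params <- function(variant) {
  base <- c("tr_ptc", "tr_gliFL", "tl_Ptc", "tl_GliFL",
            "deg_ptc", "deg_gliFL", "deg_Ptc",
            "conv_GliA", "conv_GliR", "act_Ptc", "k_ShhPtc", "Km_Ptch1",
            "K_Pol_ptc", "K_Pol_gli", "K_Pol_gfp", "K_Gli_ptc")
  x_set <- c("tr_x", "tl_X", "deg_x", "deg_X", "K_Pol_x", "K_Gli_x",
             "K_X_gli")
  deg_set <- c("deg_GliFL", "deg_GliA", "deg_GliR")
  switch(variant,
    full = c(base, deg_set, x_set),
    gli_stability = c(base, deg_set),
    ptch1_feedback = c(base, "deg_GliFL"),
    gli_transcription = c(base, "deg_GliFL", x_set)
  )
}

#' Log-uniform prior specification
#'
#' Builds the prior over the free parameters of a model variant: independent
#' uniform densities in log10 space, each spanning `span^2` (by default four
#' orders of magnitude) centred on the reference parameter value where one is
#' published, else on 1. Cooperativities and the polymerase concentration are
#' fixed (`c_GliA = 10`, `c_GliR = 0`, `c_X = 0`, `Pol = 1`), as are the
#' parameters a reduced variant removes or ties (see [apply_variant()]).
#'
#' @param variant one of [model_variants()].
#' @param span half-range factor: each free range is `[v/span, v*span]`.
#' @param ranges named list of `c(lo, hi)` overrides for individual
#'   parameters.
#' @return An object of class `prior_spec` with elements `variant`, `free`
#'   (data frame `name`, `lo`, `hi`) and `fixed` (named numeric).
#' @export
prior_spec <- function(variant = model_variants(), span = 100,
                       ranges = list()) {
  variant <- match.arg(variant)
  centre <- unlist(reference_parameters()[.param_names])
  free_names <- .free_params(variant)
  lo <- hi <- numeric(length(free_names))
  for (i in seq_along(free_names)) {
    v <- centre[[free_names[i]]]
    if (!is.finite(v) || v <= 0) v <- 1
    lo[i] <- v / span
    hi[i] <- v * span
  }
  free <- data.frame(name = free_names, lo = lo, hi = hi,
                     stringsAsFactors = FALSE)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] <= 0 || r[1] > r[2])
      stop("invalid range for ", nm, ": need 0 < lo <= hi")
    free[free$name == nm, c("lo", "hi")] <- as.list(r)
  }
  fixed <- c(Pol = 1, c_GliA = 10, c_GliR = 0, c_X = 0)
  structure(list(variant = variant, free = free, fixed = fixed),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Log-uniform prior for the %s variant: %d free parameters\n",
              x$variant, nrow(x$free)))
  print(x$free, row.names = FALSE)
  cat("fixed:", paste(sprintf("%s=%g", names(x$fixed), x$fixed),
                      collapse = ", "), "\n")
  invisible(x)
}

# matrix of n draws in log10 space
.draw_log10 <- function(prior, n) {
  d <- nrow(prior$free)
  m <- matrix(stats::runif(n * d), n, d)
  lo <- log10(prior$free$lo)
  hi <- log10(prior$free$hi)
  m <- sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(m) <- prior$free$name
  m
}

# assemble a full shh_params from one log10 draw
.params_from_log10 <- function(prior, theta) {
  vals <- as.list(10^theta)
  names(vals) <- prior$free$name
  vals <- c(vals, as.list(prior$fixed))
  shh_parameters(vals)
}

#' Sample parameter sets from a prior
#'
#' Draws each free parameter independently, uniform in log10 space over its
#' prior range; fixed entries are carried through unchanged.
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @return A single `shh_params` for `n = 1`, else a list of them.
#' @export
sample_prior <- function(prior, n = 1) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(prior$free$lo > prior$free$hi))
    stop("prior ranges must have lo <= hi")
  m <- .draw_log10(prior, n)
  out <- lapply(seq_len(n), function(i) .params_from_log10(prior, m[i, ]))
  if (n == 1) out[[1]] else out
}

# Simulate a particle under both ramps and score it. Returns distance Inf on
# solver failure.
.particle_distance <- function(params, variant, signals,
                               t_pre = 300, t_stim = 70, dt_out = 0.5,
                               rtol = 1e-5, atol = 1e-8,
                               requirements = .default_requirements(),
                               gliA_required = 2) {
  p <- apply_variant(params, variant)
  fail <- list(distance = Inf, metrics = NULL)
  zero <- shh_signal("constant", level = 0)
  y0 <- rep(0, length(.species_names))
  pre <- .integrate(y0, c(0, t_pre), .parms_vector(p, variant, zero),
                    rtol, atol)
  if (is.null(pre)) return(fail)
  ss <- pre[nrow(pre), -1L]
  times <- seq(0, t_stim, by = dt_out)
  o1 <- .integrate(ss, times, .parms_vector(p, variant, signals[[1]]),
                   rtol, atol)
  if (is.null(o1)) return(fail)
  o2 <- .integrate(ss, times, .parms_vector(p, variant, signals[[2]]),
                   rtol, atol)
  if (is.null(o2)) return(fail)
  i_gfp <- 1L + match("gfp_mRNA", .species_names)
  i_ptc <- 1L + match("ptc_mRNA", .species_names)
  i_gliA <- 1L + match("GliA", .species_names)
  met <- function(i) compute_metrics(times, o1[, i], o2[, i], ss[i - 1L])
  gfp <- met(i_gfp)
  gliA <- met(i_gliA)
  ptc <- if (variant %in% c("full", "ptch1_feedback")) met(i_ptc) else NULL
  sc <- total_distance(gfp, ptc, gliA, variant, requirements, gliA_required)
  list(distance = sc$total, metrics = list(gfp = gfp, ptc = ptc, gliA = gliA),
       score = sc)
}

#' Fit the pathway model by ABC-SMC
#'
#' Sequential Monte Carlo approximate Bayesian computation over a model
#' variant's free parameters, against the integer adaptation distance
#' ([total_distance()]) computed from simulations of the two normalized Shh
#' ramps. Generation 0 is rejection sampling from the prior (every
#' successfully simulated draw is kept, i.e. an infinite initial epsilon).
#' Each later generation resamples particles by weight, perturbs them with a
#' component-wise uniform kernel in log10 space (half-width = half the
#' current population range per parameter; proposals outside the prior are
#' redrawn), and accepts those with distance at or below the generation's
#' epsilon. The epsilon schedule is automatic: the floor of the current
#' population's median distance, forced strictly decreasing, ending at 0.
#' Importance weights follow the standard SMC-ABC scheme (uniform prior
#' density over a uniform kernel mixture). A particle whose ODE solve fails
#' is assigned infinite distance.
#'
#' @param variant one of [model_variants()].
#' @param prior a [prior_spec()]; defaults to `prior_spec(variant)`.
#' @param n_particles population size.
#' @param max_generations generation cap.
#' @param signals list of the two ramp inputs; defaults to the normalized
#'   ramps reaching 2 and 1 at 70 h ([build_ramp_inputs()]).
#' @param seed RNG seed (set once at entry; a fixed seed makes the whole run
#'   reproducible).
#' @param max_sims_per_gen per-generation simulation budget; exhausting it
#'   returns the populations completed so far, flagged as partial, rather
#'   than raising an error.
#' @param rtol,atol,dt_out,t_pre,t_stim simulation controls as in
#'   [run_protocol()].
#' @param requirements,gliA_required distance-function requirements, see
#'   [total_distance()].
#' @param verbose print per-generation progress.
#' @return An object of class `shh_abc` with elements `populations` (one
#'   record per generation: log10 particle matrix, distances, weights,
#'   per-particle metrics, epsilon, acceptance rate), `final`, `converged`
#'   (TRUE once a distance-0 population is filled), and the run settings.
#'   Methods: `print`, `summary`, `coef` (weighted posterior medians on the
#'   natural scale), `plot`.
#' @export
shh_abc <- function(variant = model_variants(), prior = NULL,
                    n_particles = 128, max_generations = 30,
                    signals = NULL, seed = NULL,
                    max_sims_per_gen = 400 * n_particles,
                    rtol = 1e-5, atol = 1e-8, dt_out = 0.5,
                    t_pre = 300, t_stim = 70,
                    requirements = .default_requirements(),
                    gliA_required = 2, verbose = FALSE) {
  variant <- match.arg(variant)
  if (is.null(prior)) prior <- prior_spec(variant)
  stopifnot(inherits(prior, "prior_spec"), n_particles >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(signals))
    signals <- build_ramp_inputs(list(slope = 1, intercept = 0),
                                 list(slope = 1, intercept = 0),
                                 t_stim = t_stim)
  d <- nrow(prior$free)
  lo <- log10(prior$free$lo)
  hi <- log10(prior$free$hi)
  dist_of <- function(theta)
    .particle_distance(.params_from_log10(prior, theta), variant, signals,
                       t_pre, t_stim, dt_out, rtol, atol, requirements,
                       gliA_required)

  populations <- list()
  # generation 0: rejection sampling at epsilon = Inf (solver failures only)
  theta <- matrix(NA_real_, n_particles, d, dimnames = list(NULL, prior$free$name))
  dists <- numeric(n_particles)
  metrics <- vector("list", n_particles)
  filled <- 0L
  sims <- 0L
  while (filled < n_particles && sims < max_sims_per_gen) {
    cand <- .draw_log10(prior, 1)[1, ]
    sims <- sims + 1L
    res <- dist_of(cand)
    if (is.finite(res$distance)) {
      filled <- filled + 1L
      theta[filled, ] <- cand
      dists[filled] <- res$distance
      metrics[[filled]] <- res$metrics
    }
  }
  if (filled < n_particles)
    stop("could not fill generation 0 within the simulation budget")
  w <- rep(1 / n_particles, n_particles)
  populations[[1]] <- list(generation = 0L, epsilon = Inf, theta = theta,
                           distances = dists, weights = w, metrics = metrics,
                           n_sims = sims, acceptance = filled / sims)
  if (verbose)
    message(sprintf("gen 0: eps=Inf, median distance %g", stats::median(dists)))

  epsilon <- Inf
  converged <- FALSE
  partial <- FALSE
  for (gen in seq_len(max_generations)) {
    eps_next <- floor(stats::median(dists))
    if (is.finite(epsilon)) eps_next <- min(eps_next, epsilon - 1L)
    eps_next <- max(eps_next, 0L)
    h <- (apply(theta, 2, max) - apply(theta, 2, min)) / 2
    h <- pmax(h, 1e-6)
    new_theta <- matrix(NA_real_, n_particles, d,
                        dimnames = list(NULL, prior$free$name))
    new_dists <- numeric(n_particles)
    new_metrics <- vector("list", n_particles)
    filled <- 0L
    sims <- 0L
    while (filled < n_particles && sims < max_sims_per_gen) {
      i <- sample.int(n_particles, 1, prob = w)
      cand <- theta[i, ] + stats::runif(d, -h, h)
      tries <- 0L
      while (any(cand < lo | cand > hi) && tries < 100L) {
        cand <- theta[i, ] + stats::runif(d, -h, h)
        tries <- tries + 1L
      }
      if (any(cand < lo | cand > hi)) next
      sims <- sims + 1L
      res <- dist_of(cand)
      if (res$distance <= eps_next) {
        filled <- filled + 1L
        new_theta[filled, ] <- cand
        new_dists[filled] <- res$distance
        new_metrics[[filled]] <- res$metrics
      }
    }
    if (filled < n_particles) {
      partial <- TRUE
      if (verbose)
        message(sprintf(
          "gen %d: budget exhausted at eps=%d (%d/%d accepted) - partial result",
          gen, eps_next, filled, n_particles))
      break
    }
    # SMC importance weights: uniform prior over uniform kernel mixture
    new_w <- numeric(n_particles)
    for (j in seq_len(n_particles)) {
      inside <- rep(TRUE, n_particles)
      for (k in seq_len(d)) {
        inside <- inside & abs(theta[, k] - new_theta[j, k]) <= h[k]
        if (!any(inside)) break
      }
      denom <- sum(w[inside])
      new_w[j] <- if (denom > 0) 1 / denom else 0
    }
    if (sum(new_w) == 0) new_w <- rep(1, n_particles)
    new_w <- new_w / sum(new_w)

    theta <- new_theta
    dists <- new_dists
    metrics <- new_metrics
    w <- new_w
    epsilon <- eps_next
    populations[[length(populations) + 1]] <- list(
      generation = gen, epsilon = eps_next, theta = theta,
      distances = dists, weights = w, metrics = metrics,
      n_sims = sims, acceptance = filled / sims)
    if (verbose)
      message(sprintf("gen %d: eps=%d, acceptance %.3f, median distance %g",
                      gen, eps_next, filled / sims, stats::median(dists)))
    if (eps_next == 0L) {
      converged <- TRUE
      break
    }
  }

  structure(list(variant = variant, prior = prior,
                 n_particles = n_particles, signals = signals,
                 populations = populations,
                 final = populations[[length(populations)]],
                 converged = converged, partial = partial, seed = seed,
                 settings = list(rtol = rtol, atol = atol, dt_out = dt_out,
                                 t_pre = t_pre, t_stim = t_stim,
                                 requirements = requirements,
                                 gliA_required = gliA_required),
                 call = match.call()),
            class = "shh_abc")
}

#' Weighted quantiles
#'
#' Inverse-CDF weighted quantile (smallest value whose cumulative weight
#' reaches the probability); with uniform weights it equals
#' `quantile(x, probs, type = 1)`.
#'
#' @param x numeric values.
#' @param w nonnegative weights.
#' @param probs probabilities.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (sum(w) <= 0) stop("weights must have positive total")
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Marginal posterior summaries of an ABC population
#'
#' Weighted quantiles (2.5/25/50/75/97.5%) of each free parameter on the
#' log10 scale, with the prior range alongside.
#'
#' @param x a `shh_abc` fit or one of its population records.
#' @param prior the `prior_spec` (taken from the fit when `x` is one).
#' @return Data frame, one row per free parameter.
#' @export
posterior_summaries <- function(x, prior = NULL) {
  if (inherits(x, "shh_abc")) {
    prior <- x$prior
    x <- x$final
  }
  if (is.null(x$theta) || !nrow(x$theta)) stop("empty population")
  qs <- t(apply(x$theta, 2, weighted_quantile, w = x$weights))
  out <- data.frame(
    parameter = colnames(x$theta),
    log10_q2.5 = qs[, 1], log10_q25 = qs[, 2], log10_median = qs[, 3],
    log10_q75 = qs[, 4], log10_q97.5 = qs[, 5],
    median = 10^qs[, 3], row.names = NULL)
  if (!is.null(prior)) {
    out$prior_lo <- prior$free$lo
    out$prior_hi <- prior$free$hi
  }
  out
}

#' Extract distance-zero (or low-distance) particles
#'
#' @param fit a `shh_abc` fit.
#' @param distance keep particles with distance at or below this value.
#' @return List with `params` (list of `shh_params`), `theta` (log10
#'   matrix), `distances`, `metrics` and `weights` of the kept particles.
#' @export
accepted_particles <- function(fit, distance = 0) {
  stopifnot(inherits(fit, "shh_abc"))
  pop <- fit$final
  keep <- which(pop$distances <= distance)
  list(
    params = lapply(keep, function(i)
      .params_from_log10(fit$prior, pop$theta[i, ])),
    theta = pop$theta[keep, , drop = FALSE],
    distances = pop$distances[keep],
    metrics = pop$metrics[keep],
    weights = pop$weights[keep]
  )
}

#' @export
print.shh_abc <- function(x, ...) {
  cat(sprintf("ABC-SMC fit of the %s variant: %d particles, %d generation(s)\n",
              x$variant, x$n_particles, length(x$populations)))
  cat(sprintf("final epsilon %s; %s\n",
              format(x$final$epsilon),
              if (x$converged) "converged (distance-0 population filled)"
              else if (x$partial) "partial (simulation budget exhausted)"
              else "generation cap reached"))
  cat(sprintf("final median distance %g; distance-0 particles: %d\n",
              stats::median(x$final$distances),
              sum(x$final$distances == 0)))
  invisible(x)
}

#' @export
summary.shh_abc <- function(object, ...) {
  out <- list(variant = object$variant, converged = object$converged,
              n_generations = length(object$populations),
              epsilons = vapply(object$populations, `[[`, numeric(1),
                                "epsilon"),
              acceptance = vapply(object$populations, `[[`, numeric(1),
                                  "acceptance"),
              marginals = posterior_summaries(object))
  class(out) <- "summary.shh_abc"
  out
}

#' @export
print.summary.shh_abc <- function(x, ...) {
  cat(sprintf("ABC-SMC posterior (%s variant), %d generations, %s\n",
              x$variant, x$n_generations,
              if (x$converged) "epsilon reached 0" else "not converged"))
  cat("epsilon schedule:", paste(format(x$epsilons), collapse = " -> "), "\n")
  cat("marginal posterior quantiles (log10 scale):\n")
  print(x$marginals, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.shh_abc <- function(object, ...) {
  s <- posterior_summaries(object)
  med <- setNames(s$median, s$parameter)
  c(med, object$prior$fixed)
}

#' @export
plot.shh_abc <- function(x, ...) {
  s <- posterior_summaries(x)
  n <- nrow(s)
  graphics::plot(NULL, xlim = range(log10(c(s$prior_lo, s$prior_hi))),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "log10 parameter value", ylab = "",
                 main = sprintf("Posterior marginals (%s)", x$variant), ...)
  graphics::axis(2, at = seq_len(n), labels = s$parameter, las = 1,
                 cex.axis = 0.7)
  graphics::segments(log10(s$prior_lo), seq_len(n), log10(s$prior_hi),
                     seq_len(n), col = "grey80", lwd = 4)
  graphics::segments(s$log10_q2.5, seq_len(n), s$log10_q97.5, seq_len(n),
                     lwd = 1.5)
  graphics::segments(s$log10_q25, seq_len(n), s$log10_q75, seq_len(n),
                     lwd = 4, col = "steelblue")
  graphics::points(s$log10_median, seq_len(n), pch = 19)
  invisible(x)
}
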
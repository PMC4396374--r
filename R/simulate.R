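# Simulation protocol: pre-equilibration followed by Shh stimulation.

# Build the numeric parameter vector handed to the compiled RHS.
.parms_vector <- function(params, variant, signal) {
  kind <- switch(signal$kind, constant = 0, ramp = 1, pulse = 2)
  c(unlist(params[.param_names], use.names = FALSE),
    .variant_code(variant), kind, signal$onset, signal$level,
    if (is.finite(signal$duration)) signal$duration else 1e9)
}

#' Pathway model right-hand side (reference implementation)
#'
#' Time derivatives of the ten pathway species under a given Shh input. This
#' is the plain-R reference for the compiled right-hand side that the solver
#' uses; the two are tested against each other.
#'
#' Species (in order): `ptc_mRNA`, `Ptc_inactive`, `Ptc_active`, `gliFL_mRNA`,
#' `GliFL`, `GliA`, `GliR`, `x_mRNA`, `X`, `gfp_mRNA`. Shh binds active Ptch1
#' by mass action (the ligand is an exogenous, non-depleted input; the
#' complex is not tracked). Unbound Ptch1 inhibits GliFL -> GliA conversion
#' through the factor `Km_Ptch1 / (Km_Ptch1 + Ptc_active)`; GliFL converts to
#' GliR at a constant rate. Target-gene transcription follows
#' [regulation_activity()]: GliA/GliR compete at two sites on the ptch1, x
#' and gfp promoters; X acts at a single site on the gli promoter with
#' cooperativity `c_X`. Reduced variants replace the decoupled promoters'
#' occupancy with its basal (polymerase-only) value.
#'
#' @param state named or unnamed numeric vector of the ten species.
#' @param t time (h).
#' @param params a [shh_parameters()] set.
#' @param variant one of [model_variants()].
#' @param shh Shh concentration at `t`, or an `shh_signal`.
#' @return Numeric vector of derivatives, named by species.
#' @export
pathway_rhs <- function(state, t, params, variant = "full", shh = 0) {
  variant <- match.arg(variant, .variant_names)
  if (anyNA(state) || any(!is.finite(state))) stop("NaN/Inf in state")
  if (inherits(shh, "shh_signal")) shh <- signal_value(shh, t)
  if (shh < 0) stop("shh input must be nonnegative")
  p <- params
  s <- setNames(as.numeric(state), .species_names)

  basal <- function(K_pol) regulation_activity(0, 0, 1, 1, K_pol, p$Pol, 1)
  f_ptc <- if (variant %in% c("gli_stability", "gli_transcription"))
    basal(p$K_Pol_ptc)
  else regulation_activity(s["GliA"], s["GliR"], p$K_Gli_ptc, p$c_GliA,
                           p$K_Pol_ptc, p$Pol, 2)
  f_gli <- if (variant %in% c("gli_stability", "ptch1_feedback"))
    basal(p$K_Pol_gli)
  else regulation_activity(s["X"], 0, p$K_X_gli, p$c_X, p$K_Pol_gli, p$Pol, 1)
  f_x <- regulation_activity(s["GliA"], s["GliR"], p$K_Gli_x, p$c_GliA,
                             p$K_Pol_x, p$Pol, 2)
  f_gfp <- regulation_activity(s["GliA"], s["GliR"], p$K_Gli_gfp, p$c_GliA,
                               p$K_Pol_gfp, p$Pol, 2)
  hill <- p$Km_Ptch1 / (p$Km_Ptch1 + s["Ptc_active"])

  d <- c(
    ptc_mRNA = p$tr_ptc * f_ptc - p$deg_ptc * s["ptc_mRNA"],
    Ptc_inactive = p$tl_Ptc * s["ptc_mRNA"] -
      (p$act_Ptc + p$deg_Ptc) * s["Ptc_inactive"],
    Ptc_active = p$act_Ptc * s["Ptc_inactive"] - p$deg_Ptc * s["Ptc_active"] -
      p$k_ShhPtc * shh * s["Ptc_active"],
    gliFL_mRNA = p$tr_gliFL * f_gli - p$deg_gliFL * s["gliFL_mRNA"],
    GliFL = p$tl_GliFL * s["gliFL_mRNA"] - p$conv_GliA * s["GliFL"] * hill -
      p$conv_GliR * s["GliFL"] - p$deg_GliFL * s["GliFL"],
    GliA = p$conv_GliA * s["GliFL"] * hill - p$deg_GliA * s["GliA"],
    GliR = p$conv_GliR * s["GliFL"] - p$deg_GliR * s["GliR"],
    x_mRNA = p$tr_x * f_x - p$deg_x * s["x_mRNA"],
    X = p$tl_X * s["x_mRNA"] - p$deg_X * s["X"],
    gfp_mRNA = p$tr_gfp * f_gfp - p$deg_gfp * s["gfp_mRNA"]
  )
  setNames(as.numeric(d), .species_names)
}

# Low-level integration with the compiled RHS; returns the deSolve matrix or
# NULL on solver failure.
.integrate <- function(y0, times, parvec, rtol, atol, maxsteps = 50000L) {
  out <- try(suppressWarnings(
    deSolve::lsoda(y = y0, times = times, func = "derivs_shh",
                   parms = parvec, dllname = "shhadapt",
                   initfunc = "initmod_shh", rtol = rtol, atol = atol,
                   maxsteps = maxsteps)
  ), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times) ||
      anyNA(out[nrow(out), ]))
    return(NULL)
  out
}

#' Run the pre-equilibration + stimulation protocol
#'
#' Integrates the pathway model from empty initial conditions with zero Shh
#' for `t_pre` hours to its basal steady state, then applies the given Shh
#' input for `t_stim` hours, reporting trajectories on a fixed output grid.
#'
#' The steady-state criterion at hand-off is
#' `max |dS/dt| / (|S| + 1e-9) < ss_tol`; failing it flags the result with a
#' warning rather than aborting.
#'
#' @param params a [shh_parameters()] set.
#' @param variant one of [model_variants()]; variant constraints are applied
#'   with [apply_variant()] before integration.
#' @param input an `shh_signal`, applied on the stimulation clock (t = 0 at
#'   stimulation start).
#' @param t_pre pre-equilibration time (h).
#' @param t_stim stimulation window (h).
#' @param dt_out output grid step (h).
#' @param rtol,atol solver tolerances (lsoda).
#' @param ss_tol relative steady-state tolerance (1/h).
#' @return An object of class `pathway_sim`: list with `times`, `traj`
#'   (matrix, one column per species), `pre_state`, `steady` flag, and the
#'   call ingredients.
#' @examples
#' sim <- run_protocol(reference_parameters(),
#'                     input = shh_signal("pulse", level = 1, duration = 48))
#' head(sim$traj[, "ptc_mRNA"])
#' @export
run_protocol <- function(params, variant = "full", input,
                         t_pre = 300, t_stim = 70, dt_out = 0.5,
                         rtol = 1e-6, atol = 1e-9, ss_tol = 1e-6) {
  variant <- match.arg(variant, .variant_names)
  validate_parameters(params)
  p <- apply_variant(params, variant)
  stopifnot(inherits(input, "shh_signal"))

  zero <- shh_signal("constant", level = 0)
  y0 <- setNames(rep(0, length(.species_names)), .species_names)
  pre <- .integrate(y0, c(0, t_pre), .parms_vector(p, variant, zero),
                    rtol, atol)
  if (is.null(pre))
    stop("pre-equilibration solver failure for parameter set: ",
         paste(sprintf("%s=%g", .param_names, unlist(p[.param_names])),
               collapse = ", "))
  ss <- setNames(pre[nrow(pre), -1L], .species_names)
  dss <- pathway_rhs(ss, t_pre, p, variant, 0)
  steady <- max(abs(dss) / (abs(ss) + 1e-9)) < ss_tol
  if (!steady)
    warning("pre-equilibration did not reach steady state within t_pre")

  times <- seq(0, t_stim, by = dt_out)
  out <- .integrate(ss, times, .parms_vector(p, variant, input), rtol, atol)
  if (is.null(out))
    stop("stimulation solver failure for parameter set: ",
         paste(sprintf("%s=%g", .param_names, unlist(p[.param_names])),
               collapse = ", "))
  traj <- out[, -1L, drop = FALSE]
  colnames(traj) <- .species_names
  structure(list(times = times, traj = traj, pre_state = ss,
                 steady = steady, params = p, variant = variant,
                 input = input, rtol = rtol, atol = atol),
            class = "pathway_sim")
}

#' @export
print.pathway_sim <- function(x, ...) {
  cat(sprintf("Pathway simulation (%s variant): %d species on [0, %g] h (%d points)\n",
              x$variant, ncol(x$traj), max(x$times), length(x$times)))
  cat(sprintf("input: %s; pre-equilibration %s\n", x$input$kind,
              if (x$steady) "steady" else "NOT steady"))
  invisible(x)
}

#' Tidy data frame of a simulated trajectory
#'
#' @param x a `pathway_sim`.
#' @param ... unused.
#' @return Data frame with columns `time_h`, `species`, `value`.
#' @export
as.data.frame.pathway_sim <- function(x, ...) {
  data.frame(
    time_h = rep(x$times, times = ncol(x$traj)),
    species = rep(colnames(x$traj), each = length(x$times)),
    value = as.vector(x$traj)
  )
}
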
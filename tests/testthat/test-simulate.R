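test_that("with all synthesis rates zero every species purely decays", {
  p <- shh_parameters(tr_ptc = 0, tr_gliFL = 0, tr_x = 0, tr_gfp = 0,
                      tl_Ptc = 0, tl_GliFL = 0, tl_X = 0,
                      conv_GliA = 0, conv_GliR = 0, act_Ptc = 0)
  state <- rep(2, 10)
  d <- pathway_rhs(state, 0, p, "full", shh = 0)
  expect_true(all(d < 0))
})

test_that("without Ptch1 the GliA production term is the full conversion rate", {
  p <- reference_parameters()
  state <- c(0, 0, 0, 0, 5, 0, 0, 0, 0, 0)  # GliFL = 5, Ptc_active = 0
  d <- pathway_rhs(state, 0, p, "full")
  expect_equal(unname(d["GliA"]), p$conv_GliA * 5)  # Hill factor = 1
})

test_that("NaN states and unknown variants are rejected", {
  p <- reference_parameters()
  expect_error(pathway_rhs(c(NaN, rep(0, 9)), 0, p), "NaN")
  expect_error(pathway_rhs(rep(0, 10), 0, p, variant = "bogus"))
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- fixture_params(c_X = 10)
  input <- shh_signal("pulse", level = 1, duration = 48)
  sim <- suppressWarnings(run_protocol(p, "full", input, t_stim = 30))
  # same integration with the plain-R derivative function
  r_rhs <- function(t, y, parms) {
    list(pathway_rhs(y, t, p, "full", signal_value(input, t)))
  }
  ref <- deSolve::lsoda(sim$pre_state, sim$times, r_rhs, parms = NULL,
                        rtol = 1e-6, atol = 1e-9)
  expect_equal(unname(sim$traj), unname(ref[, -1]), tolerance = 1e-4)
})

test_that("a zero input leaves the equilibrated system constant", {
  sim <- run_protocol(fixture_params(), "full",
                      shh_signal("constant", level = 0), t_pre = 1500)
  expect_true(sim$steady)
  rel <- abs(sweep(sim$traj, 2, sim$traj[1, ], "-")) /
    (abs(sim$traj[1, ][col(sim$traj)]) + 1e-9)
  expect_lt(max(rel), 1e-3)
})

test_that("trajectories stay nonnegative across prior draws", {
  set.seed(42)
  prior <- prior_spec("full")
  ps <- sample_prior(prior, 10)
  ramps <- build_ramp_inputs(list(slope = 1, intercept = 0),
                             list(slope = 1, intercept = 0))
  for (p in ps) {
    sim <- try(suppressWarnings(
      run_protocol(p, "full", ramps$signal1)), silent = TRUE)
    if (inherits(sim, "try-error")) next  # solver failure is reported, not silent
    expect_gte(min(sim$traj), -1e-6)
  }
})

test_that("the unstimulated reference state is repressor-dominated", {
  # cross-checked at two solver tolerances
  s1 <- suppressWarnings(run_protocol(fixture_params(), "full",
                                      shh_signal("constant", level = 0),
                                      rtol = 1e-6, atol = 1e-9))
  s2 <- suppressWarnings(run_protocol(fixture_params(), "full",
                                      shh_signal("constant", level = 0),
                                      rtol = 1e-8, atol = 1e-11))
  for (s in list(s1, s2))
    expect_gt(s$pre_state[["GliR"]], 10 * s$pre_state[["GliA"]])
  expect_equal(s1$pre_state, s2$pre_state, tolerance = 1e-3)
})

test_that("halving solver tolerances barely moves the reference trajectory", {
  input <- shh_signal("pulse", level = 1, duration = 48)
  a <- suppressWarnings(run_protocol(fixture_params(), "full", input,
                                     rtol = 1e-6, atol = 1e-9))
  b <- suppressWarnings(run_protocol(fixture_params(), "full", input,
                                     rtol = 5e-7, atol = 5e-10))
  rel <- abs(a$traj - b$traj) / (abs(b$traj) + 1e-9)
  expect_lt(max(rel), 1e-3)
})

test_that("with no Shh binding the ptch1-feedback variant ignores the input", {
  p <- shh_parameters(k_ShhPtc = 0)
  sim <- run_protocol(p, "ptch1_feedback", shh_signal("ramp", slope = 2 / 70),
                      t_pre = 1500)
  expect_true(sim$steady)
  rel <- abs(sweep(sim$traj, 2, sim$traj[1, ], "-")) /
    (abs(sim$traj[1, ][col(sim$traj)]) + 1e-9)
  expect_lt(max(rel), 1e-4)
})

test_that("equal isoform stability abolishes adaptation in the stability variant", {
  p <- shh_parameters(deg_GliA = 0.1, deg_GliR = 0.1, deg_GliFL = 0.1)
  sim <- run_protocol(p, "gli_stability", shh_signal("constant", level = 1),
                      t_pre = 1500)
  g <- sim$traj[, "gfp_mRNA"]
  expect_true(all(diff(g) > -1e-8))  # monotone approach to the step response
  m <- compute_metrics(sim$times, g, g, basal = sim$pre_state[["gfp_mRNA"]])
  expect_lt(m$adaptation1, 1.01)
})

test_that("re-equilibration from the steady state is idempotent", {
  sim <- run_protocol(fixture_params(), "full",
                      shh_signal("constant", level = 0), t_pre = 2000)
  expect_true(sim$steady)
  drift <- abs(sim$traj[nrow(sim$traj), ] - sim$pre_state) /
    (abs(sim$pre_state) + 1e-9)
  expect_lt(max(drift), 1e-4)
})
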
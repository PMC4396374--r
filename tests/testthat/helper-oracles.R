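# Independent oracles and shared fixtures for the test suite.

# Brute-force promoter-microstate enumeration: every site is empty, activator-
# bound or repressor-bound; polymerase is bound or not. Boltzmann weight of a
# microstate is the product of its site statistical weights (1, K*A, K*R),
# times K_pol*pol and the cooperativity factor of every bound TF (c_act for
# activator, c_rep for repressor) when polymerase is bound.
enumerate_occupancy <- function(A, R, K_tf, c_act, K_pol, pol, n_sites,
                                c_rep = 0) {
  site_w <- c(empty = 1, act = K_tf * A, rep = K_tf * R)
  site_c <- c(empty = 1, act = c_act, rep = c_rep)
  states <- expand.grid(rep(list(c("empty", "act", "rep")), n_sites),
                        stringsAsFactors = FALSE)
  z_off <- 0
  z_on <- 0
  for (i in seq_len(nrow(states))) {
    occ <- as.character(states[i, ])
    w <- prod(site_w[occ])
    z_off <- z_off + w
    z_on <- z_on + w * K_pol * pol * prod(site_c[occ])
  }
  z_on / (z_off + z_on)
}

# the published reference parameter set, from the packaged fixture
fixture_params <- function(...) {
  p <- read_parameters(system.file("extdata", "fig7_parameters.json",
                                   package = "shhadapt"))
  if (length(list(...))) p <- shh_parameters(utils::modifyList(unclass(p), list(...)))
  p
}

# piecewise-linear evaluation of a tent trajectory on a grid
tent_trajectory <- function(times, basal = 1, peak = 60, t_peak = 20,
                            level = 10, t_level = 40) {
  ifelse(times <= t_peak, basal + (peak - basal) * times / t_peak,
    ifelse(times < t_level,
           peak + (level - peak) * (times - t_peak) / (t_level - t_peak),
           level))
}
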
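# shhadapt

Tools for analysing the dynamics of Sonic Hedgehog (Shh) signalling in the
vertebrate neural tube. During patterning, the Shh gradient emanating from
the notochord and floor plate *increases* in amplitude over time, yet the
downstream transcriptional response (net Gli activity) rises, peaks and then
declines — it *adapts*. This package provides the computational machinery to
study how the wiring of the Ptch1/Gli pathway can produce adaptation under a
rising input, and to quantify the spatial gradient that drives it:

- a **thermodynamic promoter-occupancy model** of Gli-mediated
  transcription, where activator (GliA) and repressor (GliR) isoforms
  compete at two binding sites and bound activator recruits polymerase with
  cooperativity *c*:
  *f = Z*<sub>on</sub> / (*Z*<sub>off</sub> + *Z*<sub>on</sub>), with
  *Z*<sub>off</sub> = (1 + *K·A* + *K·R*)<sup>*n*</sup> and
  *Z*<sub>on</sub> = *K*<sub>pol</sub>*P* (1 + *c·K·A*)<sup>*n*</sup>;
- an **ODE model of the pathway** (ptch1/Ptch1 with an inactive maturation
  step, gliFL/GliFL and its GliA/GliR isoforms, an intermediary Gli-induced
  factor X, and a GBS-GFP reporter), driven by prescribed Shh inputs, in
  four wirings that isolate candidate adaptation mechanisms: full, Gli
  stability (differential isoform turnover), Ptch1 feedback, and Gli
  transcriptional regulation;
- **adaptation metrics and an integer distance**: fold-induction within
  40 h, sensitivity between two graded inputs (max1/max2), and adaptation
  (peak over the 40–70 h mean), each graded on an incremental scoring
  ladder (for the adaptation requirement 2.5: ratio < 1 scores 10, < 1.1
  scores 5, < 1.5 scores 2, < 2.5 scores 1, ≥ 2.5 scores 0);
- **ABC-SMC inference** (`shh_abc()`) over log-uniform priors spanning four
  orders of magnitude, returning a weighted posterior population of
  parameter sets whose simulated responses satisfy induction ≥ 50-fold
  (signal 1) and ≥ 30-fold (signal 2), sensitivity ≥ 1.5 and adaptation
  ≥ 2.5;
- **gradient quantification**: background subtraction, staging by
  dorsoventral (DV) length, stage/position binning with 95% confidence
  intervals, spline interpolation, source-boundary detection, nonlinear
  least-squares fits of *C(x) = C₀ e^(−x/λ)*, amplitude/decay-length trends
  against tissue size, and stereotyping of ventral time courses into the
  two normalized ramp inputs (maxima 2 and 1 over a 70-h window);
- a **synthetic-data generator** so the entire analysis is testable without
  imaging data, with every draw's ground truth recorded.

## Worked example

Simulate the published reference parameter set under a 48-h Shh pulse with
the factor X acting as a repressor (`c_X = 0`), and measure the ptch1 mRNA
response:

```r
library(shhadapt)
params <- reference_parameters(c_X = 0)
pulse  <- shh_signal("pulse", level = 1, duration = 48)
sim    <- run_protocol(params, "full", pulse)
compute_metrics(sim$times, sim$traj[, "ptc_mRNA"], sim$traj[, "ptc_mRNA"],
                basal = sim$pre_state[["ptc_mRNA"]])
#> induction 55.3 / 55.3, sensitivity 1, adaptation 11 / 11 (basal 0.651)
```

ptch1 mRNA is induced 55-fold over its basal level and then adapts 11-fold:
it peaks and declines while the pulse is still on. Setting `c_X = 10`
(X upregulates gli transcription, as in NIH3T3 fibroblasts) abolishes the
adaptation — the response keeps rising for the whole pulse.

Quantify a synthetic gradient cohort:

```r
set.seed(1)
co   <- generate_cohort(cohort_spec())
prof <- subtract_background(co$profiles[[1]])
fit_exponential(prof)
#> Exponential gradient fit: C0 = 101.8 a.u., lambda = 19.88 um, R^2 = 0.941 (boundary 12 um, n = 65)

fits <- lapply(lapply(co$profiles, subtract_background), fit_exponential)
trend_vs_size(fits, co$truth$dv_length)
#> Gradient trends vs DV length:
#>  response    slope intercept r_squared  p_value
#>        C0  1.24182     -80.6  0.800455 2.63e-11
#>    lambda -0.00104      20.9  0.000194 9.42e-01
```

The amplitude grows linearly with tissue size (R² = 0.80) while the decay
length shows no size trend — the gradient steepens in absolute terms but
keeps a roughly constant length scale near 20 µm.

Fit the Gli-stability wiring by ABC-SMC and inspect the posterior:

```r
fit <- shh_abc("gli_stability", n_particles = 128, seed = 1)
fit          # epsilon schedule, acceptance rates, distance-0 count
summary(fit) # weighted marginal quantiles per parameter (log10 scale)
coef(fit)    # posterior medians on the natural scale
plot(fit)    # marginals against their prior ranges
```

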
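test_that("a flat trajectory at basal gives unit ratios", {
  t <- seq(0, 70, 0.5)
  y <- rep(3, length(t))
  m <- compute_metrics(t, y, y, basal = 3)
  expect_equal(m$induction1, 1)
  expect_equal(m$induction2, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$adaptation1, 1)
  expect_equal(m$adaptation2, 1)
})

test_that("tent trajectory metrics match direct arithmetic", {
  t <- seq(0, 70, 0.5)
  y <- tent_trajectory(t)
  m <- compute_metrics(t, y, y, basal = 1)
  expect_equal(m$max1, 60)
  expect_equal(m$induction1, 60)
  expect_equal(m$adaptation1, 6)  # constant 10 on [40, 70]
})

test_that("the adapted level equals the closed-form average of a tent", {
  # vertices chosen so the adapted window straddles the declining flank:
  # linear from 60 at t=20 down to 10 at t=60, then flat
  t <- seq(0, 70, 0.25)
  y <- tent_trajectory(t, basal = 1, peak = 60, t_peak = 20, level = 10,
                       t_level = 60)
  m <- compute_metrics(t, y, y, basal = 1)
  # closed form: mean over [40,60] of the line (35 at 40, 10 at 60) and 10 on
  # [60,70]: (20*22.5 + 10*10)/30
  closed <- (20 * (35 + 10) / 2 + 10 * 10) / 30
  expect_equal(m$adapted1, closed)
  # fine-grid numeric cross-check
  tf <- seq(40, 70, 0.001)
  expect_equal(m$adapted1, mean(tent_trajectory(tf, 1, 60, 20, 10, 60)),
               tolerance = 1e-4)
})

test_that("short trajectories are rejected", {
  t <- seq(0, 50, 0.5)
  expect_error(compute_metrics(t, t, t, basal = 1), "cover")
})

test_that("the printed scoring ladder is reproduced for the adaptation criterion", {
  expect_identical(score_ratio(0.9, 2.5), 10L)
  expect_identical(score_ratio(1.05, 2.5), 5L)
  expect_identical(score_ratio(1.3, 2.5), 2L)
  expect_identical(score_ratio(1.8, 2.5), 1L)
  expect_identical(score_ratio(2.2, 2.5), 1L)  # gap carries the last penalty
  expect_identical(score_ratio(2.5, 2.5), 0L)
  expect_identical(score_ratio(3.0, 2.5), 0L)
})

test_that("ladder breakpoints scale proportionally with the requirement", {
  # requirement 50: breakpoints at 50 * c(1, 1.1, 1.5)/2.5 = 20, 22, 30
  expect_identical(score_ratio(19, 50), 10L)
  expect_identical(score_ratio(21, 50), 5L)
  expect_identical(score_ratio(25, 50), 2L)
  expect_identical(score_ratio(45, 50), 1L)
  expect_identical(score_ratio(50, 50), 0L)
  expect_identical(score_ratio(500, 50), 0L)  # exceeding never penalizes
})

test_that("the ladder is monotone non-increasing in the ratio", {
  set.seed(3)
  for (req in c(1.5, 2, 2.5, 30, 50)) {
    r <- sort(stats::runif(100, 0.01, 2 * req))
    s <- score_ratio(r, req)
    expect_true(all(diff(s) <= 0))
  }
  expect_error(score_ratio(-1, 2.5), "positive")
})

test_that("total distance is zero exactly when all requirements are met", {
  t <- seq(0, 70, 0.5)
  mk <- function(ind1, ind2, sens, ad1, ad2) {
    m <- list(induction1 = ind1, induction2 = ind2, sensitivity = sens,
              adaptation1 = ad1, adaptation2 = ad2)
    class(m) <- "adaptation_metrics"
    m
  }
  pass_gliA <- mk(5, 5, 1.4, 3, 3)
  gfp <- mk(55, 35, 55 / 35, 3, 2.6)
  d <- total_distance(gfp, NULL, pass_gliA, "gli_stability")
  expect_identical(d$total, 0L)
  # degrade a single ratio below requirement -> strictly positive score
  worse <- mk(55, 35, 55 / 35, 3, 1.05)
  d2 <- total_distance(worse, NULL, pass_gliA, "gli_stability")
  expect_identical(d2$total, 5L)
  # randomized equivalence: total == 0 iff every ratio >= its requirement
  set.seed(9)
  req <- c(50, 30, 1.5, 2.5, 2.5)
  for (i in 1:50) {
    ratios <- req * 10^stats::runif(5, -0.5, 0.5)
    m <- mk(ratios[1], ratios[2], ratios[3], ratios[4], ratios[5])
    tot <- total_distance(m, NULL, pass_gliA, "gli_stability")$total
    expect_identical(tot == 0L, all(ratios >= req))
  }
})

test_that("ptch1 metrics are scored only for the coupled variants", {
  mk <- function(...) structure(list(induction1 = 100, induction2 = 100,
                                     sensitivity = 2, adaptation1 = 3,
                                     adaptation2 = 3),
                                class = "adaptation_metrics")
  gfp <- mk(); gliA <- mk()
  expect_error(total_distance(gfp, NULL, gliA, "full"), "ptc")
  expect_error(total_distance(gfp, NULL, gliA, "ptch1_feedback"), "ptc")
  d <- total_distance(gfp, gfp, gliA, "full")
  expect_identical(d$total, 0L)
  expect_setequal(unique(d$table$readout), c("gfp_mRNA", "ptc_mRNA", "GliA"))
  # decoupled variants: gfp + GliA only
  d2 <- total_distance(gfp, NULL, gliA, "gli_transcription")
  expect_setequal(unique(d2$table$readout), c("gfp_mRNA", "GliA"))
})
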
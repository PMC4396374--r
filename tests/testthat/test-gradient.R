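test_that("background subtraction clamps at zero and is identity at zero", {
  p <- gradient_profile(0:10, rep(5, 11), dv_length = 20, background = 0)
  expect_equal(subtract_background(p)$intensity, p$intensity)
  q <- gradient_profile(0:10, rep(5, 11), dv_length = 20, background = 5)
  expect_equal(subtract_background(q)$intensity, rep(0, 11))
  r <- gradient_profile(0:10, c(rep(2, 5), rep(8, 6)), dv_length = 20,
                        background = 4)
  expect_equal(subtract_background(r)$intensity, c(rep(0, 5), rep(4, 6)))
})

test_that("profile construction validates its geometry", {
  expect_error(gradient_profile(c(0, 2, 1), 1:3, 10), "increasing")
  expect_error(gradient_profile(0:5, 0:5, 3), "cover")
  expect_error(gradient_profile(0:5, 0:5, 10, background = -1), "nonnegative")
})

test_that("staging by DV length inverts its calibration", {
  cal <- stage_calibration(c(100, 200, 300, 400), c(10, 20, 30, 40))
  expect_equal(as.numeric(stage_by_dv_length(250, cal)), 25)
  expect_equal(dv_length_by_stage(25, cal), 250)
  expect_warning(stage_by_dv_length(500, cal), "extrapolation")
  expect_error(stage_calibration(c(1, 2), c(3, 3)), "zero slope")
  # identity calibration
  id <- stage_calibration(c(0, 1), c(0, 1))
  expect_equal(as.numeric(stage_by_dv_length(0.7, id)), 0.7)
})

test_that("staging recovers a noisy linear law within its confidence interval", {
  set.seed(12)
  spec <- cohort_spec(n_embryos = 60)
  dv <- stats::runif(60, spec$dv_range[1], spec$dv_range[2])
  stage <- (dv - spec$stage_intercept) / spec$stage_slope +
    stats::rnorm(60, 0, 1)
  cal <- stage_calibration(dv, stage)
  ci <- stats::confint(cal$fit)["dv_lengths", ]
  expect_gt(1 / spec$stage_slope, ci[1])
  expect_lt(1 / spec$stage_slope, ci[2])
})

test_that("binning reports means and t confidence intervals", {
  one <- gradient_profile(0:99, rep(7, 100), dv_length = 100)
  b1 <- bin_profiles(list(one))
  expect_true(all(b1$mean == 7))
  expect_true(all(is.na(b1$ci_lo)))
  two <- list(gradient_profile(0:99, rep(4, 100), dv_length = 100),
              gradient_profile(0:99, rep(8, 100), dv_length = 100))
  b2 <- bin_profiles(two)
  expect_true(all(b2$mean == 6))
  expect_true(all(b2$n == 2))
  expect_true(all(b2$ci_lo < 6 & b2$ci_hi > 6))
  expect_error(bin_profiles(list()), "no profiles")
})

test_that("bin confidence intervals achieve near-nominal coverage", {
  set.seed(14)
  hits <- replicate(200, {
    profs <- lapply(1:5, function(i)
      gradient_profile(0:99, stats::rnorm(100, 50, 10), dv_length = 100))
    b <- bin_profiles(profs)
    # per-section bin means have sd 10/sqrt(10); CI should cover 50
    mean(b$ci_lo <= 50 & b$ci_hi >= 50)
  })
  expect_gte(mean(hits), 0.93)
})

test_that("spline interpolation passes through knots and reproduces cubics", {
  x <- seq(0, 10, 2)
  y_line <- 3 * x + 1
  s <- interp_spline(x, y_line, step = 0.1)
  expect_equal(s$y, 3 * s$x + 1, tolerance = 1e-10)
  y_cub <- x^3 - 2 * x^2 + 4
  s2 <- interp_spline(x, y_cub, step = 0.1)
  expect_equal(s2$y, s2$x^3 - 2 * s2$x^2 + 4, tolerance = 1e-8)
  # knots reproduced exactly, and agreement with an independent natural
  # spline at the knots
  nat <- stats::splinefun(x, y_cub, method = "natural")
  at_knots <- s2$y[s2$x %in% x]
  expect_equal(at_knots, nat(x))
  expect_warning(s3 <- interp_spline(c(0, 1, 2), c(0, 1, 4)), "linear")
  expect_equal(s3$y[s3$x == 0.5], 0.5)
})

test_that("the source boundary is the ventral-most intensity maximum", {
  x <- 0:50
  y <- exp(-(x - 8)^2 / 20)
  expect_equal(locate_source_boundary(x, y), 8)
  expect_equal(locate_source_boundary(x, exp(-x / 10)), 0)
  plateau <- c(1, 2, 5, 5, 5, 3, 1)
  expect_equal(locate_source_boundary(0:6, plateau), 2)  # ventral-most tie
  expect_error(locate_source_boundary(0:3, rep(0, 4)), "all-zero")
})

test_that("noiseless exponential profiles are recovered exactly", {
  x <- 0:150
  y <- 100 * exp(-pmax(x - 8, 0) / 20) * ifelse(x < 8, 0.5, 1)
  p <- gradient_profile(x, y, dv_length = 301)
  f <- fit_exponential(p, boundary = 8)
  expect_equal(f$C0, 100, tolerance = 1e-6)
  expect_equal(f$lambda, 20, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # log-linear initialization equals the converged fit for noiseless data
  init <- stats::lm(log(y[x >= 8 & x <= 150]) ~ I(x[x >= 8 & x <= 150] - 8))
  expect_equal(exp(unname(coef(init)[1])), f$C0, tolerance = 1e-8)
  expect_equal(-1 / unname(coef(init)[2]), f$lambda, tolerance = 1e-8)
})

test_that("the exponential fit is scale-equivariant", {
  x <- 0:120
  y <- 50 * exp(-x / 15)
  p1 <- gradient_profile(x, y, dv_length = 240)
  p2 <- gradient_profile(x, 7 * y, dv_length = 240)
  f1 <- fit_exponential(p1, boundary = 0)
  f2 <- fit_exponential(p2, boundary = 0)
  expect_equal(f2$C0, 7 * f1$C0, tolerance = 1e-8)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-8)
})

test_that("degenerate fit inputs raise errors", {
  p <- gradient_profile(0:3, c(1, 1, 1, 1), dv_length = 8)
  expect_error(fit_exponential(p, boundary = 0), "at least 5")
})

test_that("amplitude and decay-length trends are ordinary least squares", {
  mkfit <- function(C0, lambda) structure(list(C0 = C0, lambda = lambda),
                                          class = "exp_fit")
  dv <- c(100, 200, 300, 400)
  fits <- lapply(dv, function(d) mkfit(0.5 * d + 3, 20))
  tr <- suppressWarnings(trend_vs_size(fits, dv))  # exact fit warns in summary.lm
  expect_equal(tr$table["C0", "r_squared"], 1, tolerance = 1e-12)
  expect_equal(tr$table["C0", "slope"], 0.5, tolerance = 1e-12)
  # duplicated points leave the fit unchanged
  tr2 <- suppressWarnings(trend_vs_size(c(fits, fits), c(dv, dv)))
  expect_equal(tr2$table["C0", "slope"], tr$table["C0", "slope"])
  expect_error(trend_vs_size(fits[1:2], dv[1:2]), "at least 3")
  expect_error(trend_vs_size(fits, rep(100, 4)), "constant regressor")
})

test_that("lambda is uncorrelated with size at the generator defaults", {
  set.seed(15)
  covered <- replicate(60, {
    co <- generate_cohort(cohort_spec(n_embryos = 20))
    fits <- lapply(lapply(co$profiles, subtract_background), function(p)
      tryCatch(fit_exponential(p), error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    tr <- trend_vs_size(fits[ok], co$truth$dv_length[ok])
    ci <- stats::confint(tr$fits$lambda)["dv_lengths", ]
    ci[1] <= 0 && ci[2] >= 0
  })
  expect_gte(mean(covered), 0.9)
})

test_that("stereotyped time courses recover exact linear inputs", {
  tc <- data.frame(time_h = rep(c(10, 20, 30, 40), 2),
                   band = rep(c("0-10%", "10-20%"), each = 4),
                   intensity = c(3 * c(10, 20, 30, 40) - 12,
                                 1.5 * c(10, 20, 30, 40) - 9))
  st <- stereotype_timecourse(tc)
  expect_equal(st[["0-10%"]]$slope, 3, tolerance = 1e-12)
  expect_equal(st[["0-10%"]]$t_zero, 4, tolerance = 1e-12)
  expect_equal(st[["10-20%"]]$t_zero, 6, tolerance = 1e-12)
  bad <- tc
  bad$intensity[bad$band == "0-10%"] <- rev(bad$intensity[bad$band == "0-10%"])
  expect_error(stereotype_timecourse(bad), "non-positive slope")
})

test_that("the ventral band rises faster than the adjacent band", {
  # rising Shh cohort: amplitude grows with stage, gradient decays dorsally,
  # so the 0-10% band mean grows faster than the 10-20% band mean
  set.seed(16)
  co <- generate_cohort(cohort_spec(n_embryos = 40))
  profs <- lapply(co$profiles, subtract_background)
  b <- bin_profiles(profs)
  ventral <- b[b$position_bin %in% c(0, 1) & b$n >= 2, ]
  tc <- data.frame(time_h = ventral$stage_mid / 4,
                   band = ifelse(ventral$position_bin == 0, "0-10%", "10-20%"),
                   intensity = ventral$mean)
  st <- stereotype_timecourse(tc)
  expect_gt(st[["0-10%"]]$slope, st[["10-20%"]]$slope)
})
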
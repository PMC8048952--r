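test_that("interval extraction produces complete and open-tailed durations", {
  h <- fire_history("px", 2000.25, 2020.08, c(2005, 2010, 2018))
  iv <- extract_intervals(h)
  expect_equal(iv$complete, c(5, 8))
  expect_equal(iv$censored, c(4.75, 2.08), tolerance = 1e-12)
  # single fire at window midpoint
  h1 <- fire_history("px", 2000, 2020, 2010)
  iv1 <- extract_intervals(h1)
  expect_length(iv1$complete, 0)
  expect_equal(iv1$censored, c(10, 10))
  # no fires: fully censored window
  iv0 <- extract_intervals(fire_history("px", 2000, 2020))
  expect_equal(iv0$censored, 20)
  expect_equal(iv0$n_windows, 0L)
  expect_error(fire_history("px", 2000, 2020, 2021), "within")
  expect_error(fire_history("px", 2020, 2000), "precede")
})

test_that("interval accounting conserves total duration", {
  withr::with_seed(4, {
    for (i in 1:20) {
      w <- sort(runif(2, 1990, 2025))
      k <- rpois(1, 4)
      fires <- sort(runif(k, w[1] + 1e-6, w[2] - 1e-6))
      iv <- extract_intervals(fire_history("p", w[1], w[2], fires))
      expect_equal(sum(iv$complete) + sum(iv$censored), w[2] - w[1])
    }
  })
})

test_that("species pooling uses only locations that burnt", {
  hs <- list(
    a = fire_history("a", 2000, 2020, c(2004, 2010)),
    b = fire_history("b", 2000, 2020, c(2001, 2019)),
    c = fire_history("c", 2000, 2020)
  )
  iv <- pool_species_intervals(hs, c("a", "b", "c"))
  expect_length(iv$complete, 2)
  expect_length(iv$censored, 4)
  expect_equal(attr(iv, "n_burnt"), 2L)
  expect_equal(iv$n_windows, 2L)
  # unburnt-only pooling yields an empty, flagged set
  iv0 <- pool_species_intervals(hs, "c")
  expect_length(iv0$complete, 0)
  expect_equal(attr(iv0, "n_burnt"), 0L)
  expect_length(pool_species_intervals(hs, character())$complete, 0)
})

test_that("complete-data Weibull MLE matches grid oracle and survreg", {
  tc <- c(2, 3, 5, 7)
  fit <- fit_weibull_censored(interval_set(tc, numeric()))
  ora <- grid_weibull_oracle(tc)
  expect_equal(fit$b, ora$b, tolerance = 1e-4)
  expect_equal(fit$c, ora$c, tolerance = 1e-4)
  skip_if_not_installed("survival")
  sr <- survival::survreg(survival::Surv(tc, rep(1, 4)) ~ 1, dist = "weibull")
  expect_equal(fit$b, unname(exp(coef(sr))), tolerance = 1e-4)
  expect_equal(fit$c, 1 / sr$scale, tolerance = 1e-4)
})

test_that("censored likelihood matches survreg on open-tailed data", {
  skip_if_not_installed("survival")
  withr::with_seed(8, {
    tc <- rweibull(60, 1.3, 9)
    ts <- runif(30, 0, 15)
  })
  fit <- fit_weibull_censored(interval_set(tc, ts), correction = "none")
  t_all <- c(tc, ts); ev <- rep(1:0, c(60, 30))
  sr <- survival::survreg(survival::Surv(t_all, ev) ~ 1, dist = "weibull")
  expect_equal(fit$b, unname(exp(coef(sr))), tolerance = 1e-5)
  expect_equal(fit$c, 1 / sr$scale, tolerance = 1e-5)
})

test_that("Weibull parameters are recovered from complete samples", {
  withr::with_seed(99, x <- rweibull(5000, shape = 1.4, scale = 8))
  fit <- fit_weibull_censored(interval_set(x, numeric()))
  expect_lt(abs(fit$b / 8 - 1), 0.05)
  expect_lt(abs(fit$c / 1.4 - 1), 0.10)
})

test_that("regular fires give a large shape and median near the spacing", {
  fit <- fit_weibull_censored(interval_set(c(4, 4, 4, 4) + c(-1, 1, -1, 1) * 1e-3,
                                           numeric()))
  expect_gt(fit$c, 50)
  expect_equal(fit$median_fri, 4, tolerance = 1e-2)
})

test_that("all-censored interval sets are flagged non-convergent", {
  fit <- fit_weibull_censored(interval_set(numeric(), c(5, 10, 20)))
  expect_false(fit$converged)
  expect_warning(v <- median_fri(fit), "converge")
  expect_true(is.na(v))
})

test_that("median FRI formula has its closed-form and limit behaviour", {
  expect_equal(weibull_median_fri(10, 1), 10 * log(2))
  expect_lt(abs(weibull_median_fri(7, 1e6) - 7), 1e-4 * 7)
  # Monte-Carlo median oracle
  withr::with_seed(12, mc <- median(rweibull(1e6, shape = 1.3, scale = 8)))
  expect_lt(abs(weibull_median_fri(8, 1.3) / mc - 1), 0.005)
  # strictly increasing in b at fixed c
  b <- seq(1, 30, length.out = 40)
  expect_true(all(diff(weibull_median_fri(b, 1.7)) > 0))
})

test_that("break-point regression recovers a noiseless hinge exactly", {
  x <- seq(0, 1, length.out = 60)
  y <- 120 - 400 * pmin(x, 0.26) - 15 * pmax(x - 0.26, 0)
  fit <- fit_breakpoint(x, y)
  expect_equal(fit$breakpoint, 0.26, tolerance = 1e-6)
  expect_equal(fit$left_slope, -400, tolerance = 1e-6)
  expect_equal(fit$right_slope, -15, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("break-point fit matches the exhaustive grid oracle", {
  withr::with_seed(5, {
    for (rep in 1:3) {
      x <- sort(runif(80))
      psi <- runif(1, 0.3, 0.7)
      y <- 2 + 3 * x - 5 * pmax(x - psi, 0) + rnorm(80, 0, 0.1)
      fit <- fit_breakpoint(x, y)
      ora <- grid_breakpoint_oracle(x, y)
      expect_lte(fit$rss, ora$rss + 1e-8)
    }
  })
})

test_that("break-point estimate is close to truth under noise", {
  withr::with_seed(31, {
    x <- seq(0, 1, length.out = 100)
    y0 <- 10 - 25 * pmin(x, 0.26) - 2 * pmax(x - 0.26, 0)
    y <- y0 + rnorm(100, 0, 0.05 * diff(range(y0)))
  })
  fit <- fit_breakpoint(x, y)
  expect_lt(abs(fit$breakpoint - 0.26), 0.03)
})

test_that("collinear data are flagged degenerate", {
  x <- seq(0, 1, length.out = 30)
  fit <- fit_breakpoint(x, 2 + 5 * x)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$breakpoint))
})

test_that("proportion burned and fire-prone classification follow the threshold", {
  rec <- data.frame(species = rep(c("s1", "s2"), c(50, 4)),
                    location_id = c(sprintf("a%d", 1:50), sprintf("b%d", 1:4)))
  burnt <- stats::setNames(c(seq_len(50) <= 13, c(TRUE, TRUE, TRUE, TRUE)),
                           c(sprintf("a%d", 1:50), sprintf("b%d", 1:4)))
  pb <- proportion_burned(rec, burnt)
  expect_equal(pb$proportion_burned[pb$species == "s1"], 0.26)
  expect_equal(pb$proportion_burned[pb$species == "s2"], 1)
  cls <- classify_fire_prone(data.frame(proportion_burned = c(0.25, 0.26, 0)), 0.26)
  expect_equal(cls$fire_prone, c(FALSE, TRUE, FALSE))
  all_in <- classify_fire_prone(data.frame(proportion_burned = c(0.25, 0)), 0)
  expect_true(all(all_in$fire_prone))
  expect_error(proportion_burned(rec[0, ], burnt), "no records")
})

test_that("FRI bounds exclude unresolvable return intervals", {
  pr <- data.frame(species = c("a", "b", "c", "d"),
                   median_fri = c(101, 1.0, 6.9, 0.5))
  out <- filter_fri_bounds(pr, 1, 100)
  expect_equal(out$fri_excluded, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$median_fri, c(NA, 1.0, 6.9, NA))
})
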
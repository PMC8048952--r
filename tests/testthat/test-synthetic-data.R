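test_that("fire-history generator is seed-deterministic with window-bounded dates", {
  h1 <- simulate_fire_history(8, 1.3, c(2000.25, 2020.08), "p", seed = 5)
  h2 <- simulate_fire_history(8, 1.3, c(2000.25, 2020.08), "p", seed = 5)
  expect_identical(h1, h2)
  expect_true(all(h1$burn_dates >= 2000.25 & h1$burn_dates <= 2020.08))
  # a scale far beyond the window usually yields no fires
  h0 <- simulate_fire_history(5000, 1.2, c(2000, 2020), "p", seed = 1)
  expect_length(h0$burn_dates, 0)
})

test_that("simulated complete intervals match the analytic Weibull mean", {
  # a very long window makes window-truncation of long intervals negligible,
  # exposing the raw renewal moments
  withr::with_seed(2, {
    comp <- unlist(lapply(1:60, function(i) {
      extract_intervals(simulate_fire_history(5, 1.5, c(2000, 3000), "p"))$complete
    }))
  })
  expect_gt(length(comp), 5000)
  expect_lt(abs(mean(comp) / (5 * gamma(1 + 1 / 1.5)) - 1), 0.03)
})

test_that("rainfall generator honours climatology, episodes, and seeds", {
  r <- simulate_rainfall("c1", c(1901, 2010), climatology = rep(80, 12),
                         sdlog = 0, episodes = list())
  expect_true(all(r$rain_mm == 80))
  expect_equal(max(abs(monthly_fdi(r)$fdi), na.rm = TRUE), 0)
  # a fully rainless 12-month episode forces a minimum FDI of -1 downstream
  r2 <- simulate_rainfall("c1", c(1901, 2010), climatology = rep(80, 12),
                          sdlog = 0,
                          episodes = list(list(start_year = 2005, start_month = 1,
                                               length_months = 12, deficit = 1)))
  expect_equal(min(monthly_fdi(r2)$fdi, na.rm = TRUE), -1)
  s1 <- simulate_rainfall("c", c(2000, 2005), sdlog = 0.4, seed = 3)
  s2 <- simulate_rainfall("c", c(2000, 2005), sdlog = 0.4, seed = 3)
  expect_identical(s1, s2)
})

test_that("phylogeny generator returns labelled ultrametric trees", {
  tr <- simulate_phylogeny(3, seed = 4)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(ape::is.ultrametric(tr))
  tr2 <- simulate_phylogeny(25, seed = 4)
  expect_equal(ape::Ntip(tr2), 25)
  expect_false(anyDuplicated(tr2$tip.label) > 0)
  # expected depth grows with tip count at a fixed birth rate
  withr::with_seed(11, {
    d10 <- mean(replicate(60, max(ape::node.depth.edgelength(simulate_phylogeny(10)))))
    d80 <- mean(replicate(60, max(ape::node.depth.edgelength(simulate_phylogeny(80)))))
  })
  expect_gt(d80, d10)
})

test_that("binary-trait generator matches its marginal and dependence claims", {
  tr <- simulate_phylogeny(2000, seed = 31)
  # beta = 0, weak dependence: overall prevalence near one half (under strong
  # dependence single-draw prevalence varies, so average over seeds below)
  y0 <- simulate_binary_trait(tr, matrix(rnorm(2000), ncol = 1), c(0, 0),
                              alpha = 5e4, seed = 32)
  expect_lt(abs(mean(y0) - 0.5), 0.03)
  p_rep <- vapply(1:10, function(s)
    mean(simulate_binary_trait(tr, matrix(0, 2000, 1), c(0, 0),
                               alpha = 1, seed = 100 + s)), numeric(1))
  expect_lt(abs(mean(p_rep) - 0.5), 0.05)
  # huge alpha: neighbouring tips effectively independent
  yi <- simulate_binary_trait(tr, matrix(0, 2000, 1), c(0, 0),
                              alpha = 5e4, seed = 33)
  S <- ape::vcv(tr); S <- S / max(S)
  near <- which(S > 0.8 & upper.tri(S), arr.ind = TRUE)
  expect_gt(nrow(near), 100)
  expect_lt(abs(cor(yi[near[, 1]], yi[near[, 2]])), 0.05)
  # small alpha: closely related tips strongly associated
  ys <- simulate_binary_trait(tr, matrix(0, 2000, 1), c(0, 0),
                              alpha = 0.2, seed = 34)
  expect_gt(cor(ys[near[, 1]], ys[near[, 2]]), 0.3)
  # a strong slope leaves its sign in the empirical logit
  x <- rnorm(2000)
  yb <- simulate_binary_trait(tr, cbind(x), c(0, 1.5), alpha = 5, seed = 35)
  expect_gt(coef(glm(yb ~ x, family = binomial))["x"], 0.5)
})

test_that("benchmark bundle is deterministic and internally consistent", {
  cfg <- simulation_config(seed = 7, n_species = 12, n_locations = 25,
                           n_rain_cells = 6)
  b1 <- make_benchmark_bundle(cfg)
  b2 <- make_benchmark_bundle(cfg)
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$occurrences, b2$occurrences)
  # manifest FRI obeys the median formula
  expect_equal(b1$manifest$true_median_fri,
               weibull_median_fri(b1$manifest$b, b1$manifest$c))
  # all burn dates inside the window; all tips match manifest species
  expect_true(all(b1$burns$burn_date >= cfg$window[1] &
                    b1$burns$burn_date <= cfg$window[2]))
  expect_setequal(b1$tree$tip.label, b1$manifest$species)
  expect_true(all(b1$rainfall$rain_mm >= 0))
  expect_true(all(b1$traits$strategy %in% c(0L, 1L)))
  # injected pre-1980 records are all removed by the default QC settings
  yrs <- as.integer(substr(b1$occurrences$date, 1, 4))
  expect_gt(sum(yrs < 1980), 0)
  cleaned <- clean_occurrences(b1$occurrences, min_unique = 10)$records
  expect_true(all(as.integer(substr(cleaned$date, 1, 4)) >= 1980))
  expect_true(all(!is.na(cleaned$hii) & (cleaned$hii <= 30 | cleaned$protected)))
})

test_that("bundle files round-trip through the writers", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 3, n_species = 8, n_locations = 12,
                           n_rain_cells = 4)
  b <- make_benchmark_bundle(cfg, dir = dir)
  expect_true(all(file.exists(unlist(b$paths))))
  occ <- read_occurrences(b$paths$occurrences)
  expect_equal(nrow(occ), nrow(b$occurrences))
  tr <- ape::read.tree(b$paths$tree)
  expect_setequal(tr$tip.label, b$tree$tip.label)
  hs <- read_fire_histories(b$paths$burns, cfg$window[1], cfg$window[2],
                            all_locations = b$mapping$location_id)
  expect_length(hs, nrow(b$mapping))
  one <- b$histories[[names(hs)[1]]]
  expect_equal(hs[[names(hs)[1]]]$burn_dates, one$burn_dates, tolerance = 1e-9)
})
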
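# Independent oracles used to validate the package's estimators. These are
# deliberately naive (grid searches, direct formulas) and share no code with
# the implementation under test.

# brute-force nested grid maximization of the censored Weibull likelihood
# (optionally with the window-sampling conditioning term)
grid_weibull_oracle <- function(complete, censored = numeric(),
                                n_windows = 0, window = NA,
                                n_refine = 5, n_grid = 41) {
  ll <- function(b, cc) {
    out <- sum(stats::dweibull(complete, shape = cc, scale = b, log = TRUE))
    if (length(censored)) out <- out - sum((censored / b)^cc)
    if (n_windows > 0) {
      iw <- stats::integrate(function(u) exp(-(u / b)^cc), 0, window,
                             rel.tol = 1e-12)$value
      out <- out - n_windows * log(iw)
    }
    out
  }
  lb <- log(c(0.2 * mean(c(complete, censored)), 8 * mean(c(complete, censored))))
  lc <- log(c(0.1, 12))
  for (r in seq_len(n_refine)) {
    bs <- exp(seq(lb[1], lb[2], length.out = n_grid))
    cs <- exp(seq(lc[1], lc[2], length.out = n_grid))
    val <- outer(bs, cs, Vectorize(ll))
    ij <- arrayInd(which.max(val), dim(val))
    db <- (lb[2] - lb[1]) / (n_grid - 1)
    dc <- (lc[2] - lc[1]) / (n_grid - 1)
    lb <- log(bs[ij[1]]) + c(-db, db)
    lc <- log(cs[ij[2]]) + c(-dc, dc)
  }
  list(b = bs[ij[1]], c = cs[ij[2]], loglik = val[ij])
}

# exhaustive grid search for the two-segment regression RSS
grid_breakpoint_oracle <- function(x, y, n_grid = 4001) {
  cand <- seq(sort(x)[2], sort(x)[length(x) - 1], length.out = n_grid)
  rss <- vapply(cand, function(psi) {
    f <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)
    sum(f$residuals^2)
  }, numeric(1))
  list(breakpoint = cand[which.min(rss)], rss = min(rss))
}

# Firth-penalized logistic regression by direct optimization of the
# penalized likelihood l(beta) + 0.5 log det(X' W X)
firth_logistic_oracle <- function(X, y) {
  obj <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    -(sum(y * log(mu) + (1 - y) * log(1 - mu)) +
        0.5 * determinant(crossprod(X, X * W))$modulus)
  }
  o <- stats::optim(rep(0, ncol(X)), obj, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 1000))
  o$par
}

# direct matrix-algebra GLS: (X' C^-1 X)^-1 X' C^-1 y
gls_oracle <- function(X, y, C) {
  Ci <- solve(C)
  drop(solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y))
}

# spreadsheet-style rolling-sum drought index
rolling_fdi_oracle <- function(rain_mm, map, window = 36) {
  n <- length(rain_mm)
  out <- rep(NA_real_, n)
  for (m in seq_len(n)) if (m >= window)
    out[m] <- (sum(rain_mm[(m - window + 1):m]) - (window / 12) * map) / map
  out
}

# sort-and-interpolate quantile at position 1 + (n-1) q
interp_quantile_oracle <- function(x, q) {
  s <- sort(x)
  pos <- 1 + (length(s) - 1) * q
  lo <- floor(pos); hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# small occurrence-table builder for QC tests
make_occ <- function(species, lon, lat, date = "2005-06-15", hii = 0,
                     protected = FALSE, lon_txt = NULL, lat_txt = NULL) {
  n <- max(length(species), length(lon), length(lat), length(date))
  df <- data.frame(species = rep_len(species, n), lon = rep_len(lon, n),
                   lat = rep_len(lat, n), date = rep_len(date, n),
                   hii = rep_len(hii, n), protected = rep_len(protected, n),
                   stringsAsFactors = FALSE)
  df$lon_txt <- if (is.null(lon_txt)) as.character(df$lon) else rep_len(lon_txt, n)
  df$lat_txt <- if (is.null(lat_txt)) as.character(df$lat) else rep_len(lat_txt, n)
  df
}

# random occurrence fixture with known amounts of each defect
random_occ_fixture <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    df <- make_occ(
      species = sample(sprintf("sp%02d", 1:6), n, TRUE),
      lon = round(runif(n, -170, 170), 4),
      lat = round(runif(n, -60, 60), 4),
      date = sprintf("%d-0%d-1%d", sample(1950:2019, n, TRUE),
                     sample(1:9, n, TRUE), sample(0:9, n, TRUE)),
      hii = sample(c(NA, 0:60), n, TRUE),
      protected = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8)))
    df$lon_txt <- as.character(df$lon)
    df$lat_txt <- as.character(df$lat)
    df
  })
}
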
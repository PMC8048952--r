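#' Two-segment (break-point) linear regression
#'
#' Fits a continuous piecewise-linear model
#' \eqn{y = a + b_1 x + b_2 (x - \psi)_+} by least squares, estimating the
#' hinge \eqn{\psi} by a dense grid search over the interior of the x-range
#' refined by golden-section optimization of the profile RSS. Used to locate
#' the break in the species-count-versus-proportion-burned curve that
#' separates fire-prone from rarely burnt species.
#'
#' @param x,y numeric vectors, `length >= 6`; `x` should be sorted (it is
#'   sorted internally).
#' @param n_grid number of grid candidates for the hinge (default 201).
#' @return object of class `breakpoint_fit`: `breakpoint`, `left_slope`,
#'   `right_slope`, `intercept` (left-segment intercept), `rss`, `degenerate`
#'   flag. Collinear data (no break improves on a single line) give
#'   `breakpoint = NA` and `degenerate = TRUE`.
#' @examples
#' x <- seq(0, 1, length.out = 50)
#' y <- 10 - 30 * pmin(x, 0.26) - 2 * pmax(x - 0.26, 0)
#' fit_breakpoint(x, y + 10 * 0.26 * 30)$breakpoint
#' @export
fit_breakpoint <- function(x, y, n_grid = 201) {
  stopifnot(length(x) == length(y), length(x) >= 6)
  o <- order(x); x <- as.numeric(x[o]); y <- as.numeric(y[o])
  if (diff(range(x)) <= 0) stop("x has zero range")

  rss_at <- function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  # interior candidates only: the hinge must be strictly inside the x-range
  lo <- x[2]; hi <- x[length(x) - 1]
  if (lo >= hi) { lo <- min(x) + 1e-9 * diff(range(x)); hi <- max(x) - 1e-9 * diff(range(x)) }
  grid <- unique(sort(c(seq(lo, hi, length.out = n_grid),
                        x[x > lo & x < hi])))
  rss <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- stats::optimize(rss_at, interval = bracket, tol = 1e-10)
  psi <- if (opt$objective <= rss[i]) opt$minimum else grid[i]
  best_rss <- min(opt$objective, rss[i])

  lin <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(lin$residuals^2)
  tss <- sum((y - mean(y))^2)
  degenerate <- (tss < 1e-24) || (rss_lin - best_rss <= 1e-10 * max(tss, 1e-24))

  cf <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)$coefficients
  structure(list(
    breakpoint = if (degenerate) NA_real_ else psi,
    left_slope = unname(cf[2]),
    right_slope = unname(cf[2] + cf[3]),
    intercept = unname(cf[1]),
    rss = best_rss,
    degenerate = degenerate), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$degenerate) cat("<breakpoint_fit> degenerate (no break point)\n")
  else cat(sprintf("<breakpoint_fit> break at %.4f; slopes %.3f -> %.3f; RSS %.4g\n",
                   x$breakpoint, x$left_slope, x$right_slope, x$rss))
  invisible(x)
}

#' Proportion of a species' records lying in burnt pixels
#'
#' @param records data.frame with columns `species`, `location_id` (one row
#'   per occurrence record).
#' @param burnt_lookup named logical vector: `TRUE` if the location burnt at
#'   least once during the observation window. Every record must be mappable.
#' @return data.frame `(species, n_records, n_burnt, proportion_burned)`.
#' @export
proportion_burned <- function(records, burnt_lookup) {
  stopifnot(all(c("species", "location_id") %in% names(records)))
  if (nrow(records) == 0) stop("proportion_burned: no records")
  loc <- as.character(records$location_id)
  miss <- setdiff(unique(loc), names(burnt_lookup))
  if (length(miss))
    stop("records at locations with no burnt/unburnt flag: ",
         paste(utils::head(miss, 5), collapse = ", "))
  burnt <- as.logical(burnt_lookup[loc])
  agg <- stats::aggregate(burnt, by = list(species = records$species),
                          FUN = function(v) c(n = length(v), b = sum(v)))
  data.frame(species = agg$species,
             n_records = agg$x[, "n"],
             n_burnt = agg$x[, "b"],
             proportion_burned = agg$x[, "b"] / agg$x[, "n"],
             stringsAsFactors = FALSE)
}

#' Species-count curve over proportion-burned bins
#'
#' Histogram of species per proportion-burned bin — the curve to which the
#' break-point regression is fitted to derive the fire-prone threshold.
#'
#' @param proportions per-species proportion burned, in \[0, 1\].
#' @param bin_width bin width (default 0.02).
#' @return data.frame `(proportion, n_species)` with bin midpoints.
#' @export
species_count_curve <- function(proportions, bin_width = 0.02) {
  stopifnot(all(proportions >= 0 & proportions <= 1))
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  h <- graphics::hist(proportions, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(proportion = h$mids, n_species = h$counts)
}

#' Derive the fire-prone threshold from the proportion-burned distribution
#'
#' Fits [fit_breakpoint()] to the [species_count_curve()] and returns the
#' estimated hinge. The histogram is informative only when many species fill
#' the bins (the calibration behind the reference value 0.26 used a pool of
#' thousands of species); with fewer than `min_species` species, or when the
#' curve is degenerate, the calibrated `fallback` is returned instead.
#'
#' @param proportions per-species proportion burned.
#' @param bin_width histogram bin width.
#' @param fallback threshold used when the break point cannot be estimated
#'   (default 0.26, the reference calibration).
#' @param min_species minimum pool size for estimating the break point
#'   (default 200).
#' @return threshold in (0, 1) with attribute `"fit"` (the breakpoint fit or
#'   `NULL`).
#' @export
fire_prone_threshold <- function(proportions, bin_width = 0.02, fallback = 0.26,
                                 min_species = 200) {
  curve <- species_count_curve(proportions, bin_width)
  if (length(proportions) < min_species || nrow(curve) < 6 ||
      stats::var(curve$n_species) == 0)
    return(structure(fallback, fit = NULL))
  fit <- fit_breakpoint(curve$proportion, curve$n_species)
  if (fit$degenerate || is.na(fit$breakpoint) ||
      fit$breakpoint <= 0 || fit$breakpoint >= 1)
    return(structure(fallback, fit = fit))
  structure(fit$breakpoint, fit = fit)
}

#' Flag fire-prone species
#'
#' A species is fire-prone when the proportion of its records in burnt pixels
#' reaches the threshold; species below it are excluded from fire-frequency
#' analyses (exclusion is strict `<`).
#'
#' @param profiles data.frame with a `proportion_burned` column.
#' @param threshold proportion threshold in (0, 1).
#' @return `profiles` with a logical `fire_prone` column.
#' @export
classify_fire_prone <- function(profiles, threshold = 0.26) {
  stopifnot(threshold >= 0, threshold < 1,
            "proportion_burned" %in% names(profiles))
  profiles$fire_prone <- profiles$proportion_burned >= threshold
  profiles
}

#' Exclude unresolvable fire return intervals
#'
#' A 20-year observation window cannot resolve very long or sub-annual fire
#' return intervals; species whose fitted median FRI falls outside
#' `[lo, hi]` have it set to `NA` and are flagged excluded.
#'
#' @param profiles data.frame with a `median_fri` column.
#' @param lo,hi retained FRI range in years (defaults 1 and 100, inclusive).
#' @return `profiles` with `fri_excluded` flag and out-of-bounds `median_fri`
#'   set `NA`.
#' @export
filter_fri_bounds <- function(profiles, lo = 1, hi = 100) {
  stopifnot("median_fri" %in% names(profiles), lo < hi)
  out <- !is.na(profiles$median_fri) &
    (profiles$median_fri < lo | profiles$median_fri > hi)
  profiles$fri_excluded <- out
  profiles$median_fri[out] <- NA_real_
  profiles
}
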
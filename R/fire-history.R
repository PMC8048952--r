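#' Burn history of one location inside a fixed observation window
#'
#' Satellite burned-area products observe each location only inside a fixed
#' window (the MODIS burned-area record runs from April 2000 to January
#' 2020), so the interval before the first fire and after the last fire is
#' truncated ("open tailed"). Times are fractional years (see
#' [date_to_year()]).
#'
#' @param location_id identifier for the pixel/location.
#' @param window_start,window_end observation window; dates or fractional
#'   years, `window_start < window_end`.
#' @param burn_dates dates (or fractional years) of observed fires; must lie
#'   inside the window. Need not be sorted.
#' @return object of class `fire_history`.
#' @examples
#' fire_history("px1", 2000.25, 2020.08, c(2005, 2010, 2018))
#' @export
fire_history <- function(location_id, window_start, window_end, burn_dates = numeric()) {
  ws <- date_to_year(window_start)
  we <- date_to_year(window_end)
  bd <- sort(date_to_year(burn_dates))
  if (!is.finite(ws) || !is.finite(we) || ws >= we)
    stop("window_start must precede window_end")
  if (length(bd) && (any(!is.finite(bd)) || any(bd < ws) || any(bd > we)))
    stop("burn dates must lie within the observation window")
  if (any(duplicated(bd))) bd <- unique(bd)
  structure(list(location_id = location_id, window_start = ws,
                 window_end = we, burn_dates = bd),
            class = "fire_history")
}

#' @export
print.fire_history <- function(x, ...) {
  cat(sprintf("<fire_history> %s: %d fires in [%.2f, %.2f]\n",
              x$location_id, length(x$burn_dates), x$window_start, x$window_end))
  invisible(x)
}

#' Read burn histories from a long CSV
#'
#' Expects columns `location_id, burn_date`; every location appearing in the
#' file gets a history. Locations known to be unburnt can be added through
#' `all_locations`.
#'
#' @param path CSV path.
#' @param window_start,window_end observation window applied to all locations.
#' @param all_locations optional character vector of location ids; ids with no
#'   rows in the file become zero-fire histories.
#' @return named list of [fire_history()] objects.
#' @export
read_fire_histories <- function(path, window_start, window_end, all_locations = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("location_id", "burn_date") %in% names(df)))
  ids <- unique(c(as.character(df$location_id), as.character(all_locations)))
  by_loc <- split(df$burn_date, factor(as.character(df$location_id), levels = ids))
  out <- lapply(ids, function(id)
    fire_history(id, window_start, window_end, by_loc[[id]] %||% numeric()))
  names(out) <- ids
  out
}

#' Extract complete and open-tailed inter-fire intervals
#'
#' A history with `k >= 1` fires yields `k - 1` complete intervals (between
#' successive fires) and two open-tailed intervals (window start to first
#' fire; last fire to window end), the latter treated as right-censored
#' observations of the interval distribution. A zero-fire history yields a
#' single censored interval equal to the window length. Total duration is
#' conserved: complete + censored intervals sum to the window length
#' (zero-length tails from a fire exactly at a window edge are dropped).
#'
#' @param history a [fire_history()].
#' @return object of class `interval_set`: list with numeric `complete` and
#'   `censored` (years).
#' @export
extract_intervals <- function(history) {
  stopifnot(inherits(history, "fire_history"))
  bd <- history$burn_dates
  w <- history$window_end - history$window_start
  if (length(bd) == 0) {
    return(interval_set(numeric(), w, n_windows = 0L, window_length = w))
  }
  complete <- diff(bd)
  censored <- c(bd[1] - history$window_start, history$window_end - bd[length(bd)])
  interval_set(complete[complete > 0], censored[censored > 0],
               n_windows = 1L, window_length = w)
}

#' Construct an interval set
#'
#' @param complete numeric vector of fully observed inter-fire durations (yr).
#' @param censored numeric vector of right-censored (open-tailed) durations (yr).
#' @param n_windows number of burnt observation windows the intervals came
#'   from (used by the stationarity correction in [fit_weibull_censored()];
#'   `NA` for interval data of unknown sampling design).
#' @param window_length common observation-window length in years (`NA` if
#'   unknown).
#' @return object of class `interval_set`.
#' @export
interval_set <- function(complete = numeric(), censored = numeric(),
                         n_windows = NA_integer_, window_length = NA_real_) {
  stopifnot(all(complete > 0), all(censored > 0))
  structure(list(complete = as.numeric(complete), censored = as.numeric(censored),
                 n_windows = as.integer(n_windows),
                 window_length = as.numeric(window_length)),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d complete, %d censored interval(s)\n",
              length(x$complete), length(x$censored)))
  invisible(x)
}

#' Pool inter-fire intervals across a species' burnt locations
#'
#' Unions the interval sets of the listed locations, excluding locations that
#' never burnt during the window (their single fully censored interval says
#' only that the local return interval exceeds the window and they are not
#' used in the fit). Every interval counts once (unweighted pooling).
#'
#' @param histories named list of [fire_history()] objects.
#' @param locations character vector of location ids for one species.
#' @return an [interval_set()] with attributes `n_locations` (ids found) and
#'   `n_burnt` (locations contributing). A species with no burnt locations
#'   yields an empty set.
#' @export
pool_species_intervals <- function(histories, locations) {
  locations <- intersect(as.character(locations), names(histories))
  comp <- list(); cens <- list(); n_burnt <- 0L; wlen <- NA_real_
  for (id in locations) {
    h <- histories[[id]]
    if (length(h$burn_dates) == 0) next
    iv <- extract_intervals(h)
    comp[[id]] <- iv$complete
    cens[[id]] <- iv$censored
    n_burnt <- n_burnt + 1L
    wlen <- if (is.na(wlen) || abs(wlen - iv$window_length) < 1e-9)
      iv$window_length else NaN   # mixed window lengths: no correction possible
  }
  if (is.nan(wlen)) wlen <- NA_real_
  out <- interval_set(unlist(comp, use.names = FALSE) %||% numeric(),
                      unlist(cens, use.names = FALSE) %||% numeric(),
                      n_windows = n_burnt, window_length = wlen)
  attr(out, "n_locations") <- length(locations)
  attr(out, "n_burnt") <- n_burnt
  out
}

#' Per-species interval sets from a record-to-location mapping
#'
#' @param histories named list of [fire_history()] objects.
#' @param mapping data.frame with columns `species`, `location_id` (one row
#'   per record; duplicate locations contribute their intervals once per
#'   species, not once per record).
#' @return named list of [interval_set()]s, one per species.
#' @export
species_interval_sets <- function(histories, mapping) {
  stopifnot(all(c("species", "location_id") %in% names(mapping)))
  # pre-extract every location's intervals once, then pool by species
  ivs <- lapply(histories, extract_intervals)
  comp <- lapply(ivs, `[[`, "complete")
  cens <- lapply(ivs, `[[`, "censored")
  burnt <- vapply(ivs, function(x) x$n_windows > 0, logical(1))
  wlen <- vapply(ivs, `[[`, numeric(1), "window_length")
  locs <- lapply(split(as.character(mapping$location_id), mapping$species), unique)
  lapply(locs, function(l) {
    l <- l[l %in% names(histories)]
    lb <- l[burnt[l]]
    out <- interval_set(unlist(comp[lb], use.names = FALSE) %||% numeric(),
                        unlist(cens[lb], use.names = FALSE) %||% numeric(),
                        n_windows = length(lb),
                        window_length = if (length(lb)) wlen[lb[1]] else NA_real_)
    attr(out, "n_locations") <- length(l)
    attr(out, "n_burnt") <- length(lb)
    out
  })
}
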
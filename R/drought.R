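#' Foley's drought index from monthly rainfall
#'
#' Foley's drought index (FDI) measures multi-year rainfall deficit on a
#' scale comparable across rainfall zones: for each month it takes the actual
#' rainfall accumulated over the three years ending at (and including) that
#' month, subtracts the expected rainfall for such a period, and divides by
#' the long-term mean annual precipitation (MAP),
#' \deqn{FDI(m) = \frac{\sum_{k=m-35}^{m} P_k - 3\,MAP}{MAP}.}
#' MAP is computed over a fixed baseline period (default 1901-2003). More
#' negative values are more extreme droughts; a series at its climatology has
#' FDI identically 0, and a totally rainless year inside the window at an
#' otherwise constant climatology gives FDI = -1.
#'
#' @param rain data.frame with columns `location_id`, `year`, `month`,
#'   `rain_mm` (monthly totals, `>= 0`), months contiguous within location.
#' @param baseline optional data.frame in the same layout used only for MAP;
#'   by default MAP is computed from `rain` restricted to the baseline years.
#' @param baseline_start,baseline_end baseline period for MAP (defaults 1901
#'   and 2003, inclusive).
#' @param window_months accumulation window (default 36).
#' @return data.frame `(location_id, year, month, fdi)`; months with fewer
#'   than `window_months` months of history (or spanning a gap) get `NA`.
#' @export
monthly_fdi <- function(rain, baseline = NULL,
                        baseline_start = 1901, baseline_end = 2003,
                        window_months = 36) {
  stopifnot(all(c("location_id", "year", "month", "rain_mm") %in% names(rain)),
            window_months >= 1)
  if (any(rain$rain_mm < 0, na.rm = TRUE)) stop("negative monthly rainfall")
  base <- baseline %||% rain
  out <- lapply(split(rain, as.character(rain$location_id)), function(d) {
    d <- d[order(d$year, d$month), , drop = FALSE]
    idx <- d$year * 12L + (d$month - 1L)
    if (any(diff(idx) != 1L)) stop("months are not contiguous for location ",
                                   d$location_id[1])
    bl <- base[as.character(base$location_id) == as.character(d$location_id[1]) &
                 base$year >= baseline_start & base$year <= baseline_end, ,
               drop = FALSE]
    if (nrow(bl) == 0)
      stop("no baseline months for location ", d$location_id[1])
    map <- 12 * mean(bl$rain_mm)
    if (map <= 0) stop("baseline MAP is zero for location ", d$location_id[1])
    cs <- cumsum(c(0, d$rain_mm))
    n <- nrow(d)
    fdi <- rep(NA_real_, n)
    if (n >= window_months) {
      i <- window_months:n
      roll <- cs[i + 1] - cs[i + 1 - window_months]
      fdi[i] <- (roll - (window_months / 12) * map) / map
    }
    data.frame(location_id = d$location_id, year = d$year, month = d$month,
               fdi = fdi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Species mean drought index
#'
#' Averages the monthly FDI series over every record of a species: each
#' record contributes its location's full series, so locations holding
#' several records count once per record.
#'
#' @param records data.frame `(species, location_id)`, one row per record.
#' @param fdi data.frame from [monthly_fdi()].
#' @return data.frame `(species, mean_fdi, n_records)`; species with no
#'   mappable records get `NA` with a warning.
#' @export
species_mean_fdi <- function(records, fdi) {
  stopifnot(all(c("species", "location_id") %in% names(records)))
  series <- split(fdi$fdi, as.character(fdi$location_id))
  sp_locs <- split(as.character(records$location_id), records$species)
  rows <- lapply(names(sp_locs), function(sp) {
    locs <- sp_locs[[sp]]
    v <- unlist(series[locs[locs %in% names(series)]], use.names = FALSE)
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning("species ", sp, " has no mappable FDI months")
      return(data.frame(species = sp, mean_fdi = NA_real_,
                        n_records = length(locs), stringsAsFactors = FALSE))
    }
    data.frame(species = sp, mean_fdi = mean(v), n_records = length(locs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
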
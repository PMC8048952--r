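#' Occurrence-record quality control
#'
#' Cleaning filters applied to georeferenced, dated occurrence records before
#' any fire-regime statistic is computed. Each filter takes and returns an
#' occurrence table: a data.frame with columns `species`, `lon`, `lat`,
#' `date`, and optionally `hii` (human-influence index score), `protected`
#' (logical), and `lon_txt`/`lat_txt` carrying the source text of the
#' coordinates (used to judge stated decimal precision). All filters are
#' idempotent and each step of [clean_occurrences()] records its attrition.
#'
#' @name occurrence_qc
NULL

#' Read an occurrence table from CSV
#'
#' Reads `species, lon, lat, date[, hii, protected]`, preserving the textual
#' representation of the coordinates in `lon_txt`/`lat_txt` so that stated
#' decimal precision can be checked by [filter_precision()].
#'
#' @param path CSV file with a header.
#' @return occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("species", "lon", "lat", "date")
  if (!all(need %in% names(raw)))
    stop("occurrence CSV must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    species = raw$species,
    lon = suppressWarnings(as.numeric(raw$lon)),
    lat = suppressWarnings(as.numeric(raw$lat)),
    date = raw$date,
    lon_txt = raw$lon,
    lat_txt = raw$lat,
    stringsAsFactors = FALSE
  )
  out$hii <- if ("hii" %in% names(raw)) suppressWarnings(as.numeric(raw$hii)) else NA_real_
  out$protected <- if ("protected" %in% names(raw))
    tolower(raw$protected) %in% c("true", "t", "1", "yes") else FALSE
  if ("location_id" %in% names(raw)) out$location_id <- raw$location_id
  out
}

#' Remove invalid coordinates and exact duplicates
#'
#' Drops records with non-numeric or out-of-range coordinates
#' (lon outside \[-180, 180\], lat outside \[-90, 90\]), the (0, 0) sea-origin
#' artefact, and exact duplicates of the (species, lon, lat, date) tuple.
#' A terrestriality check runs only when a land mask is supplied.
#'
#' @param records occurrence data.frame.
#' @param land_mask optional `function(lon, lat)` returning logical "on land";
#'   records returning `FALSE` are dropped.
#' @return filtered records.
#' @export
filter_coordinates <- function(records, land_mask = NULL) {
  if (nrow(records) == 0) {
    warning("filter_coordinates: empty input")
    return(records)
  }
  ok <- is.finite(records$lon) & is.finite(records$lat) &
    records$lon >= -180 & records$lon <= 180 &
    records$lat >= -90 & records$lat <= 90 &
    !(records$lon == 0 & records$lat == 0)
  records <- records[ok, , drop = FALSE]
  if (!is.null(land_mask) && nrow(records) > 0)
    records <- records[land_mask(records$lon, records$lat) %in% TRUE, , drop = FALSE]
  key <- paste(records$species, records$lon, records$lat, records$date, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

# decimal places stated by a coordinate's textual representation
.stated_decimals <- function(txt) {
  txt <- sub("^[-−+]", "", trimws(txt))
  has <- grepl(".", txt, fixed = TRUE)
  n <- integer(length(txt))
  n[has] <- nchar(sub("^[^.]*\\.", "", txt[has]))
  n
}

#' Remove coordinates stated to fewer than `min_decimals` decimal places
#'
#' Fire regimes turn over at small spatial scales, so coarse coordinates are
#' discarded. Precision is judged on the source text (`lon_txt`/`lat_txt`)
#' when available; otherwise a numeric surrogate is used: a value is treated
#' as having at least `d` decimals when it differs from its own value rounded
#' to `d - 1` decimals by more than 1e-12.
#'
#' @param records occurrence data.frame.
#' @param min_decimals minimum stated decimal places for both lon and lat
#'   (default 3); `0` retains everything.
#' @return filtered records.
#' @export
filter_precision <- function(records, min_decimals = 3) {
  stopifnot(min_decimals >= 0)
  if (min_decimals == 0 || nrow(records) == 0) return(records)
  prec_ok <- function(num, txt) {
    if (!is.null(txt)) .stated_decimals(txt) >= min_decimals
    else abs(num - round(num, min_decimals - 1)) > 1e-12
  }
  ok <- prec_ok(records$lon, records$lon_txt) & prec_ok(records$lat, records$lat_txt)
  records[ok, , drop = FALSE]
}

#' Remove records from highly transformed landscapes
#'
#' Records with a human-influence index above `hii_max` come from landscapes
#' whose fire regime is altered and are excluded — unless the record lies in a
#' protected area, which is kept regardless of its score. Records with a
#' missing score that are not protected are removed (conservative).
#'
#' @param records occurrence data.frame with `hii` and `protected`.
#' @param hii_max exclusion threshold, strict `>` (default 30).
#' @return filtered records.
#' @export
filter_human_influence <- function(records, hii_max = 30) {
  if (nrow(records) == 0) return(records)
  prot <- records$protected %in% TRUE
  keep <- prot | (!is.na(records$hii) & records$hii <= hii_max)
  records[keep, , drop = FALSE]
}

#' Remove records predating the satellite fire record
#'
#' @param records occurrence data.frame.
#' @param min_year earliest retained year (default 1980). Records with
#'   unparseable dates are removed.
#' @return filtered records.
#' @export
filter_date <- function(records, min_year = 1980) {
  if (nrow(records) == 0) return(records)
  yr <- year_of(records$date)
  records[!is.na(yr) & yr >= min_year, , drop = FALSE]
}

#' Drop sparsely sampled species
#'
#' A species is retained only if it is represented by at least `min_unique`
#' distinct coordinate points (unique (lon, lat) pairs; repeated visits to one
#' point count once).
#'
#' @param records occurrence data.frame.
#' @param min_unique minimum distinct points per species (default 50).
#' @return filtered records.
#' @export
filter_min_sampling <- function(records, min_unique = 50) {
  if (nrow(records) == 0) return(records)
  pts <- unique(records[, c("species", "lon", "lat")])
  n <- table(pts$species)
  keep_sp <- names(n)[n >= min_unique]
  records[records$species %in% keep_sp, , drop = FALSE]
}

#' Spatially thin records on an equal-area grid
#'
#' Retains at most `max_per_cell` records per species in each grid cell,
#' selected uniformly at random under `seed`. Used for the spatial-bias
#' sensitivity check, not the main pipeline. Cells are squares of area
#' `cell_km2` on a locally equal-area projection (longitude scaled by
#' cos(latitude)).
#'
#' @param records occurrence data.frame.
#' @param cell_km2 cell area in km^2 (default 10).
#' @param max_per_cell records kept per species per cell (default 3).
#' @param seed RNG seed for the random subsample.
#' @return thinned records.
#' @export
spatial_thin <- function(records, cell_km2 = 10, max_per_cell = 3, seed = 1L) {
  if (nrow(records) == 0) return(records)
  edge <- sqrt(cell_km2)                       # km
  km_per_deg <- 111.32
  x <- records$lon * cos(records$lat * pi / 180) * km_per_deg
  y <- records$lat * km_per_deg
  cell <- paste(records$species, floor(x / edge), floor(y / edge), sep = "\r")
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(records)), cell), function(idx) {
      if (length(idx) <= max_per_cell) idx else sort(sample(idx, max_per_cell))
    }), use.names = FALSE)
  })
  records[sort(keep), , drop = FALSE]
}

#' Run the full occurrence-cleaning pipeline with an attrition report
#'
#' Applies, in order: coordinate validity/dedup, stated decimal precision,
#' human-influence exclusion with protected-area exemption, date floor, and
#' minimum per-species sampling. Optionally finishes with spatial thinning
#' (off by default; thinning is a sensitivity check).
#'
#' @param records occurrence data.frame (see [read_occurrences()]).
#' @param min_decimals,hii_max,min_year,min_unique filter parameters; defaults
#'   3, 30, 1980, 50.
#' @param thin apply [spatial_thin()] as a final step (default `FALSE`).
#' @param cell_km2,max_per_cell,seed thinning parameters.
#' @param land_mask optional terrestriality predicate for [filter_coordinates()].
#' @return list with `records` (cleaned table) and `report`, a data.frame of
#'   `(step, records_in, records_out, species)` satisfying
#'   `records_out[k] == records_in[k + 1]`.
#' @export
clean_occurrences <- function(records, min_decimals = 3, hii_max = 30,
                              min_year = 1980, min_unique = 50,
                              thin = FALSE, cell_km2 = 10, max_per_cell = 3,
                              seed = 1L, land_mask = NULL) {
  steps <- list(
    coordinates = function(r) filter_coordinates(r, land_mask = land_mask),
    precision = function(r) filter_precision(r, min_decimals),
    human_influence = function(r) filter_human_influence(r, hii_max),
    date = function(r) filter_date(r, min_year),
    min_sampling = function(r) filter_min_sampling(r, min_unique)
  )
  if (thin)
    steps$spatial_thin <- function(r) spatial_thin(r, cell_km2, max_per_cell, seed)
  rep <- data.frame(step = character(), records_in = integer(),
                    records_out = integer(), species = integer(),
                    stringsAsFactors = FALSE)
  for (nm in names(steps)) {
    n_in <- nrow(records)
    records <- steps[[nm]](records)
    rep <- rbind(rep, data.frame(step = nm, records_in = n_in,
                                 records_out = nrow(records),
                                 species = length(unique(records$species)),
                                 stringsAsFactors = FALSE))
  }
  list(records = records, report = rep)
}
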
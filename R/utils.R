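#' Convert calendar dates to fractional years
#'
#' Burn histories and occurrence dates are handled internally on a continuous
#' fractional-year scale, with the day of year mapped to `year + (yday - 1)/365.25`.
#'
#' @param x a `Date` vector, or character parseable as ISO-8601 dates, or a
#'   numeric vector already on the fractional-year scale (returned unchanged).
#' @return numeric vector of fractional years; unparseable dates become `NA`.
#' @examples
#' date_to_year(as.Date("2000-04-01"))
#' @export
date_to_year <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  d <- if (inherits(x, "Date")) x else as.Date(as.character(x), format = "%Y-%m-%d")
  yr <- as.integer(format(d, "%Y"))
  doy <- as.integer(format(d, "%j"))
  yr + (doy - 1) / 365.25
}

#' Extract the calendar year from dates of mixed representation
#'
#' @param x `Date`, ISO-8601 character, or fractional-year numeric.
#' @return integer years; `NA` where unparseable.
#' @keywords internal
year_of <- function(x) {
  if (is.numeric(x)) return(as.integer(floor(x)))
  if (inherits(x, "Date")) return(as.integer(format(x, "%Y")))
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  as.integer(format(d, "%Y"))
}

#' Normalize species names for tree/table matching
#'
#' Tip labels and trait tables frequently differ only in underscore versus
#' space and stray whitespace; matching is exact after this normalization.
#'
#' @param x character vector of species names.
#' @return normalized names (single underscores, trimmed).
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", "_", trimws(as.character(x)))
  gsub("_+", "_", x)
}

# Run `expr` under a local RNG state seeded with `seed` (if non-NULL), restoring
# the caller's state afterwards so generators never disturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
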
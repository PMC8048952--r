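#' Configuration for the synthetic benchmark generator
#'
#' Collects the knobs of every generator with defaults chosen to emulate the
#' study conditions: a c. 20-year satellite observation window (April 2000 to
#' January 2020), species-level Weibull interval distributions centred near
#' the observed species-level median fire return interval of c. 7 yr,
#' rainfall with a 1901-2003 baseline and multi-year drought episodes, a
#' pure-birth phylogeny, and a binary strategy generated from a logistic
#' model on log fire frequency and drought with moderate phylogenetic
#' signal (effect sizes near the fitted strategy model: intercept 0.4, log-FRI
#' slope 0.85, drought slope 1.3).
#'
#' @param seed master RNG seed.
#' @param n_species number of species (default 150, about half the size of
#'   the real comparative sample after filtering).
#' @param n_locations locations (burn pixels) per species (default 120; the
#'   study kept only species with at least 50 unique points and had a median
#'   of 270 records per species, so the default clears the sampling filter
#'   while keeping species-level fire statistics reasonably precise).
#' @param window observation window in fractional years (default
#'   `c(2000.25, 2020.08)`).
#' @param fri_meanlog,fri_sdlog log-normal distribution of species Weibull
#'   scales `b` (defaults `log(8)` and 0.7, spanning roughly 2-32 yr scales
#'   for fire-prone species, comparable to the observed 1-94 yr FRI range).
#' @param shape_range species Weibull shapes `c` drawn uniformly from this
#'   range (default `c(1.0, 1.6)`).
#' @param prop_rarely_burnt fraction of species given very long fire return
#'   times (scale multiplied by `rare_scale_mult`), producing the
#'   low-proportion-burned mode below the fire-prone break (default 0.25).
#' @param rare_scale_mult scale multiplier for rarely burnt species (40).
#' @param burnable_range range of the per-species fraction of locations lying
#'   in burnable landscape (default `c(0.35, 1)`); the remaining locations
#'   never burn, spreading the proportion-burned distribution as in real
#'   occurrence data where many records fall on unburnable microsites.
#' @param climatology 12 monthly mean rainfall totals (mm); default a wet-dry
#'   seasonal cycle summing to c. 1000 mm/yr.
#' @param rain_sdlog lognormal monthly rainfall noise (default 0.3).
#' @param n_rain_cells number of coarse climate cells (default 30); rainfall
#'   is simulated per cell and locations are assigned to cells, mirroring the
#'   0.5-degree rainfall grid against c. 500-m burn pixels.
#' @param drought_cell_frac fraction of climate cells that are drought-prone
#'   (default 0.5); each species has a random affinity for drought cells,
#'   creating species-level drought variation.
#' @param n_droughts recurrent drought episodes per drought-prone cell during
#'   the satellite era (default 3).
#' @param drought_length_months,drought_deficit episode length and fractional
#'   rainfall deficit (defaults 30 months, 0.6).
#' @param baseline_years rainfall record span (default 1901-2019; the first
#'   103 years are the MAP baseline).
#' @param beta logistic coefficients `(intercept, centred log FRI, centred
#'   mean FDI)` of the strategy model; defaults `c(0.4, 0.85, 1.3)`, the
#'   magnitudes of the fitted strategy model (per log-year and per FDI unit).
#' @param alpha phylogenetic-signal reversion rate per unit tree depth
#'   (default 2, moderate signal: the strategy is heritable but labile, with
#'   both states scattered across the major clades; larger = weaker signal).
#' @param birth pure-birth speciation rate for the tree (default 1).
#' @param frp_coupling slope of log median FRP on -log FRI (default 0.35),
#'   giving the observed negative frequency-intensity relationship;
#'   `frp_base` (default 28 MW) is the typical detection-level median, chosen
#'   so species-level 95th quantiles land on the observed few-tens-to-few-
#'   hundreds MW scale; `frp_sdlog` (0.7) is the detection-level spread and
#'   `frp_species_sdlog` (0.45) the species-level ecological scatter around
#'   the frequency-intensity coupling.
#' @param frp_base,frp_sdlog,frp_species_sdlog,frp_detections_per_location
#'   see `frp_coupling`.
#' @param dup_rate,low_precision_rate,pre1980_rate,high_hii_rate rates of
#'   injected QC-noise records (defaults 0.05, 0.05, 0.05, 0.10).
#' @param records_per_location occurrence records per location (default 1).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L, n_species = 150, n_locations = 120,
    window = c(2000.25, 2020.08),
    fri_meanlog = log(8), fri_sdlog = 0.7, shape_range = c(1.0, 1.6),
    prop_rarely_burnt = 0.25, rare_scale_mult = 40,
    burnable_range = c(0.35, 1),
    climatology = 85 + 60 * sin(2 * pi * (1:12) / 12),
    rain_sdlog = 0.3, n_rain_cells = 30, drought_cell_frac = 0.5,
    n_droughts = 3, drought_length_months = 30, drought_deficit = 0.6,
    baseline_years = c(1901, 2019),
    beta = c(0.4, 0.85, 1.3), alpha = 2, birth = 1,
    frp_coupling = 0.35, frp_base = 28, frp_sdlog = 0.7,
    frp_species_sdlog = 0.45, frp_detections_per_location = 5,
    dup_rate = 0.05, low_precision_rate = 0.05, pre1980_rate = 0.05,
    high_hii_rate = 0.10, records_per_location = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 3, cfg$n_locations >= 1,
            cfg$window[1] < cfg$window[2],
            cfg$drought_deficit >= 0, cfg$drought_deficit <= 1,
            all(cfg$climatology >= 0), length(cfg$climatology) == 12,
            all(c(cfg$dup_rate, cfg$low_precision_rate, cfg$pre1980_rate,
                  cfg$high_hii_rate) >= 0))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a Weibull-renewal fire history
#'
#' Fires recur as a renewal process with Weibull(scale `b`, shape `c`)
#' inter-fire intervals. The process is started a burn-in of five mean
#' intervals before the window opens, so the truncation of the first and
#' last interval by the window reproduces the open-tailed censoring of a
#' satellite record sampled from an ongoing fire regime.
#'
#' @param b,c Weibull scale (years) and shape, both `> 0`.
#' @param window numeric `c(start, end)` in fractional years.
#' @param location_id id for the resulting history.
#' @param seed RNG seed (optional; generators are seed-deterministic).
#' @return a [fire_history()].
#' @export
simulate_fire_history <- function(b, c, window = c(2000.25, 2020.08),
                                  location_id = "loc", seed = NULL) {
  stopifnot(b > 0, c > 0)
  with_seed(seed, {
    mean_iv <- b * gamma(1 + 1 / c)
    t0 <- window[1] - 5 * mean_iv
    span <- window[2] - t0
    n_guess <- ceiling(span / mean_iv + 10 * sqrt(span / mean_iv) + 10)
    draws <- stats::rweibull(n_guess, shape = c, scale = b)
    while (sum(draws) < span)
      draws <- c(draws, stats::rweibull(n_guess, shape = c, scale = b))
    times <- t0 + cumsum(draws)
    fires <- times[times >= window[1] & times <= window[2]]
    fire_history(location_id, window[1], window[2], fires)
  })
}

#' Simulate monthly rainfall with drought episodes
#'
#' Monthly totals are the seasonal climatology multiplied by lognormal noise
#' (`exp(N(-sdlog^2/2, sdlog))`, mean 1), with optional episodes during which
#' totals are scaled by `1 - deficit`.
#'
#' @param location_id location identifier.
#' @param years `c(first, last)` calendar years (inclusive).
#' @param climatology 12 monthly means (mm).
#' @param sdlog lognormal noise scale (0 = deterministic climatology).
#' @param episodes list of `list(start_year, start_month, length_months,
#'   deficit)` drought episodes.
#' @param seed RNG seed.
#' @return data.frame `(location_id, year, month, rain_mm)`.
#' @export
simulate_rainfall <- function(location_id, years = c(1901, 2019),
                              climatology = 85 + 60 * sin(2 * pi * (1:12) / 12),
                              sdlog = 0.3, episodes = list(), seed = NULL) {
  stopifnot(length(climatology) == 12, all(climatology >= 0))
  yrs <- seq(years[1], years[2])
  n <- length(yrs) * 12L
  with_seed(seed, {
    noise <- if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
    df <- data.frame(location_id = location_id,
                     year = rep(yrs, each = 12L),
                     month = rep(1:12, length(yrs)),
                     rain_mm = rep(climatology, length(yrs)) * noise,
                     stringsAsFactors = FALSE)
    for (ep in episodes) {
      i0 <- match(ep$start_year, yrs)
      if (is.na(i0)) next
      start <- (i0 - 1L) * 12L + ep$start_month
      idx <- start:min(n, start + ep$length_months - 1L)
      df$rain_mm[idx] <- df$rain_mm[idx] * (1 - ep$deficit)
    }
    df
  })
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Pure-birth by default; tip labels are `sp001, sp002, ...`.
#'
#' @param n_tips number of tips, `>= 3`.
#' @param birth,death speciation and extinction rates.
#' @param seed RNG seed.
#' @return an ultrametric `phylo` tree.
#' @export
simulate_phylogeny <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  stopifnot(n_tips >= 3)
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth, death = death)
    tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
    tr
  })
}

#' Simulate a binary strategy with logistic means and phylogenetic signal
#'
#' Draws a latent Gaussian vector with the fixed-root mean-reversion
#' correlation `R(alpha)` of the fitting model (see
#' [phylo_logistic_mple()]) and thresholds its probability transform at the
#' logistic mean, so tip i is 1 with probability
#' `plogis(x_i' beta)` marginally while cross-tip dependence decays with
#' `alpha`. As `alpha` grows the tips become independent.
#'
#' @param tree ultrametric `phylo` tree.
#' @param X design matrix (rows in tip-label order) or data.frame of
#'   predictors without intercept; an intercept column is added if absent.
#' @param beta coefficient vector (including intercept).
#' @param alpha reversion rate per unit tree depth, `> 0`.
#' @param seed RNG seed.
#' @return named integer vector of 0/1 per tip.
#' @export
simulate_binary_trait <- function(tree, X, beta, alpha, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), alpha > 0)
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(v) all(v == 1)))) X <- cbind(1, X)
  stopifnot(ncol(X) == length(beta), nrow(X) == length(tree$tip.label))
  S <- ape::vcv(tree)
  S <- S / max(diag(S))
  R <- .pglm_corr(S, alpha)
  ch <- chol(R)
  mu <- stats::plogis(drop(X %*% beta))
  with_seed(seed, {
    z <- drop(crossprod(ch, stats::rnorm(nrow(X))))
    stats::setNames(as.integer(stats::pnorm(z) < mu), tree$tip.label)
  })
}

#' Generate a full synthetic benchmark bundle
#'
#' Produces every input of the pipeline with known ground truth: occurrence
#' records (with injected QC-noise records: duplicates, low-precision
#' coordinates, pre-1980 dates, high-HII records), burn histories per
#' location, FRP detections whose species-level median is coupled to fire
#' frequency (more frequent fire, lower intensity), rainfall per location
#' with drought episodes, a phylogeny, a trait table whose strategy is
#' simulated from the logistic model on true log FRI and mean FDI, and a
#' manifest of the true parameters.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, each element is also written as
#'   CSV (tree as Newick) and the paths are returned in `paths`.
#' @return list with `occurrences`, `histories` (list of [fire_history()]),
#'   `burns` (long data.frame), `mapping`, `frp`, `rainfall`,
#'   `location_cells` (location to climate-cell lookup), `tree`, `traits`,
#'   and `manifest` (species-level truth: `b`, `c`, `true_median_fri`,
#'   `rarely_burnt`, `burnable_fraction`, plus attributes `beta`, `alpha`).
#' @export
make_benchmark_bundle <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_sp <- cfg$n_species
    species <- sprintf("sp%03d", seq_len(n_sp))
    rare <- stats::runif(n_sp) < cfg$prop_rarely_burnt
    b <- stats::rlnorm(n_sp, cfg$fri_meanlog, cfg$fri_sdlog)
    b[rare] <- b[rare] * cfg$rare_scale_mult
    cc <- stats::runif(n_sp, cfg$shape_range[1], cfg$shape_range[2])
    true_fri <- weibull_median_fri(b, cc)

    tree <- simulate_phylogeny(n_sp, birth = cfg$birth)

    # coarse climate cells: rainfall (and droughts) live at cell scale
    n_cells <- cfg$n_rain_cells
    cells <- sprintf("cell%03d", seq_len(n_cells))
    cell_drought <- seq_len(n_cells) <= round(cfg$drought_cell_frac * n_cells)
    rainfall <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
      eps <- if (cell_drought[k])
        lapply(sample(2001:2016, cfg$n_droughts), function(y)
          list(start_year = y, start_month = 1,
               length_months = cfg$drought_length_months,
               deficit = cfg$drought_deficit)) else list()
      simulate_rainfall(cells[k], cfg$baseline_years, cfg$climatology,
                        cfg$rain_sdlog, episodes = eps)
    }))
    rownames(rainfall) <- NULL
    # each species prefers drought-prone cells to a random degree
    affinity <- stats::runif(n_sp)
    # fraction of each species' locations lying in burnable landscape
    burnable <- stats::runif(n_sp, cfg$burnable_range[1], cfg$burnable_range[2])
    burnable[rare] <- 1
    # species-level ecological scatter around the frequency-intensity coupling
    frp_scatter <- stats::rlnorm(n_sp, 0, cfg$frp_species_sdlog)

    histories <- vector("list", n_sp * cfg$n_locations)
    occ <- vector("list", n_sp); mapping <- vector("list", n_sp)
    frp <- vector("list", n_sp)
    loc_cell <- character(0)
    idx <- 0L
    for (i in seq_len(n_sp)) {
      ids <- sprintf("%s_L%03d", species[i], seq_len(cfg$n_locations))
      use_drought <- stats::runif(cfg$n_locations) < affinity[i]
      cell_of <- ifelse(use_drought,
                        sample(cells[cell_drought], cfg$n_locations, TRUE),
                        sample(cells[!cell_drought], cfg$n_locations, TRUE))
      loc_cell[ids] <- cell_of
      med_frp <- cfg$frp_base * (true_fri[i] / 8)^cfg$frp_coupling *
        frp_scatter[i]
      nf <- cfg$frp_detections_per_location
      loc_burnable <- stats::runif(cfg$n_locations) < burnable[i]
      for (j in seq_len(cfg$n_locations)) {
        idx <- idx + 1L
        histories[[idx]] <- if (loc_burnable[j])
          simulate_fire_history(b[i], cc[i], cfg$window, ids[j])
        else fire_history(ids[j], cfg$window[1], cfg$window[2])
      }
      nl <- cfg$n_locations
      n_rec <- cfg$records_per_location
      occ[[i]] <- data.frame(
        species = species[i],
        lon = rep(round(stats::runif(nl, -179, 179), 4), each = n_rec),
        lat = rep(round(stats::runif(nl, -55, 55), 4), each = n_rec),
        date = sprintf("%d-06-15", sample(1985:2019, nl * n_rec, TRUE)),
        hii = sample(0:30, nl * n_rec, replace = TRUE), protected = FALSE,
        location_id = rep(ids, each = n_rec), stringsAsFactors = FALSE)
      frp[[i]] <- data.frame(
        location_id = rep(ids, each = nf),
        timestamp = sprintf("%d-08-01", sample(2002:2019, nl * nf, TRUE)),
        frp = stats::rlnorm(nl * nf, log(med_frp), cfg$frp_sdlog),
        confidence = sample(10:100, nl * nf, replace = TRUE),
        stringsAsFactors = FALSE)
      mapping[[i]] <- data.frame(species = species[i], location_id = ids,
                                 stringsAsFactors = FALSE)
    }
    names(histories) <- unlist(lapply(histories, `[[`, "location_id"))
    occurrences <- do.call(rbind, occ)
    rownames(occurrences) <- NULL
    occurrences <- .inject_qc_noise(occurrences, cfg)
    mapping <- do.call(rbind, mapping)
    frp <- do.call(rbind, frp)
    rownames(mapping) <- rownames(frp) <- NULL

    # strategy from the logistic model on true log FRI and species mean FDI
    fdi <- monthly_fdi(rainfall[rainfall$year >= 2000, ], baseline = rainfall,
                       baseline_start = cfg$baseline_years[1],
                       baseline_end = 2003)
    cell_mapping <- data.frame(species = mapping$species,
                               location_id = loc_cell[mapping$location_id],
                               stringsAsFactors = FALSE)
    sp_fdi <- species_mean_fdi(cell_mapping, fdi)
    mfdi <- stats::setNames(sp_fdi$mean_fdi, sp_fdi$species)[species]
    Xs <- cbind(1, log(true_fri) - mean(log(true_fri)), mfdi - mean(mfdi))
    strategy <- simulate_binary_trait(tree, Xs, cfg$beta, cfg$alpha)

    traits <- data.frame(species = species,
                         strategy = as.integer(strategy[species]),
                         stringsAsFactors = FALSE)
    burns <- do.call(rbind, lapply(histories, function(h)
      if (length(h$burn_dates))
        data.frame(location_id = h$location_id, burn_date = h$burn_dates,
                   stringsAsFactors = FALSE) else NULL))
    rownames(burns) <- NULL
    manifest <- data.frame(species = species, b = b, c = cc,
                           true_median_fri = true_fri, rarely_burnt = rare,
                           burnable_fraction = burnable,
                           mean_fdi_truth = unname(mfdi),
                           stringsAsFactors = FALSE)
    attr(manifest, "beta") <- cfg$beta
    attr(manifest, "alpha") <- cfg$alpha

    out <- list(occurrences = occurrences, histories = histories,
                burns = burns, mapping = mapping, frp = frp,
                rainfall = rainfall,
                location_cells = data.frame(location_id = names(loc_cell),
                                            cell_id = unname(loc_cell),
                                            stringsAsFactors = FALSE),
                tree = tree, traits = traits,
                manifest = manifest, config = cfg)
    if (!is.null(dir)) out$paths <- .write_bundle(out, dir)
    out
  })
}

# inject QC-noise records that the cleaning filters must remove
.inject_qc_noise <- function(occ, cfg) {
  n <- nrow(occ)
  add <- list()
  pick <- function(rate) if (n > 0 && rate > 0)
    sample(n, max(1, round(rate * n))) else integer()
  dup <- occ[pick(cfg$dup_rate), , drop = FALSE]
  lowp <- occ[pick(cfg$low_precision_rate), , drop = FALSE]
  if (nrow(lowp)) { lowp$lon <- round(lowp$lon, 1); lowp$lat <- round(lowp$lat, 1) }
  old <- occ[pick(cfg$pre1980_rate), , drop = FALSE]
  if (nrow(old)) old$date <- sprintf("%d-06-15", sample(1900:1979, nrow(old), TRUE))
  hii <- occ[pick(cfg$high_hii_rate), , drop = FALSE]
  if (nrow(hii)) { hii$hii <- sample(31:64, nrow(hii), TRUE); hii$lon <- hii$lon + 0.0101 }
  out <- rbind(occ, dup, lowp, old, hii)
  out$lon_txt <- format(out$lon, trim = TRUE)
  out$lat_txt <- format(out$lat, trim = TRUE)
  rownames(out) <- NULL
  out[sample(nrow(out)), , drop = FALSE]
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    occurrences = file.path(dir, "occurrences.csv"),
    burns = file.path(dir, "burn_histories.csv"),
    mapping = file.path(dir, "species_locations.csv"),
    frp = file.path(dir, "frp_detections.csv"),
    rainfall = file.path(dir, "rainfall.csv"),
    location_cells = file.path(dir, "location_cells.csv"),
    traits = file.path(dir, "traits.csv"),
    manifest = file.path(dir, "manifest.csv"),
    tree = file.path(dir, "tree.nwk"))
  for (nm in setdiff(names(p), "tree"))
    utils::write.csv(bundle[[nm]], p[[nm]], row.names = FALSE)
  ape::write.tree(bundle$tree, p$tree)
  p
}
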
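#' Run the fire-regime / persistence-strategy pipeline end to end
#'
#' Orchestrates: occurrence QC -> proportion burned and fire-prone
#' classification (break-point threshold) -> pooled inter-fire intervals and
#' censored Weibull median FRI per species (with the [1, 100] yr bounds) ->
#' FRP 95th-quantile per species -> Foley's drought index per species ->
#' phylogenetic logistic regressions of strategy on log FRI + FDI and on
#' log FRP + FDI (interaction kept only when significant), optional trait
#' models, and PGLS diagnostics among the fire/drought variables. Natural
#' logs are used for the fire variables and nothing else is transformed.
#'
#' @param inputs list with elements `occurrences` (data.frame, see
#'   [read_occurrences()]), `histories` (named list of [fire_history()]),
#'   `mapping` (species x location_id records), `frp` (detections), either
#'   `rainfall` (monthly totals) or a precomputed `fdi` table,
#'   `location_cells` (optional location_id -> cell_id table when rainfall
#'   lives on a coarser grid), `tree` (`phylo`), `traits` (data.frame with
#'   `species`, `strategy`). A [make_benchmark_bundle()] output is accepted
#'   directly.
#' @param params list overriding defaults: `min_decimals` (3), `hii_max`
#'   (30), `min_year` (1980), `min_unique` (50), `conf_min` (50), `q` (0.95),
#'   `fri_bounds` (`c(1, 100)`), `baseline` (`c(1901, 2003)`),
#'   `breakpoint_bin` (0.02), `threshold` (`NULL` = estimate via break-point
#'   regression, fallback 0.26), `boot` (1000; `0` skips bootstrap CIs),
#'   `interaction_p` (0.05), `seed` (1).
#' @return list of class `grassfire_pipeline`: `profiles` (species fire
#'   profiles), `qc_report`, `threshold`, `fits` (named list of
#'   [phylo_logistic_mple()] fits), `pgls` (named list of [pgls_fit()]s),
#'   `summary` (per-strategy distribution summaries), `report` (seeds,
#'   counts, convergence).
#' @export
run_pipeline <- function(inputs, params = list()) {
  p <- utils::modifyList(list(
    min_decimals = 3, hii_max = 30, min_year = 1980, min_unique = 50,
    conf_min = 50, q = 0.95, fri_bounds = c(1, 100),
    baseline = c(1901, 2003), breakpoint_bin = 0.02, threshold = NULL,
    boot = 1000, interaction_p = 0.05, seed = 1L), params)

  qc <- clean_occurrences(inputs$occurrences, min_decimals = p$min_decimals,
                          hii_max = p$hii_max, min_year = p$min_year,
                          min_unique = p$min_unique)
  occ <- qc$records
  if (nrow(occ) == 0) stop("pipeline stage occurrence_qc: no records survive")
  mapping <- inputs$mapping
  mapping <- mapping[mapping$location_id %in% occ$location_id &
                       mapping$species %in% occ$species, , drop = FALSE]

  histories <- inputs$histories
  burnt <- vapply(histories, function(h) length(h$burn_dates) > 0, logical(1))

  prop <- proportion_burned(mapping, burnt)
  thr <- p$threshold %||% fire_prone_threshold(prop$proportion_burned,
                                               bin_width = p$breakpoint_bin)
  prop <- classify_fire_prone(prop, as.numeric(thr))

  ivs <- species_interval_sets(histories, mapping)
  fits <- lapply(ivs, fit_weibull_censored)
  fri <- vapply(fits, function(f)
    if (isTRUE(f$converged)) f$median_fri else NA_real_, numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))

  frp_det <- filter_confidence(inputs$frp, p$conf_min)
  frp_tab <- species_frp_quantile(frp_det, mapping, q = p$q)

  fdi_map <- mapping
  if (!is.null(inputs$location_cells)) {
    cell <- stats::setNames(inputs$location_cells$cell_id,
                            inputs$location_cells$location_id)
    fdi_map$location_id <- unname(cell[mapping$location_id])
  }
  fdi_tab <- if (!is.null(inputs$fdi)) inputs$fdi
  else monthly_fdi(inputs$rainfall[inputs$rainfall$year >= 2000, ,
                                   drop = FALSE],
                   baseline = inputs$rainfall,
                   baseline_start = p$baseline[1], baseline_end = p$baseline[2])
  sp_fdi <- species_mean_fdi(fdi_map, fdi_tab)

  profiles <- prop
  profiles$median_fri <- unname(fri[profiles$species])
  profiles$fri_converged <- unname(conv[profiles$species])
  profiles$median_fri[!profiles$fire_prone] <- NA_real_
  profiles <- filter_fri_bounds(profiles, p$fri_bounds[1], p$fri_bounds[2])
  profiles$frp_q95 <- frp_tab$frp_q[match(profiles$species, frp_tab$species)]
  profiles$mean_fdi <- sp_fdi$mean_fdi[match(profiles$species, sp_fdi$species)]

  tr <- inputs$traits
  profiles$strategy <- tr$strategy[match(profiles$species,
                                         normalize_species(tr$species))]

  model_fits <- list()
  dat_fri <- profiles[!is.na(profiles$median_fri) & !is.na(profiles$strategy) &
                        !is.na(profiles$mean_fdi), , drop = FALSE]
  dat_fri$log_fri <- log(dat_fri$median_fri)
  model_fits$strategy_fri <- .fit_with_interaction(
    strategy ~ log_fri + mean_fdi, "log_fri", "mean_fdi",
    dat_fri, inputs$tree, p)
  dat_frp <- profiles[!is.na(profiles$frp_q95) & !is.na(profiles$strategy) &
                        !is.na(profiles$mean_fdi), , drop = FALSE]
  dat_frp$log_frp <- log(dat_frp$frp_q95)
  model_fits$strategy_frp <- .fit_with_interaction(
    strategy ~ log_frp + mean_fdi, "log_frp", "mean_fdi",
    dat_frp, inputs$tree, p)

  # trait-association models for any further columns of the trait table
  trait_cols <- setdiff(names(tr), c("species", "strategy"))
  for (tc in trait_cols) {
    d <- data.frame(species = normalize_species(tr$species),
                    strategy = tr$strategy, x = tr[[tc]],
                    stringsAsFactors = FALSE)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    fit <- tryCatch(phylo_logistic_mple(strategy ~ x, d, inputs$tree),
                    error = function(e) NULL)
    if (!is.null(fit) && p$boot >= 100)
      fit <- bootstrap_ci(fit, n_boot = p$boot, seed = p$seed)
    model_fits[[paste0("strategy_", tc)]] <- fit
  }

  pgls_fits <- list()
  d2 <- dat_fri[!is.na(dat_fri$frp_q95), , drop = FALSE]
  d2$log_frp <- log(d2$frp_q95)
  if (nrow(d2) >= 5)
    pgls_fits$fri_frp <- pgls_fit(log_fri ~ log_frp, d2, inputs$tree)
  if (nrow(dat_frp) >= 5)
    pgls_fits$frp_fdi <- pgls_fit(log_frp ~ mean_fdi, dat_frp, inputs$tree)
  if (nrow(dat_fri) >= 5)
    pgls_fits$fri_fdi <- pgls_fit(log_fri ~ mean_fdi, dat_fri, inputs$tree)

  summaries <- tryCatch(
    summarize_distributions(profiles, profiles$strategy),
    error = function(e) NULL)

  structure(list(
    profiles = profiles, qc_report = qc$report,
    threshold = as.numeric(thr), threshold_fit = attr(thr, "fit"),
    fits = model_fits, pgls = pgls_fits, summary = summaries,
    report = list(
      seed = p$seed, params = p,
      n_records_clean = nrow(occ),
      n_species = length(unique(occ$species)),
      n_fire_prone = sum(profiles$fire_prone),
      n_fri_defined = sum(!is.na(profiles$median_fri)),
      n_weibull_converged = sum(conv),
      n_fri_model = nrow(dat_fri), n_frp_model = nrow(dat_frp))),
    class = "grassfire_pipeline")
}

# fit the main-effects model, test a mean-centered interaction term, and keep
# it only when significant. Centering the product preserves the main-effect
# coefficients as slopes at the covariate means, so "the fire effect" keeps
# its meaning whether or not the interaction is retained.
.fit_with_interaction <- function(f_main, x1, x2, data, tree, p) {
  if (nrow(data) < 10) return(NULL)
  fit <- phylo_logistic_mple(f_main, data, tree)
  data$interaction <- (data[[x1]] - mean(data[[x1]])) *
    (data[[x2]] - mean(data[[x2]]))
  f_int <- stats::update(f_main, . ~ . + interaction)
  fit_i <- tryCatch(phylo_logistic_mple(f_int, data, tree),
                    error = function(e) NULL)
  if (!is.null(fit_i) && isTRUE(fit_i$converged)) {
    p_int <- fit_i$pvalue[length(fit_i$pvalue)]
    if (is.finite(p_int) && p_int < p$interaction_p) fit <- fit_i
  }
  if (p$boot >= 100 && isTRUE(fit$converged))
    fit <- bootstrap_ci(fit, n_boot = p$boot, seed = p$seed)
  fit
}

#' @export
print.grassfire_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf("<grassfire_pipeline> %d species (%d fire-prone), threshold %.3f\n",
              r$n_species, r$n_fire_prone, x$threshold))
  for (nm in names(x$fits)) if (!is.null(x$fits[[nm]])) {
    cat("--", nm, "--\n"); print(x$fits[[nm]])
  }
  invisible(x)
}

#' Per-strategy location and spread of the fire-regime statistics
#'
#' Median, standard deviation and kernel-density mode (Gaussian kernel,
#' Silverman's bandwidth) of median FRI and FRP quantile, split by
#' persistence strategy. With fewer than `min_n` species in a stratum the
#' mode is omitted (medians only).
#'
#' @param profiles species profile data.frame with `median_fri` and
#'   `frp_q95`.
#' @param strategy 0/1 vector aligned with `profiles` rows.
#' @param min_n minimum stratum size for mode estimation (default 5).
#' @return data.frame with one row per strategy x variable:
#'   `(strategy, variable, n, median, sd, mode)`.
#' @export
summarize_distributions <- function(profiles, strategy, min_n = 5) {
  vars <- c(fri = "median_fri", frp = "frp_q95")
  rows <- list()
  for (s in c(0, 1)) for (vn in names(vars)) {
    v <- profiles[[vars[[vn]]]][!is.na(strategy) & strategy == s]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    mode <- if (length(v) >= min_n) kde_mode(v) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      strategy = s, variable = vars[[vn]], n = length(v),
      median = stats::median(v), sd = stats::sd(v), mode = mode)
  }
  if (!length(rows)) stop("no strategy groups to summarize")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kernel-density mode
#'
#' Location of the maximum of a Gaussian kernel density estimate with
#' Silverman's rule-of-thumb bandwidth.
#'
#' @param x numeric sample (length >= 2 unless all values are equal).
#' @return the KDE mode; for a point mass, that value.
#' @export
kde_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 2048)
  d$x[which.max(d$y)]
}
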
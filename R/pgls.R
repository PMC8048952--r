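#' Phylogenetic generalized least squares
#'
#' Linear regression between species-level variables whose errors covary in
#' proportion to shared branch length (Brownian-motion covariance, fixed
#' lambda = 1). The covariance matrix `C = vcv(tree)` is Cholesky-whitened
#' and the transformed model solved by ordinary least squares; on a star
#' phylogeny `C` is diagonal and the fit coincides with OLS.
#'
#' @param formula two-sided formula, e.g. `log_fri ~ log_frp`.
#' @param data data.frame with a `species` column or species row names;
#'   complete cases only.
#' @param tree rooted `phylo` tree with branch lengths covering the species.
#' @return object of class `pgls_fit`: `coefficients`, `slope`, `intercept`,
#'   `Fstat`, `df`, `r2`, `pvalue`, `n`, `sigma2`.
#' @export
pgls_fit <- function(formula, data, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  sp <- if ("species" %in% names(data)) data$species else rownames(data)
  if (is.null(sp)) stop("data needs a 'species' column or species row names")
  sp <- normalize_species(sp)
  tips <- normalize_species(tree$tip.label)
  data <- data.frame(data, stringsAsFactors = FALSE)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- setdiff(seq_len(nrow(data)), as.integer(attr(mf, "na.action")))
  keep_sp <- sp[keep]
  miss <- setdiff(keep_sp, tips)
  if (length(miss)) stop("species absent from the tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- as.numeric(stats::model.response(mf))
  tree$tip.label <- tips
  C <- ape::vcv(ape::keep.tip(tree, keep_sp))[keep_sp, keep_sp]
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance"))
  Lt <- t(ch)
  Xw <- forwardsolve(Lt, X)
  yw <- forwardsolve(Lt, y)
  f <- stats::lm.fit(Xw, yw)
  n <- length(y); p <- ncol(X) - 1
  rss <- sum(f$residuals^2)
  # null (GLS intercept-only) sum of squares for F and r2
  f0 <- stats::lm.fit(forwardsolve(Lt, matrix(1, n, 1)), yw)
  tss <- sum(f0$residuals^2)
  df2 <- n - p - 1
  Fstat <- if (p > 0) ((tss - rss) / p) / (rss / df2) else NA_real_
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  pv <- if (p > 0) stats::pf(Fstat, p, df2, lower.tail = FALSE) else NA_real_
  cf <- stats::setNames(f$coefficients, colnames(X))
  structure(list(
    coefficients = cf,
    slope = if (p >= 1) unname(cf[2]) else NA_real_,
    intercept = unname(cf[1]),
    Fstat = Fstat, df = c(p, df2), r2 = r2, pvalue = pv,
    n = n, sigma2 = rss / df2), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> n = %d, slope = %.4f, F(%d,%d) = %.2f, r2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$df[1], x$df[2], x$Fstat, x$r2, x$pvalue))
  invisible(x)
}
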
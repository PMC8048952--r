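#' Classify persistence strategy from scorch-trial mortality
#'
#' Quantitative classification rule: plants suffering under 30% mortality
#' after 100% leaf scorch are resprouters (coded 1); over 70% mortality
#' marks a seeder (coded 0); intermediate mortality is left unknown (`NA`).
#'
#' @param mortality_pct percent mortality at 100% leaf scorch, in \[0, 100\].
#' @return integer vector: 1 = resprouter, 0 = seeder, `NA` = unknown.
#' @examples
#' classify_strategy(c(25, 80, 50))
#' @export
classify_strategy <- function(mortality_pct) {
  if (any(!is.na(mortality_pct) &
          (mortality_pct < 0 | mortality_pct > 100)))
    stop("mortality must be a percentage in [0, 100]")
  out <- rep(NA_integer_, length(mortality_pct))
  out[!is.na(mortality_pct) & mortality_pct < 30] <- 1L
  out[!is.na(mortality_pct) & mortality_pct > 70] <- 0L
  out
}

#' Principal components of the leaf economic traits
#'
#' Centered-and-scaled PCA of specific leaf area (SLA), foliar N content and
#' foliar C:N ratio, collapsing them to two axes. Axis signs are fixed so
#' that leaf N loads positively on dimension 1 and SLA positively on
#' dimension 2, making scores comparable across runs.
#'
#' @param traits data.frame with numeric columns `sla`, `leaf_n`, `cn_ratio`
#'   and a `species` column (or species row names); no missing values.
#' @return list with `scores` (data.frame: species, dim1, dim2), `loadings`
#'   (3 x 3), `variance_fraction` (length 3, sums to 1).
#' @export
leaf_trait_pca <- function(traits) {
  need <- c("sla", "leaf_n", "cn_ratio")
  stopifnot(all(need %in% names(traits)))
  sp <- if ("species" %in% names(traits)) traits$species else rownames(traits)
  M <- as.matrix(traits[, need])
  if (nrow(M) < 3) stop("need at least 3 species")
  if (anyNA(M)) stop("missing trait values")
  if (any(apply(M, 2, stats::sd) == 0)) stop("constant trait column")
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  scores <- pc$x
  if (rot["leaf_n", 1] < 0) { rot[, 1] <- -rot[, 1]; scores[, 1] <- -scores[, 1] }
  if (rot["sla", 2] < 0) { rot[, 2] <- -rot[, 2]; scores[, 2] <- -scores[, 2] }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = data.frame(species = sp, dim1 = scores[, 1], dim2 = scores[, 2],
                           stringsAsFactors = FALSE, row.names = NULL),
       loadings = rot,
       variance_fraction = vf)
}
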
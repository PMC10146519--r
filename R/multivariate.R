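#' Sample dissimilarity matrix over the peaks of one elution range
#'
#' Restricts the table to the peaks of an elution range (see [rt_range()])
#' and computes pairwise sample dissimilarities, Bray-Curtis by default
#' (appropriate for non-negative abundance profiles with many zeros;
#' invariant to a common rescaling of two samples). An optional `log1p`
#' pre-transformation tames the heavy right tail of raw areas.
#'
#' @param table a `peak_table`.
#' @param range `"short"`, `"mid"`, `"long"` or `NULL` for all peaks.
#' @param metric `"bray"` or `"euclidean"` (passed to [vegan::vegdist()]).
#' @param transform `"none"` or `"log1p"`.
#' @return A `dist` object with attributes `metric` and `sample_ids`.
#' @export
distance_matrix <- function(table, range = NULL, metric = "bray",
                            transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  validate_peak_table(table)
  if (!is.null(range)) {
    rng <- rt_range(table$peak_labels, scale = table$label_type)
    table <- subset_peak_table(table, peaks = table$peak_labels[rng == range])
  }
  x <- table$areas
  if (nrow(x) < 2) stop("need >= 2 samples")
  tot <- rowSums(x)
  if (any(tot <= 0))
    stop("all-zero sample(s) in the selected range: ",
         paste(table$samples$sample_id[tot <= 0], collapse = ", "))
  if (transform == "log1p") x <- log1p(x)
  d <- vegan::vegdist(x, method = metric)
  attr(d, "metric") <- metric
  attr(d, "sample_ids") <- table$samples$sample_id
  d
}

#' PERMANOVA of line (and nested locality) effects on a distance matrix
#'
#' Permutational multivariate analysis of variance via a Gower-centred
#' decomposition of the dissimilarity matrix with sequential (Type I) sums
#' of squares, free permutation of sample rows, and the +1-corrected
#' permutation p value. Two designs are supported: differences across all
#' lines (`factors` with a `line` column only), and locality of origin with
#' lines nested within localities (`factors` with `locality` and `line`;
#' locality enters first, the line term then captures line-within-locality
#' variation because line identities are unique to their locality).
#'
#' @param dist a `dist` (see [distance_matrix()]).
#' @param factors data.frame aligned with the distance matrix rows, with
#'   column `line` and optionally `locality`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed making the permutation p reproducible.
#' @return data.frame `(term, df, SumOfSqs, F, p)` including the residual and
#'   total rows, with `n_perm` and the seed as attributes.
#' @export
permanova <- function(dist, factors, n_perm = 999, seed = NULL) {
  factors <- as.data.frame(factors)
  if (is.null(factors$line)) stop("factors must contain a 'line' column")
  n <- attr(dist, "Size")
  if (nrow(factors) != n) stop("factors rows must match the distance matrix")
  nested <- !is.null(factors$locality)
  factors$line <- factor(factors$line)
  if (nested) factors$locality <- factor(factors$locality)
  if (!is.null(seed)) set.seed(seed)
  fml <- if (nested) dist ~ locality + line else dist ~ line
  fit <- vegan::adonis2(fml, data = factors, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df,
                    SumOfSqs = fit$SumOfSqs, F = fit$F, p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  if (out$df[out$term == "Residual"] <= 0) stop("residual degrees of freedom is 0")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Reduce a peak table (or matrix) to principal-component scores
#'
#' Centred (not scaled) PCA by singular value decomposition. Used ahead of
#' linear discriminant analysis to bring the number of variables below the
#' per-group sample size.
#'
#' @param x a `peak_table` or a numeric samples x variables matrix.
#' @param k number of components to keep; must be < min(samples, variables).
#' @return list with `scores` (samples x k), `explained` (per-component
#'   variance fractions over all components) and the `prcomp` fit.
#' @export
pca_reduce <- function(x, k) {
  m <- if (inherits(x, "peak_table")) x$areas else as.matrix(x)
  if (k >= min(dim(m))) stop("k must be smaller than both matrix dimensions")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE], explained = expl, fit = pc)
}

#' Linear discriminant analysis of localities on reduced scores
#'
#' Fisher discriminant axes of the groups on the PCA scores, summarised as
#' per-group centroids with standard errors on each axis and the per-axis
#' share of between-group variance.
#'
#' @param scores numeric matrix of sample scores (from [pca_reduce()]).
#' @param groups factor (or coercible) of group / locality labels, one per
#'   row; every group needs >= 2 samples.
#' @return list with `centroids` (data.frame: group, axis, mean, se, n),
#'   `axis_variance` (proportion of between-group variance per axis) and the
#'   `lda` fit.
#' @export
lda_localities <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  fit <- tryCatch(MASS::lda(scores, grouping = groups),
                  error = function(e)
                    stop("LDA failed (", conditionMessage(e),
                         "); within-group scatter may be singular - reduce k"))
  proj <- stats::predict(fit, as.data.frame(scores))$x
  axes <- colnames(proj)
  rows <- list()
  for (g in levels(groups)) for (ax in axes) {
    v <- proj[groups == g, ax]
    rows[[length(rows) + 1]] <-
      data.frame(group = g, axis = ax, mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
  }
  centroids <- do.call(rbind, rows)
  axis_variance <- fit$svd^2 / sum(fit$svd^2)
  names(axis_variance) <- axes
  list(centroids = centroids, axis_variance = axis_variance, lda = fit)
}
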
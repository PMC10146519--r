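#' Fit an ordered-quantile (rank-normal) transformation
#'
#' Maps the ranks of the training values onto standard-normal quantiles using
#' plotting positions `p = (rank - 0.5) / n` with average ranks for ties, so
#' the transformed training sample has mean 0 (exactly, for distinct values)
#' and variance close to 1. The fitted map supports transforming new values
#' and inverting scores by monotone interpolation.
#'
#' @param values numeric vector, at least 3 finite values, not all equal.
#' @return An object of class `ordernorm` holding the monotone (value, score)
#'   node table.
#' @export
ordernorm_fit <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values")
  if (max(values) == min(values)) stop("constant input: no variance to normalise")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  scores <- stats::qnorm((r - 0.5) / n)
  ord <- order(values)
  nodes <- data.frame(value = values[ord], score = scores[ord])
  nodes <- nodes[!duplicated(nodes$value), ]
  structure(list(nodes = nodes, n = n), class = "ordernorm")
}

#' @rdname ordernorm_fit
#' @param map a fitted `ordernorm` object.
#' @export
ordernorm_transform <- function(map, values) {
  stats::approx(map$nodes$value, map$nodes$score, xout = values, rule = 2)$y
}

#' @rdname ordernorm_fit
#' @param scores normal-scale scores to map back to the original scale;
#'   scores beyond the training range are clamped to the extreme training
#'   values.
#' @export
ordernorm_inverse <- function(map, scores) {
  stats::approx(map$nodes$score, map$nodes$value, xout = scores, rule = 2)$y
}

#' One-way line-effect F test for a single peak
#'
#' Tests whether variation between lines exceeds variation between replicates
#' (within and across generations, which stay in the residual) by a one-way
#' fixed-effects decomposition: `F = MS_between / MS_within` with
#' `df = (n_lines - 1, n - n_lines)`. A significant F on a common-garden
#' design indicates inherited differences between the lines.
#'
#' @param values numeric response (normally the rank-normal transformed
#'   areas).
#' @param lines factor (or coercible) of line identities.
#' @return list with `F`, `df_between`, `df_within`, `p`, `degenerate`
#'   (`TRUE` when the within-line variance is exactly zero, giving an
#'   infinite F), and the underlying `lm` fit as `fit`.
#' @export
fit_line_model <- function(values, lines) {
  lines <- factor(lines)
  if (nlevels(lines) < 2) stop("need >= 2 lines")
  if (length(values) != length(lines)) stop("values and lines differ in length")
  df_between <- nlevels(lines) - 1
  df_within <- length(values) - nlevels(lines)
  if (df_within <= 0) stop("no replication: residual degrees of freedom is 0")
  d <- data.frame(value = values, line = lines)
  fit <- stats::lm(value ~ line, data = d)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits warn; flagged below
  msw <- an$`Mean Sq`[2]
  # a numerically-zero within-line mean square means no replicate variation
  if (msw <= 1e-12 * max(an$`Mean Sq`[1], .Machine$double.xmin)) {
    return(list(F = Inf, df_between = df_between, df_within = df_within,
                p = 0, degenerate = TRUE, fit = fit))
  }
  list(F = an$`F value`[1], df_between = an$Df[1], df_within = an$Df[2],
       p = an$`Pr(>F)`[1], degenerate = FALSE, fit = fit)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Step-up adjusted p values (monotone in rank, capped at 1).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Estimated marginal means per line, with back-transformation
#'
#' Marginal means and confidence limits of the fitted one-way model on the
#' transformed scale, optionally mapped back to the original area scale
#' through the inverse rank-normal map (for display; the inference lives on
#' the transformed scale).
#'
#' @param model result of [fit_line_model()] (or a plain `lm` fit with a
#'   `line` term).
#' @param map optional `ordernorm` map for back-transformation.
#' @param level confidence level.
#' @return data.frame `(line, emmean, se, df, lower, upper[, response,
#'   response_lower, response_upper])`.
#' @export
marginal_means <- function(model, map = NULL, level = 0.95) {
  fit <- if (inherits(model, "lm")) model else model$fit
  em <- emmeans::emmeans(fit, "line", level = level)
  s <- as.data.frame(summary(em))
  out <- data.frame(line = as.character(s$line), emmean = s$emmean, se = s$SE,
                    df = s$df, lower = s$lower.CL, upper = s$upper.CL,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    out$response <- ordernorm_inverse(map, out$emmean)
    out$response_lower <- ordernorm_inverse(map, out$lower)
    out$response_upper <- ordernorm_inverse(map, out$upper)
  }
  out
}

#' Compact letter display from pairwise line contrasts
#'
#' Pairwise t contrasts between line marginal means (Tukey-adjusted by
#' default) are summarised as letter codes by the insert-and-absorb
#' algorithm, so that two lines share at least one letter exactly when their
#' contrast is not significant at `alpha`.
#'
#' @param model result of [fit_line_model()] or an `lm` fit.
#' @param alpha significance level for the pairwise contrasts.
#' @param adjust multiplicity adjustment passed to `emmeans` (`"tukey"`,
#'   `"none"`, `"BH"`, ...).
#' @return Named character vector of letter codes, one per line, ordered by
#'   decreasing marginal mean.
#' @export
pairwise_letters <- function(model, alpha = 0.05, adjust = "tukey") {
  fit <- if (inherits(model, "lm")) model else model$fit
  em <- emmeans::emmeans(fit, "line")
  ctr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                 adjust = adjust)))
  means <- as.data.frame(summary(em))
  lev <- as.character(means$line)[order(-means$emmean)]
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  unwrap <- function(s) sub("^\\((.*)\\)$", "\\1", s)  # emmeans (...) quoting
  pair_names <- strsplit(as.character(ctr$contrast), " - ", fixed = TRUE)
  for (k in seq_len(nrow(ctr))) {
    a <- unwrap(pair_names[[k]][1]); b <- unwrap(pair_names[[k]][2])
    if (!is.na(ctr$p.value[k]) && ctr$p.value[k] < alpha)
      sig[a, b] <- sig[b, a] <- TRUE
  }
  letters_from_significance(sig, lev)
}

#' Letters from a pairwise significance matrix (insert-and-absorb)
#'
#' @param sig logical matrix, `TRUE` where a pair differs significantly; row
#'   and column names are the level names.
#' @param order optional level ordering for letter assignment.
#' @return Named character vector of letter strings.
#' @export
letters_from_significance <- function(sig, order = rownames(sig)) {
  lev <- order
  cols <- list(lev)  # each column is a set of levels sharing one letter
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i || !sig[lev[i], lev[j]]) next
    k <- 1
    while (k <= length(cols)) {
      col <- cols[[k]]
      if (lev[i] %in% col && lev[j] %in% col) {
        cols[[k]] <- setdiff(col, lev[i])
        cols[[length(cols) + 1]] <- setdiff(col, lev[j])
      }
      k <- k + 1
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a]) next
      if (all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the position of their top member so letters read naturally
  first_pos <- vapply(cols, function(col) min(match(col, lev)), numeric(1))
  cols <- cols[order(first_pos)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(cols))
    for (l in cols[[k]]) out[l] <- paste0(out[l], letters[k])
  out
}

#' Spearman correlation screen over per-line mean peak areas
#'
#' All pairwise Spearman correlations between peaks across lines, with
#' Benjamini-Hochberg adjustment over the pairs, optionally excluding a named
#' line (e.g. a domesticated line that dominates the spread).
#'
#' @param line_means numeric matrix, peaks in rows, lines in columns.
#' @param exclude optional line (column) name to drop before correlating.
#' @return data.frame `(peak1, peak2, rho, p_raw, p_fdr, n)`; pairs with a
#'   constant vector get `NA` rho.
#' @export
spearman_screen <- function(line_means, exclude = NULL) {
  m <- as.matrix(line_means)
  if (!is.null(exclude)) m <- m[, setdiff(colnames(m), exclude), drop = FALSE]
  if (ncol(m) < 3) stop("need >= 3 lines per correlation")
  pk <- rownames(m) %||% as.character(seq_len(nrow(m)))
  pairs <- utils::combn(nrow(m), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ij <- pairs[, k]
    x <- m[ij[1], ]; y <- m[ij[2], ]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(peak1 = pk[ij[1]], peak2 = pk[ij[2]],
                        rho = NA_real_, p_raw = NA_real_, n = length(x)))
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(peak1 = pk[ij[1]], peak2 = pk[ij[2]],
               rho = unname(ht$estimate), p_raw = ht$p.value, n = length(x))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out[c("peak1", "peak2", "rho", "p_raw", "p_fdr", "n")]
}

#' Heritable-line-variation screen over a peak table
#'
#' The per-dataset pipeline: inclusion filter, per-peak rank-normal
#' transformation, one-way line F test, Benjamini-Hochberg adjustment across
#' the peaks of the dataset, and (for FDR-significant peaks) marginal means
#' with confidence limits and compact letter displays. Peaks that cannot be
#' modelled (constant after transformation, no replication) are logged and
#' skipped.
#'
#' @param table a single-category `peak_table`.
#' @param fdr_level FDR significance level.
#' @param threshold inclusion-filter detection threshold.
#' @param by_line inclusion cells within lines?
#' @param alpha,adjust passed to [pairwise_letters()].
#' @param letters compute marginal means and letters for significant peaks?
#' @return list with `results` (per-peak data.frame: `peak_label`, `F`,
#'   `df_between`, `df_within`, `p_raw`, `p_fdr`, `significant`),
#'   `emmeans` (named list per significant peak, each with the
#'   [marginal_means()] frame plus a `letters` column), `n_tested`, and
#'   `retained` (labels passing the filter).
#' @export
screen_dataset <- function(table, fdr_level = 0.05, threshold = 0.5,
                           by_line = TRUE, alpha = 0.05, adjust = "tukey",
                           letters = TRUE) {
  validate_peak_table(table)
  retained <- inclusion_filter(table, by_line = by_line, threshold = threshold)
  lines <- factor(table$samples$line)
  rows <- list(); maps <- list(); fits <- list()
  for (lab in retained) {
    j <- match_label(table, lab)
    a <- table$areas[, j]
    res <- tryCatch({
      map <- ordernorm_fit(a)
      z <- ordernorm_transform(map, a)
      fm <- fit_line_model(z, lines)
      maps[[as.character(lab)]] <- map
      fits[[as.character(lab)]] <- fm
      data.frame(peak_label = lab, F = fm$F, df_between = fm$df_between,
                 df_within = fm$df_within, p_raw = fm$p)
    }, error = function(e) {
      message("screen_dataset: skipping peak ", lab, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0)
    return(list(results = data.frame(), emmeans = list(), n_tested = 0,
                retained = retained))
  results <- do.call(rbind, rows)
  results$p_fdr <- fdr_adjust(results$p_raw)
  results$significant <- results$p_fdr < fdr_level
  em <- list()
  if (letters) {
    for (lab in results$peak_label[results$significant]) {
      key <- as.character(lab)
      mm <- marginal_means(fits[[key]], map = maps[[key]])
      lt <- pairwise_letters(fits[[key]], alpha = alpha, adjust = adjust)
      mm$letters <- unname(lt[mm$line])
      em[[key]] <- mm
    }
  }
  list(results = results, emmeans = em, n_tested = nrow(results),
       retained = retained)
}
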
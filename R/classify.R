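#' Retention-time / Kovats-index range boundaries
#'
#' The chromatographic run partitions into short, mid and long elution ranges
#' that concentrate different compound families (short-chain esters/alcohols,
#' aliphatic amides, and fatty-acid esters respectively). Boundaries are
#' 4.60-10.39, 10.40-13.59 and 13.60-21 min on the retention-time scale and
#' 840-1095, 1096-1240 and 1241-2175 on the Kovats-index scale.
#'
#' @param scale `"rt"` (minutes) or `"ki"` (Kovats index units).
#' @return data.frame with columns `range`, `lo`, `hi`.
#' @export
rt_range_bounds <- function(scale = c("rt", "ki")) {
  scale <- match.arg(scale)
  if (scale == "rt")
    data.frame(range = c("short", "mid", "long"),
               lo = c(4.60, 10.40, 13.60), hi = c(10.39, 13.59, 21.00))
  else
    data.frame(range = c("short", "mid", "long"),
               lo = c(840, 1096, 1241), hi = c(1095, 1240, 2175))
}

#' Assign peaks to the short/mid/long elution range
#'
#' @param label numeric vector of retention times (min) or Kovats indices.
#' @param scale which scale `label` is on.
#' @param bounds boundary table, by default [rt_range_bounds()] for `scale`.
#' @return character vector in `c("short", "mid", "long")`.
#' @export
rt_range <- function(label, scale = c("rt", "ki"), bounds = NULL) {
  scale <- match.arg(scale)
  if (is.null(bounds)) bounds <- rt_range_bounds(scale)
  out <- character(length(label))
  for (i in seq_along(label)) {
    hit <- which(label[i] >= bounds$lo & label[i] <= bounds$hi)
    if (length(hit) != 1)
      stop("label ", label[i], " outside the classified ", scale, " range [",
           min(bounds$lo), ", ", max(bounds$hi), "]")
    out[i] <- bounds$range[hit]
  }
  out
}

category_key <- function(samples) {
  interaction(samples$sex, samples$mating, drop = TRUE, lex.order = TRUE)
}

#' Inclusion filter: detection in at least half the samples of some cell
#'
#' A peak is retained when its detection proportion (share of samples with a
#' non-zero area) reaches `threshold` in at least one evaluation cell. Cells
#' are line x sex/mating-category combinations when `by_line` is `TRUE`
#' (each line gets its own chance to carry the peak), or sex/mating
#' categories alone otherwise. For a single-category table the category
#' collapses and cells are lines.
#'
#' @param table a `peak_table`.
#' @param by_line evaluate cells within each line?
#' @param threshold detection proportion required (default 0.5, compared with
#'   `>=`).
#' @return Numeric vector of retained peak labels, in table order.
#' @export
inclusion_filter <- function(table, by_line = TRUE, threshold = 0.5) {
  validate_peak_table(table)
  cat_key <- category_key(table$samples)
  cell <- if (by_line)
    interaction(table$samples$line, cat_key, drop = TRUE)
  else cat_key
  det <- table$areas > 0
  keep <- rep(FALSE, ncol(det))
  for (lev in levels(cell)) {
    rows <- cell == lev
    if (!any(rows)) next
    keep <- keep | colMeans(det[rows, , drop = FALSE]) >= threshold
  }
  table$peak_labels[keep]
}

#' Abundance class of a peak from its maximum category share
#'
#' For each sex/mating category the peak's share of the summed total area of
#' all peaks in that category is computed; the class follows the maximum
#' share across categories: >= 1\% major, 0.1-0.99\% intermediate, < 0.1\%
#' minor.
#'
#' @param tables named list of `peak_table`s, one per sex/mating category.
#' @param peak_label the peak to classify.
#' @return `"major"`, `"intermediate"` or `"minor"`, with the maximum share
#'   attached as attribute `"max_share"`.
#' @export
abundance_class <- function(tables, peak_label) {
  shares <- vapply(tables, function(t) {
    j <- match_label(t, peak_label)
    if (is.na(j)) return(NA_real_)
    tot <- sum(t$areas)
    if (tot <= 0) return(NA_real_)
    sum(t$areas[, j]) / tot
  }, numeric(1))
  if (all(is.na(shares)))
    stop("peak ", peak_label, " absent from all category tables")
  m <- max(shares, na.rm = TRUE)
  cls <- if (m >= 0.01) "major" else if (m >= 0.001) "intermediate" else "minor"
  structure(cls, max_share = m)
}

match_label <- function(table, peak_label) {
  tol <- if (table$label_type == "rt") 5e-3 else 0.5
  j <- which(abs(table$peak_labels - peak_label) < tol)
  if (length(j) == 0) NA_integer_ else j[1]
}

#' Sex specificity / selectivity of a peak within one sample type
#'
#' A peak detected in only one sex is sex *specific*; one detected in both
#' but with more than a log10 (10-fold) difference in mean area is sex
#' *selective* toward the more abundant sex; detection in both without such a
#' bias gives `"none"`. Means are taken over all samples of the category,
#' zeros included (they are true non-detections in this data model); set
#' `include_zeros = FALSE` to average detected samples only.
#'
#' @param male_table,female_table `peak_table`s restricted to one sample type
#'   (virgin or mixed); pass `NULL` for a sex that was not assayed.
#' @param peak_label the peak.
#' @param include_zeros include non-detections in the means?
#' @param log10_cut selectivity threshold on the |log10 mean ratio| scale
#'   (strict `>`; exactly 10-fold classifies as `"none"`).
#' @return One of `"male_specific"`, `"male_selective"`, `"female_specific"`,
#'   `"female_selective"`, `"none"`, `"not_detected"`, `"not_assayed"`.
#' @export
sex_bias_class <- function(male_table, female_table, peak_label,
                           include_zeros = TRUE, log10_cut = 1) {
  if (is.null(male_table) || is.null(female_table)) return("not_assayed")
  get <- function(t) {
    j <- match_label(t, peak_label)
    if (is.na(j)) numeric(nrow(t$areas)) else t$areas[, j]
  }
  am <- get(male_table); af <- get(female_table)
  det_m <- any(am > 0); det_f <- any(af > 0)
  if (!det_m && !det_f) return("not_detected")
  if (det_m && !det_f) return("male_specific")
  if (!det_m && det_f) return("female_specific")
  mean_of <- function(a) if (include_zeros) mean(a) else mean(a[a > 0])
  d <- log10(mean_of(am)) - log10(mean_of(af))
  if (d > log10_cut) "male_selective"
  else if (d < -log10_cut) "female_selective"
  else "none"
}

#' Chi-square test for enrichment of significant peaks across categories
#'
#' Compares observed category counts (e.g. of significantly varying peaks per
#' elution range) against the proportions of a reference count vector (all
#' peaks tested per range). The default is a goodness-of-fit test with
#' expected counts `sum(observed) * reference / sum(reference)` and
#' `df = k - 1`. `method = "contingency"` instead tests the 2 x k table of
#' observed vs remaining (`reference - observed`) counts for homogeneity;
#' the two formulations answer slightly different questions and give
#' slightly different statistics, so both are exposed (contingency requires
#' `observed <= reference`).
#'
#' @param observed,reference integer count vectors of equal length.
#' @param method `"gof"` (default) or `"contingency"`.
#' @return list with `statistic`, `df`, `p.value`, `expected`, `method`.
#' @export
enrichment_test <- function(observed, reference, method = c("gof", "contingency")) {
  method <- match.arg(method)
  if (length(observed) != length(reference))
    stop("observed and reference must have equal length")
  if (any(reference <= 0)) stop("all reference counts must be positive")
  if (sum(observed) <= 0) stop("observed counts sum to zero")
  if (method == "gof") {
    ht <- suppressWarnings(
      stats::chisq.test(observed, p = reference / sum(reference)))
  } else {
    if (any(observed > reference))
      stop("contingency formulation needs observed <= reference in every category")
    ht <- suppressWarnings(
      stats::chisq.test(rbind(observed, reference - observed), correct = FALSE))
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), expected = unname(ht$expected),
       method = method)
}

#' Tabulate peak classifications
#'
#' Counts peaks per combination of sex-bias pattern (virgin status / mixed
#' status), elution range and abundance class, mirroring the row structure of
#' the classification summary table.
#'
#' @param classifications data.frame with columns `peak_label`, `rt_range`,
#'   `abundance_class`, `sex_bias_virgin`, `sex_bias_mixed`.
#' @return data.frame of counts over the observed combinations plus a full
#'   cross-tabulation in attribute `"xtab"`.
#' @export
classification_summary <- function(classifications) {
  cols <- c("peak_label", "rt_range", "abundance_class",
            "sex_bias_virgin", "sex_bias_mixed")
  missing_cols <- setdiff(cols, names(classifications))
  if (length(missing_cols))
    stop("classification frame lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(classifications) == 0) {
    out <- data.frame(sex_bias_virgin = character(), sex_bias_mixed = character(),
                      rt_range = character(), abundance_class = character(),
                      n = integer())
    attr(out, "xtab") <- table(character())
    return(out)
  }
  ag <- stats::aggregate(
    list(n = classifications$peak_label),
    by = classifications[c("sex_bias_virgin", "sex_bias_mixed",
                           "rt_range", "abundance_class")],
    FUN = length)
  ag <- ag[order(ag$sex_bias_virgin, ag$sex_bias_mixed, ag$rt_range), ]
  rownames(ag) <- NULL
  attr(ag, "xtab") <- with(classifications,
    table(virgin = sex_bias_virgin, mixed = sex_bias_mixed, range = rt_range))
  ag
}

#' Classify every peak of a category set in one pass
#'
#' Convenience wrapper running [rt_range()], [abundance_class()] and
#' [sex_bias_class()] per peak over a named list of category tables (names
#' like `"virgin_male"`, `"mixed_female"`).
#'
#' @param tables named list of per-category `peak_table`s.
#' @param peak_labels peaks to classify (default: union over tables).
#' @param scale label scale for the range classification.
#' @return data.frame suitable for [classification_summary()].
#' @export
classify_peaks <- function(tables, peak_labels = NULL, scale = "rt") {
  if (is.null(peak_labels))
    peak_labels <- sort(unique(unlist(lapply(tables, `[[`, "peak_labels"))))
  pick <- function(sex, mating) {
    nm <- paste(mating, sex, sep = "_")
    if (nm %in% names(tables)) tables[[nm]] else NULL
  }
  rows <- lapply(peak_labels, function(lab) {
    data.frame(
      peak_label = lab,
      rt_range = rt_range(lab, scale = scale),
      abundance_class = as.character(abundance_class(tables, lab)),
      sex_bias_virgin = sex_bias_class(pick("male", "virgin"),
                                       pick("female", "virgin"), lab),
      sex_bias_mixed = sex_bias_class(pick("male", "mixed"),
                                      pick("female", "mixed"), lab),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
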
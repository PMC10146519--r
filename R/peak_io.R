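#' Default metadata-column dialect for deposited peak-table CSVs
#'
#' The deposited datasets carry sample metadata in named columns ahead of the
#' numeric-headed peak columns. This helper returns the default mapping from
#' internal field names to CSV column headers; pass a modified copy to
#' [read_peak_table()] when a file uses different headers.
#'
#' @param sample,line,locality,generation,cage,sex,mating,batch column headers.
#' @return Named list of column headers.
#' @export
peak_dialect <- function(sample = "Sample", line = "Line", locality = "Locality",
                         generation = "Gen", cage = "Cage", sex = "Sex",
                         mating = "Mating", batch = "Batch") {
  list(sample = sample, line = line, locality = locality, generation = generation,
       cage = cage, sex = sex, mating = mating, batch = batch)
}

format_peak_label <- function(label, label_type) {
  if (label_type == "ki") format(as.integer(round(label)), trim = TRUE)
  else sprintf("%.2f", label)
}

#' Construct a validated peak table
#'
#' A peak table couples a sample metadata frame with a samples x peaks matrix
#' of non-negative peak areas. Zero encodes "not detected". Peak columns are
#' labelled by retention time in minutes (2 decimal places, `label_type =
#' "rt"`) or by integer Kovats index (`label_type = "ki"`) and are kept in
#' strictly increasing label order.
#'
#' @param samples data.frame with columns `sample_id`, `line`, `locality`,
#'   `generation`, `cage`, `sex`, `mating`, `batch` (missing metadata columns
#'   are filled with `NA`; `sample_id` is required and must be unique).
#' @param peak_labels numeric vector of peak labels.
#' @param areas numeric matrix, `nrow(samples)` x `length(peak_labels)`.
#' @param label_type `"rt"` or `"ki"`.
#' @param dataset_tag free-text tag identifying the dataset.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(samples, peak_labels, areas,
                       label_type = c("rt", "ki"), dataset_tag = "") {
  label_type <- match.arg(label_type)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$sample_id)) stop("samples must have a 'sample_id' column")
  for (col in c("line", "locality", "generation", "cage", "sex", "mating", "batch"))
    if (is.null(samples[[col]])) samples[[col]] <- NA
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  peak_labels <- as.numeric(peak_labels)
  if (label_type == "rt") peak_labels <- round(peak_labels, 2)
  else peak_labels <- round(peak_labels)
  ord <- order(peak_labels)
  peak_labels <- peak_labels[ord]
  if (ncol(areas) > 0) areas <- areas[, ord, drop = FALSE]
  x <- structure(list(samples = samples, peak_labels = peak_labels,
                      areas = areas, label_type = label_type,
                      dataset_tag = dataset_tag),
                 class = "peak_table")
  validate_peak_table(x)
  x
}

#' Validate the internal invariants of a peak table
#'
#' Checks dimensions, uniqueness of sample ids, non-negativity of areas and
#' strict ordering of peak labels; stops with an informative error naming the
#' offending row/column on failure.
#'
#' @param x a `peak_table`.
#' @return `x`, invisibly.
#' @export
validate_peak_table <- function(x) {
  stopifnot(inherits(x, "peak_table"))
  if (nrow(x$areas) != nrow(x$samples))
    stop("area matrix has ", nrow(x$areas), " rows but ", nrow(x$samples), " samples")
  if (ncol(x$areas) != length(x$peak_labels))
    stop("area matrix has ", ncol(x$areas), " columns but ",
         length(x$peak_labels), " peak labels")
  dup <- duplicated(x$samples$sample_id)
  if (any(dup))
    stop("duplicate sample_id: ", paste(unique(x$samples$sample_id[dup]), collapse = ", "))
  if (anyNA(x$areas)) stop("areas contain NA; encode non-detection as 0")
  if (any(x$areas < 0)) {
    idx <- which(x$areas < 0, arr.ind = TRUE)[1, ]
    stop("negative area for sample '", x$samples$sample_id[idx[1]],
         "', peak ", format_peak_label(x$peak_labels[idx[2]], x$label_type))
  }
  if (length(x$peak_labels) > 1 && any(diff(x$peak_labels) <= 0))
    stop("peak labels must be strictly increasing")
  invisible(x)
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table", if (nzchar(x$dataset_tag)) paste0(" '", x$dataset_tag, "'"), ">\n",
      sep = "")
  cat("  ", nrow(x$samples), " samples x ", length(x$peak_labels), " peaks (",
      x$label_type, " labels)\n", sep = "")
  det <- if (length(x$areas)) mean(x$areas > 0) else NA
  cat("  detection rate: ", format(round(det, 3)), "\n", sep = "")
  invisible(x)
}

#' Read a peak-area table from a deposited-style CSV
#'
#' Metadata columns are identified by the dialect headers; every remaining
#' column whose header parses as a number is taken as a peak column (its
#' header being the retention time or Kovats index). Empty cells are read as
#' zero (not detected) with a message. Peak columns are returned sorted by
#' ascending label.
#'
#' @param path CSV file path.
#' @param dialect metadata header mapping, see [peak_dialect()].
#' @param label_type `"rt"` (retention-time headers, minutes) or `"ki"`.
#' @param dataset_tag tag stored on the returned table (defaults to the
#'   file name).
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path, dialect = peak_dialect(),
                            label_type = c("rt", "ki"), dataset_tag = NULL) {
  label_type <- match.arg(label_type)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(raw)
  num_hdr <- suppressWarnings(as.numeric(hdr))
  meta_cols <- hdr[is.na(num_hdr)]
  peak_cols <- hdr[!is.na(num_hdr)]
  known <- unlist(dialect, use.names = FALSE)
  unknown <- setdiff(meta_cols, known)
  if (length(unknown))
    stop("non-numeric peak header(s) not in the metadata dialect: ",
         paste(unknown, collapse = ", "))
  grab <- function(key) {
    col <- dialect[[key]]
    if (col %in% meta_cols) raw[[col]] else NA
  }
  samples <- data.frame(
    sample_id = if (dialect$sample %in% meta_cols) as.character(raw[[dialect$sample]])
                else sprintf("s%03d", seq_len(nrow(raw))),
    line = as.character(grab("line")),
    locality = as.character(grab("locality")),
    generation = suppressWarnings(as.integer(grab("generation"))),
    cage = as.character(grab("cage")),
    sex = as.character(grab("sex")),
    mating = as.character(grab("mating")),
    batch = as.character(grab("batch")),
    stringsAsFactors = FALSE
  )
  areas <- as.matrix(raw[, peak_cols, drop = FALSE])
  storage.mode(areas) <- "double"
  n_missing <- sum(is.na(areas))
  if (n_missing > 0) {
    message("read_peak_table: ", n_missing,
            " empty cell(s) read as 0 (not detected)")
    areas[is.na(areas)] <- 0
  }
  peak_table(samples, as.numeric(peak_cols), areas,
             label_type = label_type,
             dataset_tag = dataset_tag %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a peak table back to the deposited CSV dialect
#'
#' Inverse of [read_peak_table()]: metadata columns first (under the dialect
#' headers), then one column per peak headed by its formatted label.
#'
#' @param table a `peak_table`.
#' @param path output CSV path.
#' @param dialect metadata header mapping.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, dialect = peak_dialect()) {
  validate_peak_table(table)
  s <- table$samples
  out <- data.frame(s$sample_id, s$line, s$locality, s$generation, s$cage,
                    s$sex, s$mating, s$batch,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unlist(dialect[c("sample", "line", "locality", "generation",
                                 "cage", "sex", "mating", "batch")],
                       use.names = FALSE)
  labels <- vapply(table$peak_labels, format_peak_label, "", table$label_type)
  areas <- as.data.frame(table$areas)
  names(areas) <- labels
  out <- cbind(out, areas)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Restrict a peak table to a subset of samples and/or peaks
#'
#' @param table a `peak_table`.
#' @param samples logical or integer index over rows, or `NULL` to keep all.
#' @param peaks numeric vector of peak labels to keep, or `NULL`.
#' @return A `peak_table`.
#' @export
subset_peak_table <- function(table, samples = NULL, peaks = NULL) {
  s <- table$samples; a <- table$areas; lab <- table$peak_labels
  if (!is.null(samples)) {
    s <- s[samples, , drop = FALSE]
    a <- a[samples, , drop = FALSE]
  }
  if (!is.null(peaks)) {
    keep <- lab %in% peaks
    lab <- lab[keep]
    a <- a[, keep, drop = FALSE]
  }
  peak_table(s, lab, a, label_type = table$label_type,
             dataset_tag = table$dataset_tag)
}

#' Normalise peak areas for batch differences in total area
#'
#' Each batch is rescaled multiplicatively so that every batch's total summed
#' area equals the grand mean of the pre-normalisation batch totals. Zeros
#' stay zero, within-batch peak proportions are unchanged, and applying the
#' normalisation twice is equivalent to applying it once.
#'
#' @param table a `peak_table` with a batch label on every sample.
#' @return A normalised `peak_table` with attribute `"batch_normalization"`
#'   holding the batch totals and scale factors.
#' @export
normalize_batches <- function(table) {
  validate_peak_table(table)
  batch <- table$samples$batch
  if (anyNA(batch)) stop("every sample needs a batch label")
  tt <- tapply(rowSums(table$areas), batch, sum)
  totals <- stats::setNames(as.vector(tt), names(tt))
  if (any(totals <= 0))
    stop("batch with zero total area: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  target <- mean(totals)
  factors <- target / totals
  areas <- table$areas * factors[match(batch, names(totals))]
  out <- peak_table(table$samples, table$peak_labels, areas,
                    label_type = table$label_type, dataset_tag = table$dataset_tag)
  attr(out, "batch_normalization") <-
    list(batch_totals = totals, scale_factors = factors, target = target)
  out
}
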
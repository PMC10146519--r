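#' Run the full analysis workflow on a simulated or loaded study
#'
#' Orchestrates the stages in the order of the analysis: batch
#' normalisation, peak classification, Rt-KI calibration and imputation,
#' cross-platform matching, the per-dataset heritable-line-variation screen,
#' and the multivariate locality analysis. Writes every stage's result table
#' under `out_dir` together with a run manifest (seed, config, package
#' version), and returns the results invisibly. With the same config the run
#' is deterministic.
#'
#' @param config a [sim_config()] (the study is simulated), or a list with
#'   element `tables` (named per-category `peak_table`s) plus optional
#'   `ms_peaks` and `calibrators`.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param stages subset of `c("classify", "calibrate", "match", "screen",
#'   "multivariate")` to run.
#' @param fdr_level FDR level for the screen.
#' @param n_perm permutations for the PERMANOVAs.
#' @return list with per-stage results, invisibly.
#' @export
run_all <- function(config, out_dir = NULL,
                    stages = c("classify", "calibrate", "match", "screen",
                               "multivariate"),
                    fdr_level = 0.05, n_perm = 199) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(config, "sim_config")) {
    sim <- simulate_study(config)
    tables <- sim$tables
    ms_peaks <- simulate_gcms(config, sim$truth)
    calibrators <- truth_calibrators(config, sim$truth)
    seed <- config$seed
  } else {
    tables <- config$tables
    ms_peaks <- config$ms_peaks
    calibrators <- config$calibrators
    sim <- NULL
    seed <- config$seed %||% 1L
  }
  tables <- lapply(tables, normalize_batches)
  out <- list(seed = seed)
  emit <- function(name, df) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if ("classify" %in% stages) {
    cls <- classify_peaks(tables)
    out$classification <- cls
    out$classification_summary <- classification_summary(cls)
    emit("classification", cls)
    emit("classification_summary", out$classification_summary)
  }
  if ("calibrate" %in% stages && !is.null(calibrators)) {
    model <- fit_calibration(calibrators)
    rt <- tables[[1]]$peak_labels
    ok <- rt >= min(calibrators$rt) - 1 & rt <= max(calibrators$rt) + 1
    imputed <- data.frame(rt = rt[ok], ki_imputed = impute_ki(model, rt[ok]))
    out$calibration <- model
    out$imputed_ki <- imputed
    emit("imputed_ki", imputed)
  }
  if ("match" %in% stages && !is.null(ms_peaks) && !is.null(out$imputed_ki)) {
    fid_kis <- sort(unique(out$imputed_ki$ki_imputed))
    ms_kis <- sort(unique(ms_peaks$ms_ki))
    cand <- candidate_matches(fid_kis, ms_kis)
    out$match <- assign_spectra(cand)
    emit("matches", out$match$accepted)
  }
  if ("screen" %in% stages) {
    out$screen <- lapply(tables, screen_dataset, fdr_level = fdr_level)
    for (nm in names(out$screen))
      if (nrow(out$screen[[nm]]$results))
        emit(paste0("screen_", nm), out$screen[[nm]]$results)
  }
  if ("multivariate" %in% stages) {
    out$permanova <- list()
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      for (rng in c("short", "mid", "long")) {
        res <- tryCatch({
          d <- distance_matrix(tab, range = rng)
          permanova(d, tab$samples["line"], n_perm = n_perm, seed = seed)
        }, error = function(e) NULL)
        if (!is.null(res)) out$permanova[[paste(nm, rng, sep = ".")]] <- res
      }
    }
    perm_tab <- do.call(rbind, lapply(names(out$permanova), function(k)
      cbind(analysis = k, out$permanova[[k]])))
    if (!is.null(perm_tab)) emit("permanova", perm_tab)
  }
  if (!is.null(out_dir)) {
    manifest <- list(
      package = "glandvolatiles",
      version = as.character(utils::packageVersion("glandvolatiles")),
      seed = seed,
      stages = stages,
      timestamp_free = TRUE,  # manifest content is deterministic given config
      config_hash = config_hash(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  # small rolling hash; avoids a digest dependency for a provenance string
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Calibrator pairs from the simulation's true Rt-KI map
#'
#' Returns 15 (rt, KI) pairs spread over the run - anchoring both linear
#' regions and the curved mid region - with unit KI noise, playing the role
#' of compounds identified against authentic standards on both platforms.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_study()] (kept for
#'   interface symmetry; the calibrators depend only on the config's true
#'   map and seed).
#' @return data.frame `(rt, ki, name)`.
#' @export
truth_calibrators <- function(config, truth) {
  set.seed(config$seed + 2L)
  rts <- c(seq(5, 12.5, length.out = 7), 13.59, 14.5, 15.5, 16.5, 17.37,
           18.5, 19.5, 20.5)
  cal <- data.frame(rt = rts,
                    ki = round(true_ki_map(config, rts) +
                                 stats::rnorm(length(rts), 0, 1)),
                    name = sprintf("standard-%02d", seq_along(rts)),
                    stringsAsFactors = FALSE)
  cal
}
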
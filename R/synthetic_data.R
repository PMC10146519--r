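#' Configuration for the synthetic study generator
#'
#' Defaults emulate the design of the isofemale-line volatile study: 23
#' recently collected isofemale lines spread over 7 source localities plus
#' one long-domesticated line, up to 4 screened generations with 1-4
#' replicate cages each, four sex/mating-history categories, ~150 peaks on a
#' retention-time grid spanning 4.6-21 min with sex-specific presence
#' patterns, log-scale line effects on a subset of peaks, detection
#' censoring producing zeros, mild batch scale factors, and a curved true
#' Rt-KI map with cross-platform index noise.
#'
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @param lines_per_locality integer vector, one entry per locality.
#' @param domesticated include a domesticated line (always sampled, larger
#'   positive line effects)?
#' @param generations generations screened.
#' @param reps_per_generation integer vector of candidate replicate-cage
#'   counts per line x generation (sampled with `rep_probs`); a single value
#'   gives balanced replication.
#' @param rep_probs sampling weights over `reps_per_generation`.
#' @param categories subset of
#'   `c("virgin_male", "mixed_male", "virgin_female", "mixed_female")`.
#' @param n_peaks number of FID peaks.
#' @param rt_min,rt_max retention-time grid limits (minutes).
#' @param frac_sex_specific fraction of peaks produced by one sex only
#'   (two-thirds of them male-specific, as male-biased profiles dominate
#'   this gland).
#' @param frac_line_affected fraction of peaks given heritable line effects.
#' @param line_effect_sd line-effect scale in units of the residual SD.
#' @param domesticated_multiplier multiplier on the domesticated line's
#'   (positive) effect for affected peaks.
#' @param baseline_mean,baseline_sd log10-area baseline distribution.
#' @param sex_shift_sd SD of the log10 male-female shift for shared peaks.
#' @param residual_sd within-cage residual SD, log10 units.
#' @param gen_jitter_sd SD of the line x generation jitter, log10 units.
#' @param batch_log_sd SD of the per-batch log10 scale factor (batches are
#'   the screened generations).
#' @param detection_threshold areas below this are recorded as 0.
#' @param ki_knots matrix-like of (rt, ki) knots of the true piecewise-linear
#'   Rt-KI map.
#' @param ki_noise_sd SD of the cross-platform KI measurement noise.
#' @param frac_shared fraction of FID peaks also observed on the MS side.
#' @param frac_ms_extra platform-specific MS peaks, as a fraction of
#'   `n_peaks`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       lines_per_locality = c(3, 3, 3, 4, 4, 3, 3),
                       domesticated = TRUE,
                       generations = c(6, 8, 10, 12),
                       reps_per_generation = 1:4,
                       rep_probs = c(0.55, 0.25, 0.15, 0.05),
                       categories = c("virgin_male", "mixed_male",
                                      "virgin_female", "mixed_female"),
                       n_peaks = 150,
                       rt_min = 4.6, rt_max = 21,
                       frac_sex_specific = 0.45,
                       frac_line_affected = 0.1,
                       line_effect_sd = 2,
                       domesticated_multiplier = 2,
                       baseline_mean = 3.2, baseline_sd = 1.0,
                       sex_shift_sd = 0.5,
                       residual_sd = 0.3,
                       gen_jitter_sd = 0.1,
                       batch_log_sd = 0.05,
                       detection_threshold = 100,
                       ki_knots = cbind(rt = c(4.6, 10.4, 13.6, 21),
                                        ki = c(840, 1096, 1241, 2175)),
                       ki_noise_sd = 1.5,
                       frac_shared = 0.5,
                       frac_ms_extra = 0.1) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("frac_sex_specific", "frac_line_affected",
                             "frac_shared", "frac_ms_extra")]) >= 0),
            all(unlist(cfg[c("frac_sex_specific", "frac_line_affected",
                             "frac_shared", "frac_ms_extra")]) <= 1),
            cfg$line_effect_sd >= 0, cfg$residual_sd > 0,
            cfg$rt_min >= 4.6, cfg$rt_max <= 21,
            length(rep_probs) == length(reps_per_generation) ||
              length(reps_per_generation) == 1)
  structure(cfg, class = "sim_config")
}

true_ki_map <- function(config, rt) {
  k <- as.data.frame(config$ki_knots)
  stats::approx(k$rt, k$ki, xout = rt, rule = 2)$y
}

#' Simulate a full study with known ground truth
#'
#' Areas are drawn log-normally: `log10(area) = peak baseline + sex effect +
#' line effect + generation jitter + batch log-factor + residual noise`,
#' then left-censored to 0 below the detection threshold. Sex-specific peaks
#' are structurally absent in the other sex. Replication is unbalanced per
#' line x generation as configured. The returned truth records every
#' injected effect.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (named list of per-category `peak_table`s) and
#'   `truth` (list: `peaks` data.frame, `line_effects` matrix, `lines`
#'   data.frame with localities, `batch_log_factors`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_loc <- length(config$lines_per_locality)
  localities <- sprintf("L%02d", seq_len(n_loc))
  lines <- unlist(lapply(seq_len(n_loc), function(i)
    sprintf("%s-%02d", localities[i], seq_len(config$lines_per_locality[i]))))
  line_loc <- rep(localities, config$lines_per_locality)
  if (config$domesticated) {
    lines <- c(lines, "DOM")
    line_loc <- c(line_loc, localities[1])
  }
  n_lines <- length(lines)

  n_peaks <- config$n_peaks
  # peaks are placed near-regularly on the Kovats scale (real lists are
  # dense in Rt late in the run but roughly even in KI) and mapped back to
  # Rt through the true calibration; upstream alignment merges anything
  # closer than its Rt tolerance, so resolvable lists keep a minimum spacing
  kk <- as.data.frame(config$ki_knots)
  ki_lo <- min(kk$ki); ki_hi <- max(kk$ki)
  step <- (ki_hi - ki_lo) / (n_peaks - 1)
  ki_grid <- sort(seq(ki_lo, ki_hi, length.out = n_peaks) +
                    stats::runif(n_peaks, -0.2 * step, 0.2 * step))
  rt <- stats::approx(kk$ki, kk$rt, xout = ki_grid, rule = 2)$y
  rt <- pmin(pmax(rt, config$rt_min), config$rt_max - 0.01)
  rt <- sort(round(rt, 2))
  while (anyDuplicated(rt)) {  # 2-dp labels: nudge clashes to stay unique
    dup <- which(duplicated(rt))
    rt[dup] <- rt[dup] + 0.01
    rt <- sort(round(rt, 2))
  }
  sex_pattern <- sample(c("male_specific", "female_specific", "shared"),
                        n_peaks, replace = TRUE,
                        prob = c(2 / 3 * config$frac_sex_specific,
                                 1 / 3 * config$frac_sex_specific,
                                 1 - config$frac_sex_specific))
  baseline <- stats::rnorm(n_peaks, config$baseline_mean, config$baseline_sd)
  sex_shift <- ifelse(sex_pattern == "shared",
                      stats::rnorm(n_peaks, 0, config$sex_shift_sd), 0)
  affected <- stats::runif(n_peaks) < config$frac_line_affected
  eff_sd <- config$line_effect_sd * config$residual_sd
  line_effects <- matrix(0, n_peaks, n_lines, dimnames = list(NULL, lines))
  for (p in which(affected)) {
    line_effects[p, ] <- stats::rnorm(n_lines, 0, eff_sd)
    if (config$domesticated)
      line_effects[p, "DOM"] <-
        abs(stats::rnorm(1, 0, eff_sd)) * config$domesticated_multiplier
  }
  gens <- config$generations
  batch_logf <- stats::setNames(stats::rnorm(length(gens), 0, config$batch_log_sd),
                                paste0("B", seq_along(gens)))

  make_category <- function(category) {
    sex <- if (grepl("male$", category) && !grepl("female", category))
      "male" else "female"
    mating <- if (grepl("^virgin", category)) "virgin" else "mixed"
    recs <- list()
    for (li in seq_len(n_lines)) for (gi in seq_along(gens)) {
      n_rep <- if (length(config$reps_per_generation) == 1)
        config$reps_per_generation
      else sample(config$reps_per_generation, 1, prob = config$rep_probs)
      for (r in seq_len(n_rep))
        recs[[length(recs) + 1]] <-
          data.frame(line = lines[li], locality = line_loc[li],
                     generation = gens[gi], cage = paste0("C", r),
                     sex = sex, mating = mating,
                     batch = paste0("B", gi), stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, recs)
    samples$sample_id <- sprintf("%s_%s_g%d_%s", category, samples$line,
                                 samples$generation, samples$cage)
    n <- nrow(samples)
    log_area <- matrix(rep(baseline, each = n), n, n_peaks)
    if (sex == "male") log_area <- log_area + rep(sex_shift / 2, each = n)
    else log_area <- log_area - rep(sex_shift / 2, each = n)
    li_idx <- match(samples$line, lines)
    log_area <- log_area + t(line_effects)[li_idx, , drop = FALSE]
    gj <- matrix(stats::rnorm(n_lines * length(gens) * n_peaks,
                              0, config$gen_jitter_sd),
                 n_lines * length(gens), n_peaks)
    cell <- (li_idx - 1) * length(gens) + match(samples$generation, gens)
    log_area <- log_area + gj[cell, , drop = FALSE]
    log_area <- log_area + batch_logf[samples$batch]
    log_area <- log_area + matrix(stats::rnorm(n * n_peaks, 0, config$residual_sd),
                                  n, n_peaks)
    area <- 10^log_area
    absent_sex <- if (sex == "male") "female_specific" else "male_specific"
    area[, sex_pattern == absent_sex] <- 0
    area[area < config$detection_threshold] <- 0
    peak_table(samples, rt, area, label_type = "rt", dataset_tag = category)
  }

  tables <- lapply(config$categories, make_category)
  names(tables) <- config$categories
  truth <- list(
    peaks = data.frame(rt = rt, true_ki = round(true_ki_map(config, rt)),
                       sex_pattern = sex_pattern, baseline = baseline,
                       sex_shift = sex_shift, line_affected = affected,
                       stringsAsFactors = FALSE),
    line_effects = line_effects,
    lines = data.frame(line = lines, locality = line_loc,
                       domesticated = lines == "DOM",
                       stringsAsFactors = FALSE),
    batch_log_factors = batch_logf)
  list(tables = tables, truth = truth)
}

#' Simulate the MS-side peak list for cross-platform matching
#'
#' A configured fraction of the FID peaks is re-observed on the MS platform
#' with Gaussian Kovats-index noise, plus platform-specific extra peaks.
#' Detection patterns carry over from the truth's sex patterns, so
#' compatibility ratings of true pairs are predictable.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_study()].
#' @return data.frame `(ms_ki, source_rt, shared, sex_pattern)`, sorted by
#'   `ms_ki` with duplicate indices dropped.
#' @export
simulate_gcms <- function(config, truth) {
  set.seed(config$seed + 1L)
  pk <- truth$peaks
  shared_idx <- sort(sample(nrow(pk), round(config$frac_shared * nrow(pk))))
  ms <- data.frame(
    ms_ki = round(pk$true_ki[shared_idx] +
                    stats::rnorm(length(shared_idx), 0, config$ki_noise_sd)),
    source_rt = pk$rt[shared_idx],
    shared = TRUE,
    sex_pattern = pk$sex_pattern[shared_idx],
    stringsAsFactors = FALSE)
  n_extra <- round(config$frac_ms_extra * nrow(pk))
  if (n_extra > 0) {
    extra <- data.frame(
      ms_ki = round(stats::runif(n_extra, min(pk$true_ki), max(pk$true_ki))),
      source_rt = NA_real_, shared = FALSE,
      sex_pattern = sample(c("male_specific", "female_specific", "shared"),
                           n_extra, replace = TRUE),
      stringsAsFactors = FALSE)
    ms <- rbind(ms, extra)
  }
  ms <- ms[order(ms$ms_ki), ]
  ms <- ms[!duplicated(ms$ms_ki), ]
  rownames(ms) <- NULL
  ms
}

#' The 19-pair worked-example fixture of matched FID/MS peaks
#'
#' The printed table of 19 previously anonymous GC-FID peaks matched to
#' GC-MS peaks by imputed vs observed Kovats index (tolerance 4, adjacency
#' and abundance compatibility), with their confirmed or tentative
#' identities where available.
#'
#' @return data.frame `(rt, ki_imp, ki_obs, identity, identity_status,
#'   line_variable)` with 19 rows.
#' @export
fixture_table4 <- function() {
  out <- data.frame(
    rt = c(5.20, 6.21, 6.30, 6.64, 7.08, 8.06, 9.58, 10.05, 11.16, 11.46,
           11.50, 11.70, 11.93, 11.97, 13.88, 13.95, 14.37, 17.07, 17.17),
    ki_imp = c(885, 933, 937, 953, 974, 1021, 1093, 1115, 1161, 1171,
               1172, 1179, 1185, 1186, 1252, 1254, 1267, 1463, 1482),
    ki_obs = c(883, 933, 939, 955, 972, 1019, 1094, 1115, 1164, 1171,
               1173, 1179, 1187, 1188, 1253, 1256, 1267, 1464, 1484),
    identity = c("2-Methyl-3-hexanol", "Ethyl 2-methylpentanoate",
                 "x-Octenal isomer 2", "n-Butylcyclopentane", "Phenol",
                 "n-Octen-1-ol", "N-(2-Methylpropyl) propanamide",
                 NA, NA, "2-Bornanone", NA, "Borneol isomer 1",
                 "Borneol isomer 2", NA, NA, NA, NA, NA, NA),
    identity_status = c("tentative", "validated", "validated", "tentative",
                        "tentative", "validated", "validated", NA, NA,
                        "validated", NA, "tentative", "tentative",
                        NA, NA, NA, NA, NA, NA),
    line_variable = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out
}
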
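#!/usr/bin/env Rscript

# Stage 1: generate the study. A synthetic common-garden design shaped like
# the real one — 23 isofemale lines from 7 localities plus one domesticated
# line, four sex/mating-history categories, up to 4 screened generations
# with 1-4 replicate cages, ~150 peaks with sex-specific presence patterns,
# line effects on a subset of peaks, batch scale factors and detection
# censoring — written out as deposited-style CSVs with the ground truth
# alongside.

suppressMessages(library(glandvolatiles))

seed <- 428L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_study(cfg)

for (nm in names(sim$tables)) {
  path <- file.path(out, paste0(nm, ".csv"))
  write_peak_table(sim$tables[[nm]], path)
  cat(sprintf("wrote %-28s %3d samples x %d peaks\n", path,
              nrow(sim$tables[[nm]]$samples),
              length(sim$tables[[nm]]$peak_labels)))
}

ms <- simulate_gcms(cfg, sim$truth)
write.csv(ms, file.path(out, "ms_peaks.csv"), row.names = FALSE)
cal <- truth_calibrators(cfg, sim$truth)
write.csv(cal, file.path(out, "calibrators.csv"), row.names = FALSE)

jsonlite::write_json(
  list(seed = seed,
       peaks = sim$truth$peaks,
       lines = sim$truth$lines,
       line_effects = as.data.frame(sim$truth$line_effects)),
  file.path(out, "truth.json"))

n_aff <- sum(sim$truth$peaks$line_affected)
cat(sprintf("truth: %d of %d peaks carry line effects; %d MS peaks (%d shared)\n",
            n_aff, nrow(sim$truth$peaks), nrow(ms), sum(ms$shared)))
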
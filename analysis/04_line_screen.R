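#!/usr/bin/env Rscript

# Stage 4: the heritable-line-variation screen, per category: inclusion
# filter (detected in >= 50% of samples of some line x category cell),
# rank-normal transformation, one-way line F test, BH-FDR across the peaks
# of the dataset, marginal means with letters for significant peaks. Then
# the elution-range enrichment test on the significant counts and the
# Spearman correlation structure of the significant peaks' line means.

suppressMessages(library(glandvolatiles))

data_dir <- "results/data"
categories <- c("virgin_male", "mixed_male", "virgin_female", "mixed_female")
tables <- lapply(categories, function(nm)
  normalize_batches(read_peak_table(file.path(data_dir, paste0(nm, ".csv")),
                                    dataset_tag = nm)))
names(tables) <- categories

screens <- list()
for (nm in categories) {
  scr <- screen_dataset(tables[[nm]])
  screens[[nm]] <- scr
  write.table(scr$results, sprintf("results/screen_%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("%-14s %3d peaks tested, %2d FDR-significant\n", nm,
              scr$n_tested, sum(scr$results$significant)))
  for (peak in names(scr$emmeans)) {
    em <- scr$emmeans[[peak]]
    write.table(em, sprintf("results/emmeans_%s_%.2f.tsv", nm,
                            as.numeric(peak)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
}

# enrichment of significant peaks across elution ranges, male datasets pooled
male <- c("virgin_male", "mixed_male")
sig_labels <- unique(unlist(lapply(screens[male], function(s)
  s$results$peak_label[s$results$significant])))
all_labels <- unique(unlist(lapply(screens[male], function(s)
  s$results$peak_label)))
if (length(sig_labels) >= 3) {
  obs <- table(factor(rt_range(sig_labels), c("short", "mid", "long")))
  ref <- table(factor(rt_range(all_labels), c("short", "mid", "long")))
  if (all(ref > 0) && sum(obs) > 0) {
    et <- enrichment_test(as.integer(obs), as.integer(ref))
    cat(sprintf("range enrichment: chi2 = %.2f, df = %d, p = %.3g\n",
                et$statistic, et$df, et$p.value))
  }
}

# correlation structure of significant virgin-male peaks across line means
scr_vm <- screens$virgin_male
sig_vm <- scr_vm$results$peak_label[scr_vm$results$significant]
if (length(sig_vm) >= 2) {
  t_vm <- tables$virgin_male
  line_means <- t(sapply(sig_vm, function(lab) {
    j <- which(abs(t_vm$peak_labels - lab) < 5e-3)
    tapply(t_vm$areas[, j], t_vm$samples$line, mean)
  }))
  rownames(line_means) <- sprintf("%.2f", sig_vm)
  cors <- spearman_screen(line_means)
  cors_no_dom <- spearman_screen(line_means, exclude = "DOM")
  write.table(cors, "results/spearman_with_dom.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cors_no_dom, "results/spearman_without_dom.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("correlations among %d significant peaks: %d FDR-significant with the domesticated line, %d without\n",
              length(sig_vm), sum(cors$p_fdr < 0.05, na.rm = TRUE),
              sum(cors_no_dom$p_fdr < 0.05, na.rm = TRUE)))
}
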
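# in-code fixtures: tiny peak tables with fully known structure

tiny_samples <- function(n, line = "AS09", sex = "male", mating = "mixed",
                         batch = "B1", generation = 6) {
  data.frame(sample_id = sprintf("%s_%s_%02d", line, sex, seq_len(n)),
             line = line, locality = substr(line, 1, 2),
             generation = generation, cage = paste0("C", seq_len(n)),
             sex = sex, mating = mating, batch = batch,
             stringsAsFactors = FALSE)
}

tiny_table <- function(areas, labels = NULL, samples = NULL, ...) {
  areas <- as.matrix(areas)
  if (is.null(labels)) labels <- 4.60 + 0.1 * seq_len(ncol(areas))
  if (is.null(samples)) samples <- tiny_samples(nrow(areas), ...)
  peak_table(samples, labels, areas, label_type = "rt")
}

# stack single-line tables into a multi-line table
multi_line_table <- function(areas_by_line, labels = NULL, sex = "male",
                             mating = "mixed") {
  lines <- names(areas_by_line)
  samples <- do.call(rbind, lapply(lines, function(l)
    tiny_samples(nrow(areas_by_line[[l]]), line = l, sex = sex, mating = mating)))
  samples$sample_id <- sprintf("s%03d", seq_len(nrow(samples)))
  areas <- do.call(rbind, areas_by_line)
  if (is.null(labels)) labels <- 4.60 + 0.1 * seq_len(ncol(areas))
  peak_table(samples, labels, areas, label_type = "rt")
}

# presence-code literal for compatibility-rating tests
code_lit <- function(male, female, mean_male = NA, mean_female = NA) {
  list(male = male, female = female,
       bias = "none", mean_male = mean_male, mean_female = mean_female)
}

# definition-based O(n^2) matching oracle, independent of the sorted-adjacency
# implementation: a pair is accepted iff within tol and strictly closer than
# every alternative pairing for both peaks
brute_force_matches <- function(fid, ms, tol = 4) {
  pairs <- list()
  for (i in seq_along(fid)) for (j in seq_along(ms)) {
    delta <- abs(fid[i] - ms[j])
    if (delta > tol) next
    alt_f <- abs(fid[i] - ms[-j])
    alt_m <- abs(ms[j] - fid[-i])
    if (all(delta < alt_f) && all(delta < alt_m))
      pairs[[length(pairs) + 1]] <- c(fid = fid[i], ms = ms[j])
  }
  if (length(pairs) == 0)
    return(data.frame(fid = numeric(), ms = numeric()))
  out <- as.data.frame(do.call(rbind, pairs))
  out[order(out$fid), ]
}
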
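test_that("rank-normal scores match the normal-quantile oracle", {
  map <- ordernorm_fit(c(5, 1, 9))
  z <- ordernorm_transform(map, c(5, 1, 9))
  expect_equal(z, qnorm(c(3, 1, 5) / 6), tolerance = 1e-4)
  expect_equal(z, c(0, -0.9674, 0.9674), tolerance = 1e-4)
})

test_that("training scores have mean zero and variance near one", {
  set.seed(2)
  for (n in c(10, 50, 200)) {
    x <- rlnorm(n)
    map <- ordernorm_fit(x)
    z <- ordernorm_transform(map, x)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(var(z), 1, tolerance = 0.1)
  }
})

test_that("the transform is rank-preserving and invertible on training data", {
  set.seed(3)
  x <- runif(100, 0, 1e5)
  map <- ordernorm_fit(x)
  z <- ordernorm_transform(map, x)
  expect_equal(rank(z), rank(x))
  expect_equal(ordernorm_inverse(map, z), x, tolerance = 1e-9)
  # ties map to their group representative and back to a single value
  xt <- c(2, 2, 7, 9)
  mt <- ordernorm_fit(xt)
  zt <- ordernorm_transform(mt, xt)
  expect_equal(zt[1], zt[2])
  expect_equal(ordernorm_inverse(mt, zt), c(2, 2, 7, 9))
  expect_error(ordernorm_fit(c(3, 3, 3)), "constant")
  # inverse clamps beyond the training range
  expect_equal(ordernorm_inverse(mt, 10), 9)
})

test_that("the one-way F test matches brute-force sums of squares", {
  set.seed(14)
  values <- rnorm(18, rep(c(0, 0.5, 2), each = 6))
  lines <- rep(c("A", "B", "C"), each = 6)
  res <- fit_line_model(values, lines)
  gm <- mean(values)
  ssb <- sum(tapply(values, lines, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, lines, function(v) sum((v - mean(v))^2)))
  f_brute <- (ssb / 2) / (ssw / 15)
  expect_equal(res$F, f_brute, tolerance = 1e-9)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 15)
  expect_equal(res$p, pf(f_brute, 2, 15, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("degenerate designs are flagged or refused", {
  res <- fit_line_model(c(0, 0, 1, 1), c("A", "A", "B", "B"))
  expect_true(res$degenerate)
  expect_equal(res$F, Inf)
  expect_error(fit_line_model(c(1, 2), c("A", "B")), "no replication")
  expect_error(fit_line_model(c(1, 2, 3), c("A", "A", "A")), ">= 2 lines")
})

test_that("the F statistic is invariant to line relabeling and row order", {
  set.seed(8)
  values <- rnorm(20)
  lines <- sample(c("AS09", "CT07", "SY13", "S06"), 20, replace = TRUE,
                  prob = c(0.3, 0.3, 0.2, 0.2))
  ref <- fit_line_model(values, lines)$F
  relabel <- c(AS09 = "z9", CT07 = "a1", SY13 = "m5", S06 = "q2")
  expect_equal(fit_line_model(values, relabel[lines])$F, ref)
  perm <- sample(20)
  expect_equal(fit_line_model(values[perm], lines[perm])$F, ref)
})

test_that("the raw F test holds its nominal size", {
  set.seed(101)
  n_sim <- 1000
  p <- numeric(n_sim)
  lines <- rep(c("A", "B", "C"), each = 4)
  for (i in seq_len(n_sim))
    p[i] <- fit_line_model(rnorm(12), lines)$p
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("BH adjustment reproduces the hand step-up and its invariants", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(6)
  p <- runif(40)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # the FDR-significant set is nested in the raw-significant set
  expect_true(all(which(q < 0.05) %in% which(p < 0.05)))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("marginal means equal line means on balanced data and back-transform", {
  set.seed(31)
  x <- rlnorm(20, rep(c(4, 5), each = 10))
  lines <- rep(c("A", "B"), each = 10)
  map <- ordernorm_fit(x)
  z <- ordernorm_transform(map, x)
  fm <- fit_line_model(z, lines)
  mm <- marginal_means(fm, map = map)
  expect_equal(mm$emmean, as.vector(tapply(z, lines, mean)), tolerance = 1e-9)
  # the back-transform inverts the map at the emmean
  expect_equal(mm$response, ordernorm_inverse(map, mm$emmean))
  # CI width shrinks like 1/sqrt(n) on balanced data with a common MSE
  w <- mm$upper - mm$lower
  expect_equal(w[1], w[2], tolerance = 1e-9)
})

test_that("letters: homogeneous lines share one letter, separated groups split", {
  set.seed(41)
  z <- rnorm(20)
  fm <- fit_line_model(z, rep(c("A", "B", "C", "D"), each = 5))
  lt <- pairwise_letters(fm)
  expect_true(all(lt == "a"))
  z2 <- rnorm(20) + rep(c(0, 0, 50, 50), each = 5)  # two well-separated groups
  fm2 <- fit_line_model(z2, rep(c("A", "B", "C", "D"), each = 5))
  lt2 <- pairwise_letters(fm2)
  expect_equal(unname(lt2[c("C", "D")]), c("a", "a"))
  expect_equal(unname(lt2[c("A", "B")]), c("b", "b"))
})

test_that("letter displays encode every 5-level significance graph exactly", {
  lev <- paste0("L", 1:5)
  pairs <- t(combn(5, 2))
  for (mask in 0:1023) {  # every subset of the 10 pairs significant
    sig <- matrix(FALSE, 5, 5, dimnames = list(lev, lev))
    bits <- bitwAnd(bitwShiftR(mask, 0:9), 1) == 1
    for (k in which(bits)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      sig[i, j] <- sig[j, i] <- TRUE
    }
    lt <- letters_from_significance(sig)
    share <- outer(lt, lt, Vectorize(function(a, b)
      length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0))
    for (k in seq_len(nrow(pairs))) {
      i <- lev[pairs[k, 1]]; j <- lev[pairs[k, 2]]
      expect_equal(unname(share[i, j]), !sig[i, j],
                   label = sprintf("mask %d pair %s-%s", mask, i, j))
    }
  }
})

test_that("Spearman screen matches the rank-formula oracle and handles edges", {
  m <- rbind(a = 1:10, b = (1:10)^2, c = rev(1:10))
  colnames(m) <- paste0("line", 1:10)
  res <- spearman_screen(m)
  r_ab <- res$rho[res$peak1 == "a" & res$peak2 == "b"]
  expect_equal(r_ab, 1)  # monotone transform of the same ranks
  r_ac <- res$rho[res$peak1 == "a" & res$peak2 == "c"]
  expect_equal(r_ac, -1)
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10)
  m2 <- rbind(x = x, y = y)
  colnames(m2) <- paste0("l", 1:10)
  res2 <- spearman_screen(m2)
  d <- rank(x) - rank(y)
  expect_equal(res2$rho, 1 - 6 * sum(d^2) / (10 * 99), tolerance = 1e-9)
  # constant vector reported as missing; excluded line honoured
  m3 <- rbind(a = rep(1, 5), b = 1:5)
  colnames(m3) <- paste0("l", 1:5)
  expect_true(is.na(spearman_screen(m3)$rho))
  expect_equal(spearman_screen(m, exclude = "line1")$n[1], 9)
})

test_that("the screen finds injected line effects and respects the null", {
  cfg_null <- sim_config(seed = 77, n_peaks = 60, frac_line_affected = 0,
                         lines_per_locality = c(3, 3), domesticated = FALSE,
                         generations = c(6, 8), reps_per_generation = 3,
                         categories = "mixed_male")
  scr0 <- screen_dataset(simulate_study(cfg_null)$tables$mixed_male,
                         letters = FALSE)
  expect_lte(sum(scr0$results$significant), 2)
  cfg_eff <- sim_config(seed = 78, n_peaks = 60, frac_line_affected = 0.15,
                        line_effect_sd = 2, generations = 6,
                        reps_per_generation = 5, categories = "mixed_male")
  sim <- simulate_study(cfg_eff)
  scr1 <- screen_dataset(sim$tables$mixed_male, letters = FALSE)
  truly <- sim$truth$peaks$rt[sim$truth$peaks$line_affected]
  hit <- sum(scr1$results$peak_label[scr1$results$significant] %in% truly)
  expect_gte(hit / length(truly), 0.8)
})
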
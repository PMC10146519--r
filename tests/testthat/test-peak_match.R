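test_that("a single close pair is accepted with its distance", {
  cand <- candidate_matches(885, 883)
  expect_equal(nrow(cand), 1)
  expect_true(cand$accepted)
  expect_equal(cand$delta, 2)
})

test_that("identical lists all match at distance zero", {
  kis <- c(900, 950, 1000, 1100)
  cand <- candidate_matches(kis, kis)
  expect_true(all(cand$accepted))
  expect_equal(cand$delta, rep(0, 4))
})

test_that("an equidistant tie with adjacent alternatives rejects the pair", {
  cand <- candidate_matches(1000, c(997, 1003))
  expect_false(any(cand$accepted))
  expect_equal(cand$reason[!cand$accepted], "adjacency")
})

test_that("matching agrees with the definition-based oracle on small instances", {
  set.seed(99)
  for (i in 1:200) {
    nf <- sample(1:10, 1); nm <- sample(1:10, 1)
    fid <- sort(sample(800:1200, nf))
    ms <- sort(sample(800:1200, nm))
    cand <- candidate_matches(fid, ms, tol = 4)
    got <- cand[cand$accepted, c("fid_ki", "ms_ki")]
    got <- got[order(got$fid_ki), ]
    want <- brute_force_matches(fid, ms, tol = 4)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 label = sprintf("instance %d", i))
  }
})

test_that("matching is symmetric and monotone in the tolerance", {
  set.seed(7)
  for (i in 1:30) {
    fid <- sort(sample(800:1100, 12))
    ms <- sort(sample(800:1100, 9))
    a <- candidate_matches(fid, ms, tol = 4)
    b <- candidate_matches(ms, fid, tol = 4)
    pa <- data.frame(f = a$fid_ki[a$accepted], m = a$ms_ki[a$accepted])
    pb <- data.frame(f = b$ms_ki[b$accepted], m = b$fid_ki[b$accepted])
    expect_equal(unname(as.matrix(pa[order(pa$f), ])),
                 unname(as.matrix(pb[order(pb$f), ])))
    prev <- 0
    for (tol in c(1, 2, 4, 8)) {
      n_acc <- sum(candidate_matches(fid, ms, tol = tol)$accepted)
      expect_gte(n_acc, prev)
      prev <- n_acc
    }
  }
})

test_that("presence codes capture detection and fold bias", {
  m <- function(v) tiny_table(matrix(v, ncol = 1), labels = 5, sex = "male")
  f <- function(v) tiny_table(matrix(v, ncol = 1), labels = 5, sex = "female")
  pc <- presence_code(m(rep(10, 6)), f(rep(0, 4)), 5)
  expect_equal(pc$male, "ALL"); expect_equal(pc$female, "ND")
  expect_equal(pc$bias, "none")  # fold bias needs both means nonzero
  pc2 <- presence_code(m(c(5, 8, 0, 0, 0)), f(rep(1, 3)), 5)
  expect_equal(pc2$male, "SOME")
  pc3 <- presence_code(m(rep(2000, 3)), f(rep(150, 3)), 5)
  expect_equal(pc3$bias, "male>10x")  # ratio 13.3 >= 10
  pc4 <- presence_code(NULL, f(10), 5)
  expect_equal(pc4$male, "NA")
})

test_that("compatibility ratings implement the YY/Y/N rules", {
  # identical male-specific codes on both platforms in both sample types
  fid <- list(virgin = code_lit("ALL", "ND", 100, 0),
              mixed = code_lit("ALL", "ND", 100, 0))
  expect_equal(compatibility_rating(fid, fid, "intermediate"), "YY")
  # ALL vs SOME never breaks YY
  ms <- list(virgin = code_lit("SOME", "ND", 80, 0),
             mixed = code_lit("ALL", "ND", 90, 0))
  expect_equal(compatibility_rating(fid, ms, "major"), "YY")
  # one side not assayed is compatible
  ms_na <- list(virgin = code_lit("NA", "NA"), mixed = code_lit("ALL", "ND", 5, 0))
  expect_equal(compatibility_rating(fid, ms_na, "minor"), "YY")
  # presence/absence difference forgiven when presence is SOME and peak minor
  fid2 <- list(virgin = code_lit("SOME", "ND", 10, 0),
               mixed = code_lit("ND", "ND"))
  ms2 <- list(virgin = code_lit("ND", "ND"), mixed = code_lit("ND", "ND"))
  expect_equal(compatibility_rating(fid2, ms2, "minor"), "Y")
  expect_equal(compatibility_rating(fid2, ms2, "intermediate"), "N")
  # ... or when the presence keeps a >10-fold bias toward the sex in question
  fid5 <- list(virgin = code_lit("SOME", "ALL", 5000, 100),
               mixed = code_lit("ALL", "ALL", 5000, 100))
  ms5 <- list(virgin = code_lit("ND", "ALL", 0, 100),
              mixed = code_lit("ALL", "ALL", 900, 80))
  expect_equal(compatibility_rating(fid5, ms5, "intermediate"), "Y")
  # same disagreement without the bias is incompatible
  fid6 <- list(virgin = code_lit("SOME", "ALL", 300, 100),
               mixed = code_lit("ALL", "ALL", 300, 100))
  expect_equal(compatibility_rating(fid6, ms5, "intermediate"), "N")
})

test_that("spectral assignment removes known identities and incompatibles", {
  set.seed(4)
  fid <- seq(800, 800 + 34 * 20, by = 20)  # 35 well-separated candidates
  ms <- fid + sample(c(-2, -1, 0, 1, 2), 35, replace = TRUE)
  cand <- candidate_matches(fid, sort(ms))
  expect_equal(sum(cand$accepted), 35)
  cand$rating <- "YY"
  cand$rating[cand$accepted][1:7] <- "N"
  known <- cand$fid_ki[cand$accepted][8:16]  # 9 already identified
  res <- assign_spectra(cand, already_identified = known)
  expect_equal(nrow(res$accepted), 19)
  expect_equal(nrow(res$already_identified), 9)
  expect_true(all(table(res$accepted$fid_ki) == 1))
  expect_true(all(table(res$accepted$ms_ki) == 1))
  # empty input
  empty <- candidate_matches(numeric(), numeric())
  res0 <- assign_spectra(empty)
  expect_equal(nrow(res0$accepted), 0)
})

test_that("noise-free simulated platforms match perfectly", {
  cfg <- sim_config(seed = 12, n_peaks = 60, ki_noise_sd = 0, frac_ms_extra = 0,
                    lines_per_locality = c(2, 2), generations = 6,
                    reps_per_generation = 2, categories = "mixed_male")
  sim <- simulate_study(cfg)
  ms <- simulate_gcms(cfg, sim$truth)
  fid_kis <- sort(unique(sim$truth$peaks$true_ki))
  cand <- candidate_matches(fid_kis, ms$ms_ki)
  hits <- cand[cand$accepted, ]
  expect_true(all(ms$ms_ki %in% hits$ms_ki))
  expect_true(all(hits$delta == 0))
})
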
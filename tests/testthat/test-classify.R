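test_that("elution ranges follow the stated boundaries on both scales", {
  expect_equal(rt_range(4.61), "short")
  expect_equal(rt_range(c(13.59, 13.60)), c("mid", "long"))
  expect_equal(rt_range(10.39), "short")
  expect_equal(rt_range(10.40), "mid")
  expect_equal(rt_range(1151, scale = "ki"), "mid")
  expect_equal(rt_range(c(840, 1095, 1096, 1241, 2175), scale = "ki"),
               c("short", "short", "mid", "long", "long"))
  expect_error(rt_range(3.5), "outside")
  expect_error(rt_range(2200, scale = "ki"), "outside")
})

test_that("inclusion filter retains peaks detected in half of some line cell", {
  # peak 1: 2/4 of AS09 (0.5 >= 0.5) -> retained; peak 2: never detected;
  # peak 3: 1/4 in one line, 1/3 in the other -> dropped at 0.5
  areas <- list(
    AS09 = cbind(c(10, 10, 0, 0), 0, c(5, 0, 0, 0)),
    S06  = cbind(c(0, 0, 0), 0, c(0, 4, 0)))
  t <- multi_line_table(areas)
  expect_equal(inclusion_filter(t), t$peak_labels[1])
  # with by_line off, cells are categories: peak1 2/7 < 0.5 -> dropped
  expect_equal(inclusion_filter(t, by_line = FALSE), numeric(0))
  # all-detected table retains everything
  t2 <- tiny_table(matrix(1, 4, 3))
  expect_equal(inclusion_filter(t2), t2$peak_labels)
})

test_that("inclusion filter is monotone in the threshold", {
  set.seed(11)
  for (rep in 1:20) {
    areas <- matrix(rbinom(60, 1, 0.4) * runif(60, 1, 100), nrow = 12)
    t <- multi_line_table(list(A = areas[1:6, ], B = areas[7:12, ]))
    prev <- t$peak_labels
    for (thr in c(0.2, 0.5, 0.8, 1)) {
      cur <- inclusion_filter(t, threshold = thr)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("abundance classes follow the maximum category share", {
  mk <- function(share) {
    # two peaks: target peak with given share of the category total
    tiny_table(cbind(share * 1000, (1 - share) * 1000), labels = c(5, 6))
  }
  tables <- list(mixed_male = mk(0.012), virgin_male = mk(0.001))
  expect_equal(as.character(abundance_class(tables, 5)), "major")
  tables2 <- list(a = mk(0.001), b = mk(0.0002))
  expect_equal(as.character(abundance_class(tables2, 5)), "intermediate")
  tables3 <- list(a = mk(0.0002), b = mk(0.0005), c = mk(0.0009), d = mk(0))
  expect_equal(as.character(abundance_class(tables3, 5)), "minor")
  expect_error(abundance_class(list(a = mk(0.5)), 99), "absent")
})

test_that("sex bias classification: specific, selective, none", {
  m <- function(v) tiny_table(matrix(v, ncol = 1), labels = 5, sex = "male")
  f <- function(v) tiny_table(matrix(v, ncol = 1), labels = 5, sex = "female")
  expect_equal(sex_bias_class(m(c(500, 500)), f(c(0, 0)), 5), "male_specific")
  expect_equal(sex_bias_class(m(c(1000, 1000)), f(c(50, 50)), 5), "male_selective")
  expect_equal(sex_bias_class(m(100), f(100), 5), "none")
  expect_equal(sex_bias_class(m(100), f(1000 + 1), 5), "female_selective")
  # exactly 10-fold is "none" (the rule is a strict log10 difference)
  expect_equal(sex_bias_class(m(1000), f(100), 5), "none")
  expect_equal(sex_bias_class(m(0), f(0), 5), "not_detected")
  expect_equal(sex_bias_class(NULL, f(10), 5), "not_assayed")
})

test_that("sex bias classification is antisymmetric under swapping sexes", {
  set.seed(5)
  swap <- c(male_specific = "female_specific", female_specific = "male_specific",
            male_selective = "female_selective", female_selective = "male_selective",
            none = "none", not_detected = "not_detected")
  m <- function(v, sex) tiny_table(matrix(v, ncol = 1), labels = 5, sex = sex)
  for (i in 1:25) {
    am <- rbinom(4, 1, 0.7) * 10^runif(4, 1, 4)
    af <- rbinom(4, 1, 0.7) * 10^runif(4, 1, 4)
    ab <- sex_bias_class(m(am, "male"), m(af, "female"), 5)
    ba <- sex_bias_class(m(af, "male"), m(am, "female"), 5)
    expect_equal(unname(swap[ab]), ba)
  }
})

test_that("enrichment test matches the brute-force goodness-of-fit sum", {
  res <- enrichment_test(c(11, 3, 12), c(31, 23, 147))
  brute <- function(obs, ref) {
    e <- sum(obs) * ref / sum(ref)
    sum((obs - e)^2 / e)
  }
  expect_equal(res$statistic, brute(c(11, 3, 12), c(31, 23, 147)),
               tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_lt(res$p.value, 0.001)
  # observed proportional to reference -> exactly zero
  expect_equal(enrichment_test(c(4, 8, 12), c(1, 2, 3))$statistic, 0)
  # abundance-class counts: gof ~ 2.096, contingency ~ 2.407 (both exposed;
  # neither equals a misprinted 2.36 and neither is forced to)
  expect_equal(enrichment_test(c(3, 13, 10), c(21, 75, 105))$statistic,
               brute(c(3, 13, 10), c(21, 75, 105)), tolerance = 1e-9)
  ct <- enrichment_test(c(3, 13, 10), c(21, 75, 105), method = "contingency")
  expect_equal(ct$statistic,
               unname(suppressWarnings(chisq.test(
                 rbind(c(3, 13, 10), c(18, 62, 95)), correct = FALSE)$statistic)),
               tolerance = 1e-9)
  expect_error(enrichment_test(c(1, 2), c(0, 5)), "positive")
})

test_that("classification summary counts match a constructed composition", {
  expect_equal(nrow(classification_summary(
    data.frame(peak_label = numeric(), rt_range = character(),
               abundance_class = character(), sex_bias_virgin = character(),
               sex_bias_mixed = character()))), 0)
  cls <- data.frame(
    peak_label = c(4.61, 4.70, 11.0, 18.0),
    rt_range = c("short", "short", "mid", "long"),
    abundance_class = c("major", "major", "minor", "minor"),
    sex_bias_virgin = c("male_specific", "male_specific", "none", "female_specific"),
    sex_bias_mixed = c("male_specific", "male_specific", "none", "female_specific"),
    stringsAsFactors = FALSE)
  cs <- classification_summary(cls)
  expect_equal(sum(cs$n), 4)
  row <- cs[cs$sex_bias_virgin == "male_specific" & cs$rt_range == "short", ]
  expect_equal(row$n, 2)
})

test_that("classify_peaks assembles per-peak classifications from tables", {
  cfg <- sim_config(seed = 8, n_peaks = 30, lines_per_locality = c(2, 2),
                    generations = 6, reps_per_generation = 3)
  tabs <- simulate_study(cfg)$tables
  cls <- classify_peaks(tabs)
  expect_equal(nrow(cls), 30)
  expect_true(all(cls$rt_range %in% c("short", "mid", "long")))
  expect_true(all(cls$abundance_class %in% c("major", "intermediate", "minor")))
})
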
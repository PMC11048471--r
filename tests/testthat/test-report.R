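test_that("per-condition success rates count accepted genuine comparisons", {
  sc <- scores_from_values(genuine_as = rep(0.785, 5),
                           impostor_as = c(0.5, 0.51))
  per <- success_rates(sc, reference_thresholds())
  expect_equal(per$n, 5)
  expect_equal(per$successes, 5)
  expect_equal(per$rate, 100)

  # threshold choice follows the condition's mask status
  sc_m <- scores_from_values(genuine_as = c(0.63, 0.65),
                             impostor_as = c(0.5), mask = "yes")
  per_m <- success_rates(sc_m, reference_thresholds())   # masked: 0.620
  expect_equal(per_m$rate, 100)
  per_u <- success_rates(sc_m, threshold_policy(0.642, 0.642))
  expect_equal(per_u$rate, 50)
})

test_that("aggregates pool integer counts exactly (arithmetic oracle)", {
  g <- tiny_gallery(n = 2, dim = 8)
  sc <- score_all_pairs(g)
  per <- success_rates(sc, reference_thresholds())
  # overwrite counts with hand-picked values, then check the pooling
  per$n <- 100L
  per$successes <- 100L
  per$successes[per$condition == "no.closed.supine.low"] <- 98L
  per$rate <- 100 * per$successes / per$n
  agg <- aggregate_rates(per)
  agg <- as.data.frame(agg)
  rownames(agg) <- agg$group
  expect_equal(agg["overall_unmasked", "n"], 800)
  expect_equal(agg["overall_unmasked", "successes"], 798)
  expect_equal(agg["overall_unmasked", "rate"], 99.75)
  expect_equal(agg["overall_masked", "rate"], 100)
  expect_equal(agg["adverse_unmasked", "n"], 700)
  expect_equal(agg["nighttime", "n"], 300)
  expect_equal(agg["nighttime", "successes"], 298)
  expect_equal(agg["nighttime", "rate"], 100 * 298 / 300)
  # pooled successes are the sums of their constituents
  fact_no <- per$mask == "no" & per$position %in% c("sitting", "supine")
  expect_identical(agg["overall_unmasked", "successes"],
                   sum(per$successes[fact_no]))

  incomplete <- per[per$condition != "no.closed.supine.low", ]
  class(incomplete) <- class(per)
  expect_error(aggregate_rates(incomplete), "incomplete")
})

test_that("welch_t matches stats::t.test on data with those exact moments", {
  set.seed(99)
  cases <- list(c(0.785, 0.004, 100, 0.508, 0.025, 100),
                c(0.7, 0.02, 50, 0.69, 0.03, 80),
                c(0.5, 0.1, 10, 0.4, 0.05, 12))
  for (cs in cases) {
    x <- exact_moments(cs[1], cs[2], cs[3])
    y <- exact_moments(cs[4], cs[5], cs[6])
    ref <- stats::t.test(x, y)
    w <- welch_t(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_two_sided, ref$p.value, tolerance = 1e-8)
  }
})

test_that("welch_t separates the standard genuine and impostor summaries", {
  w <- welch_t(0.785, 0.004, 100, 0.508, 0.025, 100)
  expect_equal(w$t_stat, 109.408, tolerance = 1e-4)
  expect_equal(w$df, 104.065, tolerance = 1e-4)
  expect_lt(w$p_two_sided, 1e-10)
})

test_that("welch_t symmetry, identity and degenerate cases", {
  same <- welch_t(0.7, 0.02, 30, 0.7, 0.02, 30)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_sided, 1)
  a <- welch_t(0.7, 0.02, 30, 0.6, 0.05, 40)
  b <- welch_t(0.6, 0.05, 40, 0.7, 0.02, 30)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_two_sided, b$p_two_sided)
  expect_error(welch_t(0.7, 0, 30, 0.6, 0, 40), "zero variance")
  expect_error(welch_t(0.7, 0.02, 1, 0.6, 0.05, 40), "sizes")
})

test_that("the analytic rate prediction matches a Monte-Carlo oracle", {
  expect_equal(predicted_success_rate(0.62, 0.027, 0.62), 0.5)
  expect_equal(predicted_success_rate(0.636, 0.027, 0.620), 0.7233,
               tolerance = 1e-3)
  expect_equal(predicted_success_rate(0.785, 0.004, 0.642), 1,
               tolerance = 1e-12)
  set.seed(8)
  mc <- mean(rnorm(4e5, 0.636, 0.027) > 0.620)
  expect_equal(predicted_success_rate(0.636, 0.027, 0.620), mc,
               tolerance = 3 * sqrt(0.72 * 0.28 / 4e5) / 0.72)
  expect_error(predicted_success_rate(0.7, 0, 0.6), "sigma")
})

test_that("simulated rates agree with the analytic oracle per condition", {
  # 2000 probe draws per condition give the binomial band enough
  # resolution near rates of ~99.97%
  set.seed(101)
  ref <- faceverify:::unit_normalize(rnorm(64))
  prof <- default_profile()
  pol <- reference_thresholds()
  n_draws <- 2000
  for (key in fr_design()$condition) {
    row <- prof[prof$condition == key, ]
    t <- if (row$mask == "yes") pol$threshold_masked else pol$threshold_unmasked
    hits <- sum(replicate(n_draws, {
      pr <- sample_probe(ref, row$mean, row$sd)
      authentication_score(cosine_similarity(ref, pr)) > t
    }))
    p <- predicted_success_rate(row$mean, row$sd, t)
    se <- sqrt(p * (1 - p) / n_draws)
    expect_lt(abs(hits / n_draws - p), 3 * se + 1e-12)
  }
})

test_that("build_report assembles rates and genuine-vs-impostor tests", {
  g <- build_gallery(sim_config(n_patients = 20, dim = 64, seed = 19))
  sc <- score_all_pairs(g)
  rep <- build_report(sc, reference_thresholds())
  expect_s3_class(rep, "fr_report")
  expect_equal(nrow(rep$per_condition), 18)
  expect_equal(nrow(rep$aggregates), 5)
  expect_equal(nrow(rep$tests), 18)
  # genuine scores dwarf impostor scores in every condition
  expect_true(all(rep$tests$p_two_sided < 1e-4))
  expect_output(print(rep), "Aggregates")
})
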
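test_that("identical configuration gives bit-identical cohorts", {
  cfg <- sim_config(n_children = 2, n_days = 1, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(lapply(a$series, `[[`, "counts"),
                   lapply(b$series, `[[`, "counts"))
  # single-child simulation reproduces the cohort's entry
  expect_identical(simulate_child(cfg, 2)$counts, a$series[[2]]$counts)
})

test_that("simulated recordings have the advertised shape and invariants", {
  cfg <- sim_config(n_children = 1, n_days = 7, epoch_len_s = 5, seed = 4)
  s <- simulate_child(cfg, 1)
  expect_equal(length(s), 7 * 86400 / 5)  # 120,960 epochs
  expect_true(all(s$counts >= 0))
  expect_true(all(s$vm >= s$counts[, 1]))          # vm dominance
  expect_equal(s$vm^2, rowSums(s$counts^2))        # vm is the norm
  # sleep window emits exact zeros on all axes (first epochs of the day)
  expect_true(all(s$counts[1:100, ] == 0L))
})

test_that("a degenerate all-sleep profile emits only zeros", {
  sm <- default_state_model()
  sm$wake_start_min <- 0
  sm$wake_end_min <- 0
  cfg <- sim_config(n_children = 1, n_days = 2, state_model = sm, seed = 1,
                    nonwear_day_prob = 0)
  s <- simulate_child(cfg, 1)
  expect_true(all(s$counts == 0L))
})

test_that("invalid epoch length is rejected naming the constraint", {
  expect_error(sim_config(epoch_len_s = 7), "divide 60")
})

test_that("sex assignment follows the configured proportion", {
  males <- sum(vapply(1:3, function(sd) {
    co <- simulate_cohort(sim_config(n_children = 134, prop_male = 74 / 134,
                                     n_days = 1, seed = sd,
                                     state_model = list(
                                       wake_start_min = 0, wake_end_min = 0)))
    sum(co$metadata$sex == "M")
  }, numeric(1)))
  # 3 x 134 Bernoulli draws at p = 74/134: mean 222, sd 9.97
  expect_gt(males, 222 - 4 * 10)
  expect_lt(males, 222 + 4 * 10)
  co <- simulate_cohort(sim_config(n_children = 1, prop_male = 1, n_days = 1,
                                   state_model = list(wake_start_min = 0,
                                                      wake_end_min = 0)))
  expect_identical(co$metadata$sex, "M")
  expect_true(co$metadata$age_years >= 3 && co$metadata$age_years <= 5)
})

test_that("cohort mean vertical cpm stays near the calibration anchor", {
  # Monte-Carlo over 20 seeds; the anchor 535 cpm is what hip-worn preschool
  # recordings average, and the generator is calibrated to it within +-15%
  cpm <- vapply(1:20, function(sd) {
    co <- simulate_cohort(sim_config(n_children = 6, n_days = 3, seed = sd))
    mean(vapply(co$series, function(s) {
      worn <- wear_mask(s, detect_nonwear(s))
      sum(s$counts[worn, 1]) / (sum(worn) * s$epoch_len_s / 60)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(cpm), 535 * 0.85)
  expect_lt(mean(cpm), 535 * 1.15)
})

test_that("weekend effect raises sedentary minutes on weekend days", {
  pate <- get_cutpoint_set("pate", "vertical")
  diffs <- vapply(1:6, function(sd) {
    cfg <- sim_config(n_children = 3, n_days = 7, seed = sd,
                      weekend_effect = 1.5)
    co <- simulate_cohort(cfg)
    mean(vapply(co$series, function(s) {
      ds <- day_summary(s, pate)
      mean(ds$sb_min[ds$day_type == "weekend"]) -
        mean(ds$sb_min[ds$day_type == "weekday"])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("raising the MVPA bout rate raises MVPA minutes on every seed", {
  pate <- get_cutpoint_set("pate", "vertical")
  mvpa_min <- function(weight, sd) {
    sm <- default_state_model()
    sm$mvpa$weight <- weight
    co <- simulate_cohort(sim_config(n_children = 2, n_days = 2, seed = sd,
                                     state_model = sm))
    sum(vapply(co$series, function(s) sum(day_summary(s, pate)$mvpa_min),
               numeric(1)))
  }
  for (sd in 1:10)
    expect_gt(mvpa_min(0.5, sd), mvpa_min(0.1, sd))
})
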
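pate <- get_cutpoint_set("pate", "vertical")

# one 60-s-epoch day: 6 h night zeros, then sed/light/mvpa blocks, 6 h zeros
hand_day <- function() {
  v <- c(integer(360), rep(100L, 300), rep(900L, 360), rep(1700L, 60),
         integer(360))
  make_series(v, epoch_len_s = 60)
}

test_that("day summaries count minutes exactly and refuse invalid days", {
  s <- hand_day()
  ds <- day_summary(s, pate)
  expect_equal(ds$wear_min, 720)
  expect_equal(ds$sb_min, 300)
  expect_equal(ds$light_min, 360)
  expect_equal(ds$mvpa_min, 60)
  expect_equal(ds$mean_cpm_vertical, (300 * 100 + 360 * 900 + 60 * 1700) / 720)

  # an all-sedentary fully worn 12 h block
  s2 <- make_series(c(rep(100L, 720), integer(720)), epoch_len_s = 60)
  ds2 <- day_summary(s2, pate)
  expect_equal(c(ds2$sb_min, ds2$light_min, ds2$mvpa_min), c(720, 0, 0))

  # a day under 10 h wear is refused when requested explicitly
  s3 <- make_series(c(rep(100L, 500), integer(940)), epoch_len_s = 60)
  expect_error(day_summary(s3, pate, dates = as.Date("2024-01-01")),
               "fail the valid-day rule")
  expect_equal(nrow(day_summary(s3, pate)), 0L)
})

test_that("sb + light + mvpa = wear on random simulated days, every set", {
  co <- simulate_cohort(sim_config(n_children = 2, n_days = 2, seed = 17))
  for (set in default_cutpoint_sets()) {
    for (s in co$series) {
      ds <- day_summary(s, set)
      expect_equal(ds$sb_min + ds$light_min + ds$mvpa_min, ds$wear_min)
      # brute-force recount of one day
      worn <- wear_mask(s, detect_nonwear(s))
      lab <- classify_series(s, set, worn)
      d1 <- epoch_dates(s) == ds$date[1]
      expect_equal(ds$mvpa_min[1],
                   sum(lab[d1] == "mvpa", na.rm = TRUE) * 5 / 60)
    }
  }
})

test_that("period means average valid days; the 60-min bound is inclusive", {
  mk <- function(mvpa, dates) data.frame(
    child_id = "c1", date = as.Date(dates), day_type = day_type(dates),
    set_name = "pate", axis = "vertical",
    wear_min = 700, sb_min = 700 - 40 - mvpa, light_min = 40,
    mvpa_min = mvpa, mean_cpm_vertical = 500, mean_cpm_vm = 1100,
    valid = TRUE, stringsAsFactors = FALSE)

  one <- period_summary(mk(55, "2024-01-01"), "weekday")
  expect_equal(one$mvpa_min, 55)
  expect_equal(one$n_days, 1L)

  ps <- period_summary(mk(c(50, 70), c("2024-01-01", "2024-01-02")), "total")
  expect_equal(ps$mvpa_min, 60)
  expect_true(ps$active)     # mean of exactly 60.0 counts as active
  ps2 <- period_summary(mk(c(50, 69.8), c("2024-01-01", "2024-01-02")),
                        "total")
  expect_false(ps2$active)   # 59.9 is inactive

  # no valid weekend day: child omitted from that period, with a log entry
  we <- period_summary(mk(80, "2024-01-01"), "weekend")
  expect_equal(nrow(we), 0L)
  expect_identical(attr(we, "omitted"), "c1")
})

test_that("the total-period mean lies between weekday and weekend means", {
  co <- simulate_cohort(sim_config(n_children = 3, n_days = 7, seed = 23))
  for (s in co$series) {
    ds <- day_summary(s, pate)
    for (v in c("sb_min", "mvpa_min")) {
      wk <- period_summary(ds, "weekday")[[v]]
      we <- period_summary(ds, "weekend")[[v]]
      tot <- period_summary(ds, "total")[[v]]
      expect_true(tot >= min(wk, we) - 1e-9 && tot <= max(wk, we) + 1e-9)
    }
  }
})

test_that("cohort tables compute percentages and collapse identical cohorts", {
  base <- data.frame(
    child_id = sprintf("c%d", 1:8), period = "total",
    set_name = "pate", axis = "vertical", n_days = 7,
    sb_min = 500, light_min = 60, mvpa_min = 80,
    mean_cpm_vertical = 500, mean_cpm_vm = 1100,
    active = rep(c(TRUE, FALSE), c(6, 2)), stringsAsFactors = FALSE)
  meta <- data.frame(child_id = base$child_id,
                     sex = rep(c("M", "F"), each = 4),
                     stringsAsFactors = FALSE)
  tabs <- cohort_tables(base, meta)
  act <- tabs$active
  expect_equal(act$pct_active, round(100 * 6 / 8, 2))
  expect_equal(act$n_active_m + act$n_active_f, act$n_active)
  # identical minutes for every child: SE 0, CI collapses to the mean
  intens <- tabs$intensity
  expect_true(all(intens$mvpa_min_se == 0))
  expect_true(all(intens$mvpa_min_lo == 80 & intens$mvpa_min_hi == 80))
})
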
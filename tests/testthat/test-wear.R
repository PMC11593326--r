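epd5 <- 86400 / 5  # epochs per day at 5 s

test_that("a fully zero day is one non-worn interval with zero wear", {
  s <- make_series(integer(epd5))
  iv <- detect_nonwear(s)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$status, "non_worn")
  expect_equal(iv$start_epoch, 1L)
  expect_equal(iv$end_epoch, epd5 + 1L)
  expect_equal(unname(wear_minutes_per_day(s, iv)), 0)
})

test_that("the 20-minute zero-run threshold is inclusive", {
  pad <- function(mins) integer(mins * 12)
  # 19-min zero run flanked by non-zero epochs: below threshold, all worn
  v <- c(100L, pad(19), 100L)
  iv <- detect_nonwear(make_series(v), 20)
  expect_true(all(iv$status == "worn"))
  # exactly 20 min: flagged ("20 or more" is inclusive)
  v <- c(100L, pad(20), 100L)
  iv <- detect_nonwear(make_series(v), 20)
  expect_true("non_worn" %in% iv$status)
  nw <- iv[iv$status == "non_worn", ]
  expect_equal(nw$end_epoch - nw$start_epoch, 240L)
})

test_that("zero runs crossing midnight are split and tested per day", {
  # 15 min before + 15 min after midnight: neither part reaches 20 min
  v <- c(rep(50L, epd5 - 15 * 12), integer(30 * 12),
         rep(50L, epd5 - 15 * 12))
  iv <- detect_nonwear(make_series(v), 20)
  expect_true(all(iv$status == "worn"))
  # 25 min on each side: both parts flagged, split at the boundary
  v <- c(rep(50L, epd5 - 25 * 12), integer(50 * 12),
         rep(50L, epd5 - 25 * 12))
  iv <- detect_nonwear(make_series(v), 20)
  nw <- iv[iv$status == "non_worn", ]
  expect_equal(nrow(nw), 2L)
  expect_equal(nw$end_epoch[1], epd5 + 1L)   # first part ends at midnight
  expect_equal(nw$start_epoch[2], epd5 + 1L)
})

test_that("detection matches a brute-force zero-run scan on random series", {
  set.seed(21)
  for (i in 1:5) {
    s <- random_series(2 * epd5)
    iv <- detect_nonwear(s, 20)
    expect_identical(!wear_mask(s, iv), bf_nonwear_mask(s, 20))
    # partition: worn + non-worn minutes = 1440 per full day
    wm <- wear_minutes_per_day(s, iv)
    nonworn_min <- as.numeric(tapply(!wear_mask(s, iv), epoch_dates(s),
                                     sum)) * 5 / 60
    expect_equal(unname(wm) + nonworn_min, c(1440, 1440))
    # statuses alternate within each day
    for (d in split(iv, iv$date))
      if (nrow(d) > 1)
        expect_true(all(d$status[-1] != d$status[-nrow(d)]))
  }
})

test_that("lowering the zero-run threshold never decreases non-worn time", {
  set.seed(31)
  for (i in 1:3) {
    s <- random_series(epd5)
    nonworn <- vapply(c(5, 10, 20, 40), function(thr)
      sum(!wear_mask(s, detect_nonwear(s, thr))), numeric(1))
    expect_true(all(diff(nonworn) <= 0))
  }
})

test_that("wear minutes per day sum worn epochs", {
  s <- make_series(rep(10L, epd5))
  expect_equal(unname(wear_minutes_per_day(s, detect_nonwear(s))), 1440)
  v <- rep(10L, epd5); v[1000 + seq_len(120 * 12)] <- 0L
  s <- make_series(v)
  expect_equal(unname(wear_minutes_per_day(s, detect_nonwear(s))), 1320)
})

test_that("the 10-hour valid-day bound is inclusive", {
  rule <- valid_day_rule()
  wm <- c("2024-01-01" = 600, "2024-01-02" = 599.9, "2024-01-03" = 1440)
  expect_equal(unname(valid_days(wm, rule)), c(TRUE, FALSE, TRUE))
  expect_length(valid_days(setNames(numeric(0), character(0)), rule), 0)
})

test_that("children are retained iff both period minimums are met", {
  rule <- valid_day_rule(min_valid_weekdays = 1, min_valid_weekend_days = 1)
  tab <- data.frame(
    child_id = c(rep("none", 2), rep("wk_only", 6), rep("ok", 7)),
    date = as.Date("2024-01-01") + c(0:1, 0:5, 0:6),
    day_type = day_type(as.Date("2024-01-01") + c(0:1, 0:5, 0:6)),
    valid = c(FALSE, FALSE,                      # no valid days
              TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,  # 5 weekdays, Sat invalid
              rep(TRUE, 7)),                     # fully compliant
    stringsAsFactors = FALSE)
  res <- filter_children(tab, rule)
  expect_identical(res$retained, "ok")
  log <- res$log
  expect_true(log$excluded[log$child_id == "none"])
  expect_match(log$reason[log$child_id == "wk_only"], "weekend")
  expect_equal(log$n_valid_weekdays[log$child_id == "wk_only"], 5L)
  expect_false(log$excluded[log$child_id == "ok"])
})
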
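#' Valid-day rule
#'
#' Screening thresholds applied after non-wear removal: a day counts as valid
#' when it retains at least `min_wear_minutes` of wear (600 min = 10 h); a
#' child is retained when they have at least `min_valid_weekdays` valid
#' weekdays and `min_valid_weekend_days` valid weekend days.
#'
#' @param min_wear_minutes minimum wear per valid day (minutes, inclusive).
#' @param min_zero_run_minutes minimum consecutive-zero run flagged as
#'   non-wear (minutes, inclusive).
#' @param min_valid_weekdays,min_valid_weekend_days per-child retention
#'   thresholds (days).
#' @return a `valid_day_rule` list.
#' @export
valid_day_rule <- function(min_wear_minutes = 600,
                           min_zero_run_minutes = 20,
                           min_valid_weekdays = 1,
                           min_valid_weekend_days = 1) {
  stopifnot(min_wear_minutes > 0, min_zero_run_minutes > 0,
            min_valid_weekdays > 0, min_valid_weekend_days > 0)
  structure(list(min_wear_minutes = min_wear_minutes,
                 min_zero_run_minutes = min_zero_run_minutes,
                 min_valid_weekdays = min_valid_weekdays,
                 min_valid_weekend_days = min_valid_weekend_days),
            class = "valid_day_rule")
}

#' Detect non-wear intervals
#'
#' Flags every maximal run of consecutive zero-count epochs lasting at least
#' `min_zero_run_minutes` ("20 or more" is inclusive) as non-worn. The zero
#' test uses the vertical axis by default, the axis preschool cut-points are
#' calibrated on; `axis = "all"` requires all three axes to be zero. Runs are
#' evaluated within calendar days: a run crossing midnight is split at the
#' boundary and each part tested against the threshold on its own.
#'
#' @param series a [count_series].
#' @param min_zero_run_minutes run-length threshold in minutes.
#' @param axis `"vertical"` (default) or `"all"`.
#' @return data.frame with one row per interval: `date`, `start_epoch`,
#'   `end_epoch` (1-based, half-open: the interval covers epochs
#'   `start_epoch` to `end_epoch - 1`), `status` (`"worn"`/`"non_worn"`).
#'   Within each day the intervals partition that day's epochs and statuses
#'   alternate.
#' @export
detect_nonwear <- function(series, min_zero_run_minutes = 20,
                           axis = c("vertical", "all")) {
  stopifnot(inherits(series, "count_series"))
  axis <- match.arg(axis)
  thr_epochs <- ceiling(min_zero_run_minutes * 60 / series$epoch_len_s)
  zero <- if (axis == "vertical") series$counts[, 1L] == 0L
          else rowSums(series$counts) == 0L
  dates <- epoch_dates(series)
  out <- list()
  for (d in split(seq_along(zero), dates)) {
    r <- rle(zero[d])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nonworn <- r$values & r$lengths >= thr_epochs
    # collapse adjacent same-status segments into alternating intervals
    seg_status <- ifelse(nonworn, "non_worn", "worn")
    keep <- c(TRUE, seg_status[-1L] != seg_status[-length(seg_status)])
    out[[length(out) + 1L]] <- data.frame(
      date = rep(dates[d[1L]], sum(keep)),
      start_epoch = d[1L] - 1L + starts[keep],
      end_epoch = d[1L] - 1L + c(starts[keep][-1L] - 1L,
                                 ends[length(ends)]) + 1L,
      status = seg_status[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$start_epoch), , drop = FALSE]
}

#' Logical wear mask from non-wear intervals
#'
#' @param series a [count_series].
#' @param intervals output of [detect_nonwear].
#' @return logical vector, TRUE where the epoch is worn.
#' @export
wear_mask <- function(series, intervals) {
  worn <- rep(TRUE, nrow(series$counts))
  nw <- intervals[intervals$status == "non_worn", , drop = FALSE]
  for (i in seq_len(nrow(nw)))
    worn[nw$start_epoch[i]:(nw$end_epoch[i] - 1L)] <- FALSE
  worn
}

#' Wear minutes per calendar day
#'
#' @param series a [count_series].
#' @param intervals output of [detect_nonwear].
#' @return named numeric vector: minutes of worn time per date.
#' @export
wear_minutes_per_day <- function(series, intervals) {
  worn <- wear_mask(series, intervals)
  dates <- epoch_dates(series)
  m <- tapply(worn, dates, sum)
  stats::setNames(as.numeric(m) * series$epoch_len_s / 60, names(m))
}

#' Valid-day flags
#'
#' A day is valid iff its wear time reaches the rule's minimum (inclusive:
#' exactly 10 h of wear is a valid day).
#'
#' @param wear_map named numeric vector from [wear_minutes_per_day].
#' @param rule a [valid_day_rule].
#' @return named logical vector over the same dates.
#' @export
valid_days <- function(wear_map, rule = valid_day_rule()) {
  if (length(wear_map) == 0L) return(stats::setNames(logical(0), character(0)))
  wear_map >= rule$min_wear_minutes
}

#' Retain children with enough valid days
#'
#' A child is retained iff they reach the rule's minimum number of valid
#' weekdays and valid weekend days; every exclusion is logged with its
#' reason.
#'
#' @param valid_day_table data.frame with columns `child_id`, `date`,
#'   `day_type` (`"weekday"`/`"weekend"`), `valid` (logical) — one row per
#'   recorded child-day.
#' @param rule a [valid_day_rule].
#' @return list with `retained` (character ids) and `log` (data.frame:
#'   `child_id`, `n_valid_weekdays`, `n_valid_weekend_days`, `excluded`,
#'   `reason`).
#' @export
filter_children <- function(valid_day_table, rule = valid_day_rule()) {
  stopifnot(all(c("child_id", "day_type", "valid") %in%
                  names(valid_day_table)))
  ids <- unique(valid_day_table$child_id)
  log <- data.frame(child_id = ids,
                    n_valid_weekdays = 0L, n_valid_weekend_days = 0L,
                    excluded = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- valid_day_table[valid_day_table$child_id == ids[i], ]
    nwd <- sum(rows$valid & rows$day_type == "weekday")
    nwe <- sum(rows$valid & rows$day_type == "weekend")
    log$n_valid_weekdays[i] <- nwd
    log$n_valid_weekend_days[i] <- nwe
    reasons <- character(0)
    if (nwd < rule$min_valid_weekdays)
      reasons <- c(reasons, sprintf("valid weekdays %d < %d", nwd,
                                    rule$min_valid_weekdays))
    if (nwe < rule$min_valid_weekend_days)
      reasons <- c(reasons, sprintf("valid weekend days %d < %d", nwe,
                                    rule$min_valid_weekend_days))
    if (length(reasons)) {
      log$excluded[i] <- TRUE
      log$reason[i] <- paste(reasons, collapse = "; ")
    }
  }
  list(retained = ids[!log$excluded], log = log)
}

#' Weekday/weekend day type of a date
#' @param date Date vector.
#' @return character vector `"weekday"`/`"weekend"` (weekend = Sat, Sun).
#' @export
day_type <- function(date) {
  wd <- format(as.Date(date), "%u")  # 1 = Monday ... 7 = Sunday
  ifelse(wd %in% c("6", "7"), "weekend", "weekday")
}
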
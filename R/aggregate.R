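#' Per-day intensity summary under one cut-point set
#'
#' Converts labelled epochs into minutes per intensity per calendar day.
#' Minutes are exact epoch counts times `epoch_len_s / 60`, so
#' `sb_min + light_min + mvpa_min == wear_min` on every day. Mean cpm is the
#' per-minute count rate over worn epochs, reported for both the vertical
#' axis and the vector magnitude regardless of the set's axis.
#'
#' @param series a [count_series].
#' @param set a `cutpoint_set`.
#' @param intervals non-wear intervals from [detect_nonwear]; computed with
#'   the rule's zero-run threshold if omitted.
#' @param rule a [valid_day_rule].
#' @param dates optional Date vector restricting the output; requesting a day
#'   that fails the valid-day rule is an error. By default all valid days are
#'   returned.
#' @return data.frame: `child_id`, `date`, `day_type`, `set_name`, `axis`,
#'   `wear_min`, `sb_min`, `light_min`, `mvpa_min`, `mean_cpm_vertical`,
#'   `mean_cpm_vm`, `valid`.
#' @export
day_summary <- function(series, set, intervals = NULL,
                        rule = valid_day_rule(), dates = NULL) {
  stopifnot(inherits(series, "count_series"), inherits(set, "cutpoint_set"))
  if (is.null(intervals))
    intervals <- detect_nonwear(series, rule$min_zero_run_minutes)
  worn <- wear_mask(series, intervals)
  labels <- classify_series(series, set, worn)
  ep_dates <- epoch_dates(series)
  min_per_epoch <- series$epoch_len_s / 60
  all_dates <- sort(unique(ep_dates))
  rows <- lapply(all_dates, function(d) {
    idx <- ep_dates == d
    widx <- idx & worn
    wear_min <- sum(widx) * min_per_epoch
    tab <- table(labels[widx])
    data.frame(child_id = series$child_id, date = d,
               day_type = day_type(d),
               set_name = set$name, axis = set$axis,
               wear_min = wear_min,
               sb_min = tab[["sedentary"]] * min_per_epoch,
               light_min = tab[["light"]] * min_per_epoch,
               mvpa_min = tab[["mvpa"]] * min_per_epoch,
               mean_cpm_vertical = if (wear_min > 0)
                 sum(series$counts[widx, 1L]) / wear_min else NA_real_,
               mean_cpm_vm = if (wear_min > 0)
                 sum(series$vm[widx]) / wear_min else NA_real_,
               valid = wear_min >= rule$min_wear_minutes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    missing <- setdiff(as.character(dates), as.character(out$date))
    if (length(missing))
      stop("no data for requested date(s): ", paste(missing, collapse = ", "))
    out <- out[out$date %in% dates, , drop = FALSE]
    if (any(!out$valid))
      stop("requested day(s) fail the valid-day rule: ",
           paste(out$date[!out$valid], collapse = ", "))
  } else {
    out <- out[out$valid, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-child period summary and guideline-compliance flag
#'
#' Unweighted means over each child's valid days in the period; a child is
#' `active` iff their mean daily MVPA reaches `guideline_minutes` (the
#' >= 60 min/day recommendation; the bound is inclusive, so a mean of exactly
#' 60.0 counts as active). Children with no valid day in the period are
#' omitted and listed in the `"omitted"` attribute.
#'
#' @param day_sums row-bound [day_summary] output for one cut-point set
#'   (possibly many children).
#' @param period `"weekday"`, `"weekend"` or `"total"` (all valid days).
#' @param guideline_minutes MVPA guideline (minutes/day, default 60).
#' @return data.frame: `child_id`, `period`, `set_name`, `axis`, `n_days`,
#'   `sb_min`, `light_min`, `mvpa_min`, `mean_cpm_vertical`, `mean_cpm_vm`,
#'   `active`; attribute `omitted` holds child ids with no valid day.
#' @export
period_summary <- function(day_sums, period = c("total", "weekday", "weekend"),
                           guideline_minutes = 60) {
  period <- match.arg(period)
  stopifnot(length(unique(day_sums$set_name)) <= 1,
            length(unique(day_sums$axis)) <= 1)
  keep <- if (period == "total") rep(TRUE, nrow(day_sums))
          else day_sums$day_type == period
  sub <- day_sums[keep & day_sums$valid, , drop = FALSE]
  all_ids <- unique(day_sums$child_id)
  rows <- lapply(split(sub, sub$child_id), function(d) {
    data.frame(child_id = d$child_id[1L], period = period,
               set_name = d$set_name[1L], axis = d$axis[1L],
               n_days = nrow(d),
               sb_min = mean(d$sb_min), light_min = mean(d$light_min),
               mvpa_min = mean(d$mvpa_min),
               mean_cpm_vertical = mean(d$mean_cpm_vertical),
               mean_cpm_vm = mean(d$mean_cpm_vm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(child_id = character(0), period = character(0),
                      set_name = character(0), axis = character(0),
                      n_days = integer(0), sb_min = numeric(0),
                      light_min = numeric(0), mvpa_min = numeric(0),
                      mean_cpm_vertical = numeric(0),
                      mean_cpm_vm = numeric(0), stringsAsFactors = FALSE)
  out$active <- out$mvpa_min >= guideline_minutes
  rownames(out) <- NULL
  attr(out, "omitted") <- setdiff(all_ids, out$child_id)
  out
}

#' Cohort description tables
#'
#' Builds the two table families a cut-point comparison reports: (a) mean
#' daily minutes per intensity with standard error and 95% t confidence
#' interval, per sex x period x cut-point set; (b) counts and percentages of
#' active/inactive children per cut-point set x period, overall and by sex,
#' with a Pearson chi-square p-value (no continuity correction) for the sex
#' difference where both margins are non-degenerate.
#'
#' @param period_sums row-bound [period_summary] output across sets and
#'   periods (an `active` column per child x period x set).
#' @param metadata cohort metadata (`child_id`, `sex`).
#' @param conf_level confidence level for the intervals.
#' @return list with data.frames `intensity` and `active`.
#' @export
cohort_tables <- function(period_sums, metadata, conf_level = 0.95) {
  ps <- merge(period_sums, metadata[, c("child_id", "sex")], by = "child_id")
  key <- interaction(ps$set_name, ps$axis, ps$period, drop = TRUE)
  intensity <- do.call(rbind, lapply(split(ps, key), function(g) {
    do.call(rbind, lapply(split(g, g$sex), function(gs) {
      row <- data.frame(set_name = g$set_name[1L], axis = g$axis[1L],
                        period = g$period[1L], sex = gs$sex[1L],
                        n = nrow(gs), stringsAsFactors = FALSE)
      for (v in c("sb_min", "light_min", "mvpa_min")) {
        ci <- if (nrow(gs) >= 2) mean_ci(gs[[v]], level = conf_level)
              else c(mean = mean(gs[[v]]), se = NA_real_,
                     lower = NA_real_, upper = NA_real_)
        row[[paste0(v, "_mean")]] <- ci[["mean"]]
        row[[paste0(v, "_se")]] <- ci[["se"]]
        row[[paste0(v, "_lo")]] <- ci[["lower"]]
        row[[paste0(v, "_hi")]] <- ci[["upper"]]
      }
      row
    }))
  }))
  active <- do.call(rbind, lapply(split(ps, key), function(g) {
    n <- nrow(g); n_act <- sum(g$active)
    m <- g[g$sex == "M", ]; f <- g[g$sex == "F", ]
    tab <- c(sum(m$active), nrow(m) - sum(m$active),
             sum(f$active), nrow(f) - sum(f$active))
    # chisq.test's small-expected-count caution is inherent at cohort sizes
    # with near-degenerate margins; the p-value is reported as computed
    p <- tryCatch(suppressWarnings(chi2_2x2(matrix(tab, 2, byrow = TRUE))[["p"]]),
                  error = function(e) NA_real_)
    data.frame(set_name = g$set_name[1L], axis = g$axis[1L],
               period = g$period[1L], n = n,
               n_active = n_act, pct_active = round(100 * n_act / n, 2),
               n_active_m = tab[1L], n_inactive_m = tab[2L],
               n_active_f = tab[3L], n_inactive_f = tab[4L],
               p_sex = p, stringsAsFactors = FALSE)
  }))
  rownames(intensity) <- rownames(active) <- NULL
  list(intensity = intensity, active = active)
}
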
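#' Synthetic cohort configuration
#'
#' Defines a seed-reproducible cohort of week-long tri-axial preschooler
#' recordings. Activity is generated as a semi-Markov sequence over four
#' states — sleep/non-wear (exact zeros on all axes), sedentary, light and
#' moderate-to-vigorous — with exponential dwell times truncated to whole
#' epochs, a diurnal occupancy profile over the waking window, and per-epoch
#' counts drawn from a gamma distribution scaled to each state's
#' counts-per-minute band (zero-inflated for sedentary). The vector magnitude
#' is synthesised as vertical count x `vm_ratio` x lognormal noise, floored
#' at the vertical count, then decomposed into two horizontal axis counts so
#' that the stored quantity is always the Euclidean norm of three integer
#' axes.
#'
#' @param n_children cohort size.
#' @param prop_male expected fraction of boys; sex is drawn per child from
#'   the child's own stream.
#' @param n_days recording length in days (default 7).
#' @param epoch_len_s epoch length in seconds (default 5; must divide 60).
#' @param start_date first recording date (default a Monday, so the
#'   weekday/weekend split of a 7-day wear protocol is deterministic).
#' @param state_model list of per-state parameters; see Details.
#' @param vm_ratio multiplicative link from vertical counts to the vector
#'   magnitude (default 2.2, the approximate ratio of cohort-mean vector
#'   magnitude to vertical cpm reported for preschoolers).
#' @param vm_sdlog lognormal noise (sdlog) on the vector-magnitude link.
#' @param sex_effect multiplier on the MVPA bout rate for boys (default
#'   1.15: boys accumulate somewhat more MVPA than girls).
#' @param weekend_effect multiplier on sedentary dwell time on weekend days
#'   (default 1.2: more sedentary time at the weekend).
#' @param nonwear_day_prob probability that a day contains one extra daytime
#'   non-wear run of 25–60 min (bathing, device off).
#' @param seed integer seed; identical configurations (including seed)
#'   produce bit-identical cohorts.
#'
#' @details `state_model` has elements `wake_start_min`, `wake_end_min`
#' (waking window, minutes from midnight; outside it the child is in
#' sleep/non-wear and every axis reads exactly 0) and one list per waking
#' state with `dwell_min` (mean bout length, minutes), `cpm_mean` (gamma mean
#' on the cpm scale), `cpm_shape` (gamma shape), `zero_prob` (per-epoch
#' zero-inflation) and `weight` (relative bout-selection rate). The MVPA
#' weight is modulated over the day by a sinusoidal diurnal profile peaking
#' mid-afternoon.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_children = 134,
                       prop_male = 74 / 134,
                       n_days = 7,
                       epoch_len_s = 5,
                       start_date = as.Date("2024-01-01"),
                       state_model = default_state_model(),
                       vm_ratio = 2.2,
                       vm_sdlog = 0.15,
                       sex_effect = 1.15,
                       weekend_effect = 1.2,
                       nonwear_day_prob = 0.25,
                       seed = 1L) {
  stopifnot(n_children >= 1, prop_male >= 0, prop_male <= 1, n_days >= 1)
  check_epoch_len(epoch_len_s)
  if (epoch_len_s > 60) stop("simulation epoch must divide 60 s")
  structure(list(n_children = as.integer(n_children), prop_male = prop_male,
                 n_days = as.integer(n_days),
                 epoch_len_s = as.integer(epoch_len_s),
                 start_date = as.Date(start_date),
                 state_model = state_model,
                 vm_ratio = vm_ratio, vm_sdlog = vm_sdlog,
                 sex_effect = sex_effect, weekend_effect = weekend_effect,
                 nonwear_day_prob = nonwear_day_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default semi-Markov state model for preschooler activity
#'
#' Waking window 07:00–21:00; state occupancies and cpm bands chosen so the
#' cohort-mean vertical-axis cpm sits near 535 cpm, the anchor reported for
#' hip-worn preschool recordings, with sedentary time dominant and short,
#' frequent MVPA bouts ("spontaneous and intermittent" activity).
#'
#' @return list suitable for the `state_model` field of [sim_config].
#' @export
default_state_model <- function() {
  list(wake_start_min = 420, wake_end_min = 1260,
       sedentary = list(dwell_min = 5.0, cpm_mean = 150, cpm_shape = 1.5,
                        zero_prob = 0.35, weight = 0.47),
       light     = list(dwell_min = 2.0, cpm_mean = 1050, cpm_shape = 1.5,
                        zero_prob = 0, weight = 0.27),
       mvpa      = list(dwell_min = 1.2, cpm_mean = 2650, cpm_shape = 1.5,
                        zero_prob = 0, weight = 0.25))
}

# Evaluate `fn()` under a private RNG stream, restoring the caller's RNG
# state afterwards so simulation never perturbs user code.
with_private_seed <- function(seed, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Per-child substream seed: children are individually reproducible and
# independent of n_children. Kept below 2^31 - 1.
child_seed <- function(seed, child_index) {
  (as.numeric(seed) * 48271 + as.numeric(child_index) * 265443) %% 2147483629
}

#' Simulate one child's recording
#'
#' @param config a [sim_config].
#' @param child_index 1-based index below or equal to `config$n_children`.
#' @return a [count_series] of `n_days * 86400 / epoch_len_s` epochs starting
#'   at local midnight of `start_date`.
#' @export
simulate_child <- function(config, child_index) {
  stopifnot(inherits(config, "sim_config"),
            child_index >= 1, child_index <= config$n_children)
  with_private_seed(child_seed(config$seed, child_index), function() {
    male <- stats::runif(1) < config$prop_male
    stats::runif(1)  # age draw position in the stream (used by cohort)
    sim_child_counts(config, child_index, male)
  })
}

# Internal: draw the series given sex, inside an already-seeded stream.
sim_child_counts <- function(config, child_index, male) {
  sm <- config$state_model
  epd <- 86400L %/% config$epoch_len_s        # epochs per day
  eps_per_min <- 60L %/% config$epoch_len_s
  states <- c("sedentary", "light", "mvpa")
  vertical <- integer(config$n_days * epd)
  dates <- config$start_date + seq_len(config$n_days) - 1L
  for (day in seq_len(config$n_days)) {
    weekend <- format(dates[day], "%u") %in% c("6", "7")
    offset <- (day - 1L) * epd
    w0 <- sm$wake_start_min * eps_per_min + 1L  # first waking epoch (1-based)
    w1 <- sm$wake_end_min * eps_per_min         # last waking epoch
    pos <- w0
    while (pos <= w1) {
      hour <- (pos - 1) / (eps_per_min * 60)
      # diurnal modulation: MVPA propensity peaks mid-afternoon
      diel <- sin(pi * (hour - sm$wake_start_min / 60) /
                    ((sm$wake_end_min - sm$wake_start_min) / 60))
      w <- c(sm$sedentary$weight * (1.15 - 0.3 * diel),
             sm$light$weight,
             sm$mvpa$weight * (0.7 + 0.6 * diel) *
               (if (male) config$sex_effect else 1))
      st <- sample(states, 1L, prob = w)
      p <- sm[[st]]
      dwell <- p$dwell_min * (if (st == "sedentary" && weekend)
        config$weekend_effect else 1)
      n_ep <- max(1L, round(stats::rexp(1L, 1 / dwell) * eps_per_min))
      n_ep <- min(n_ep, w1 - pos + 1L)
      mean_per_epoch <- p$cpm_mean * config$epoch_len_s / 60
      cnt <- stats::rgamma(n_ep, shape = p$cpm_shape,
                           scale = mean_per_epoch / p$cpm_shape)
      if (p$zero_prob > 0)
        cnt[stats::runif(n_ep) < p$zero_prob] <- 0
      vertical[offset + pos:(pos + n_ep - 1L)] <- as.integer(round(cnt))
      pos <- pos + n_ep
    }
    # occasional daytime non-wear run (device removed): zeros on all axes
    if (stats::runif(1) < config$nonwear_day_prob) {
      dur <- round(stats::runif(1, 25, 60) * eps_per_min)
      at <- round(stats::runif(1, 12 * 60, 18 * 60)) * eps_per_min + 1L
      vertical[offset + at:min(at + dur - 1L, epd)] <- 0L
    }
  }
  # vector-magnitude synthesis: vm = v * ratio * lognormal noise, floored at
  # v, decomposed into two integer horizontal axes
  nz <- which(vertical > 0L)
  axis2 <- axis3 <- integer(length(vertical))
  if (length(nz)) {
    v <- vertical[nz]
    vm_t <- pmax(v, v * config$vm_ratio *
                   exp(stats::rnorm(length(nz), 0, config$vm_sdlog)))
    h2 <- pmax(0, vm_t^2 - v^2)
    u <- stats::runif(length(nz), 0.3, 0.7)
    axis2[nz] <- as.integer(round(sqrt(u * h2)))
    axis3[nz] <- as.integer(round(sqrt((1 - u) * h2)))
  }
  count_series(sprintf("child_%03d", child_index),
               as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
               config$epoch_len_s, vertical, axis2, axis3)
}

#' Simulate a cohort
#'
#' @param config a [sim_config].
#' @return a `sim_cohort` list: `metadata` (data.frame `child_id`,
#'   `sex` in `{M, F}`, `age_years` in `[3, 5]`) and `series` (named list of
#'   [count_series]). Identical configurations give bit-identical cohorts.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  series <- vector("list", config$n_children)
  sex <- character(config$n_children)
  age <- numeric(config$n_children)
  for (i in seq_len(config$n_children)) {
    res <- with_private_seed(child_seed(config$seed, i), function() {
      male <- stats::runif(1) < config$prop_male
      a <- round(stats::runif(1, 3, 5), 1)
      list(male = male, age = a,
           series = sim_child_counts(config, i, male))
    })
    sex[i] <- if (res$male) "M" else "F"
    age[i] <- res$age
    series[[i]] <- res$series
  }
  ids <- vapply(series, function(s) s$child_id, character(1))
  names(series) <- ids
  structure(list(metadata = data.frame(child_id = ids, sex = sex,
                                       age_years = age,
                                       stringsAsFactors = FALSE),
                 series = series,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$metadata), " children (",
      sum(x$metadata$sex == "M"), " M / ", sum(x$metadata$sex == "F"),
      " F), ", x$config$n_days, " days at ", x$config$epoch_len_s,
      "-s epochs, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one epoch CSV per child (the [read_epoch_csv] dialect) plus
#' `metadata.csv` (`child_id,sex,age_years`).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in cohort$series)
    write_epoch_csv(s, file.path(dir, paste0(s$child_id, ".csv")))
  invisible(dir)
}

#' Read a cohort written by [write_cohort]
#' @param dir directory containing `metadata.csv` and per-child epoch CSVs.
#' @return a `sim_cohort`-shaped list (without a `config`).
#' @export
read_cohort <- function(dir) {
  # sex codes M/F must never be parsed as logicals
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(sex = "character"))
  series <- lapply(meta$child_id, function(id)
    read_epoch_csv(file.path(dir, paste0(id, ".csv")), child_id = id))
  names(series) <- meta$child_id
  structure(list(metadata = meta, series = series, config = NULL),
            class = "sim_cohort")
}
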
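#' Run the cut-point comparison analysis on a cohort
#'
#' The package's central entry point. Takes a cohort of epoch-count
#' recordings (simulated via [simulate_cohort], or read from disk via
#' [read_cohort]), applies non-wear removal and valid-day screening, labels
#' every worn epoch under each selected cut-point set, aggregates to daily
#' and period (weekday / weekend / total) summaries with the >= 60 min/day
#' MVPA compliance flag, and computes the cohort description tables and
#' inter-cut-point agreement matrices.
#'
#' @param cohort a `sim_cohort`, or a directory path understood by
#'   [read_cohort].
#' @param sets list of `cutpoint_set` objects; default: every built-in set
#'   on both axes (Pate vertical; Butte and Johansson on vertical and vector
#'   magnitude).
#' @param rule a [valid_day_rule].
#' @param guideline_minutes MVPA guideline threshold (minutes/day).
#' @return an object of class `cutpoint_analysis` with components
#'   `metadata`, `exclusions` (per-child valid-day log), `day_summaries`,
#'   `period_summaries`, `tables` (`intensity`, `active`), `agreement`
#'   (by sex and overall), `rule`, `guideline_minutes`, `sets`, `call`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_children = 8, n_days = 7, seed = 42)
#' fit <- cutpoint_analysis(simulate_cohort(cfg))
#' summary(fit)
#' }
#' @export
cutpoint_analysis <- function(cohort,
                              sets = default_cutpoint_sets(),
                              rule = valid_day_rule(),
                              guideline_minutes = 60) {
  cl <- match.call()
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "sim_cohort") ||
              (is.list(cohort) && !is.null(cohort$series)))
  series <- cohort$series
  metadata <- cohort$metadata

  # wear-time screening (cut-point independent)
  intervals <- lapply(series, detect_nonwear, rule$min_zero_run_minutes)
  wear_maps <- mapply(wear_minutes_per_day, series, intervals,
                      SIMPLIFY = FALSE)
  vdt <- do.call(rbind, lapply(names(series), function(id) {
    wm <- wear_maps[[id]]
    v <- valid_days(wm, rule)
    data.frame(child_id = id, date = as.Date(names(wm)),
               wear_min = as.numeric(wm),
               day_type = day_type(as.Date(names(wm))),
               valid = as.logical(v), stringsAsFactors = FALSE)
  }))
  flt <- filter_children(vdt, rule)
  if (length(flt$retained) == 0L)
    stop("no children retained after valid-day screening; exclusion log:\n",
         paste(utils::capture.output(print(flt$log)), collapse = "\n"))

  kept <- flt$retained
  day_sums <- list()
  period_sums <- list()
  for (set in sets) {
    ds <- do.call(rbind, lapply(kept, function(id)
      day_summary(series[[id]], set, intervals[[id]], rule)))
    day_sums[[length(day_sums) + 1L]] <- ds
    for (pd in c("weekday", "weekend", "total"))
      period_sums[[length(period_sums) + 1L]] <-
        period_summary(ds, pd, guideline_minutes)
  }
  day_sums <- do.call(rbind, day_sums)
  period_sums <- do.call(rbind, lapply(period_sums, function(p) {
    attr(p, "omitted") <- NULL
    p
  }))
  meta_kept <- metadata[metadata$child_id %in% kept, , drop = FALSE]
  tables <- cohort_tables(period_sums, meta_kept)
  agreement <- rbind(agreement_matrix(period_sums, meta_kept),
                     agreement_matrix(period_sums, metadata = NULL))
  structure(list(metadata = metadata, exclusions = flt$log,
                 valid_day_table = vdt,
                 day_summaries = day_sums, period_summaries = period_sums,
                 tables = tables, agreement = agreement,
                 rule = rule, guideline_minutes = guideline_minutes,
                 sets = sets, call = cl),
            class = "cutpoint_analysis")
}

#' Default cut-point selection: every built-in set on both axes
#' @return list of `cutpoint_set` objects.
#' @export
default_cutpoint_sets <- function() {
  out <- list()
  for (axis in c("vertical", "vector_magnitude"))
    for (nm in builtin_cutpoint_names(axis))
      out[[length(out) + 1L]] <- get_cutpoint_set(nm, axis)
  out
}

#' @export
print.cutpoint_analysis <- function(x, ...) {
  n_all <- nrow(x$metadata)
  n_kept <- sum(!x$exclusions$excluded)
  cat("Cut-point comparison analysis\n")
  cat("  children: ", n_kept, " retained of ", n_all,
      " (rule: >= ", x$rule$min_wear_minutes, " min wear/day, zero-run >= ",
      x$rule$min_zero_run_minutes, " min)\n", sep = "")
  cat("  cut-point sets: ",
      paste(vapply(x$sets, function(s) paste0(s$name, "[", s$axis, "]"),
                   character(1)), collapse = ", "), "\n", sep = "")
  cat("  guideline: >= ", x$guideline_minutes, " min MVPA/day\n", sep = "")
  invisible(x)
}

#' @export
summary.cutpoint_analysis <- function(object, ...) {
  structure(list(fit = object), class = "summary.cutpoint_analysis")
}

#' @export
print.summary.cutpoint_analysis <- function(x, ...) {
  print(x$fit)
  act <- x$fit$tables$active
  cat("\nPercent classified active (>= ", x$fit$guideline_minutes,
      " min MVPA/day):\n", sep = "")
  show <- act[, c("set_name", "axis", "period", "n", "n_active",
                  "pct_active", "p_sex")]
  print(show, row.names = FALSE, digits = 3)
  agr <- x$fit$agreement
  agr <- agr[agr$sex == "all", , drop = FALSE]
  if (nrow(agr)) {
    cat("\nAgreement between cut-point sets (all children):\n")
    print(agr[, c("period", "set_first", "set_second", "pct_agreement",
                  "kappa", "band")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.cutpoint_analysis <- function(x, period = "total", ...) {
  ps <- x$period_summaries
  ps <- ps[ps$period == period, ]
  lab <- paste(ps$set_name, ifelse(ps$axis == "vertical", "y", "vm"),
               sep = ".")
  agg <- stats::aggregate(ps[, c("sb_min", "light_min", "mvpa_min")],
                          list(set = lab), mean)
  m <- t(as.matrix(agg[, -1]))
  colnames(m) <- agg$set
  graphics::barplot(m, beside = TRUE,
                    legend.text = c("sedentary", "light", "MVPA"),
                    ylab = "mean minutes/day",
                    main = paste("Intensity minutes by cut-point set,",
                                 period, "days"), ...)
  invisible(x)
}

#' Write the analysis output bundle
#'
#' Emits the exclusion log, day and period summaries, the intensity and
#' active-classification tables, the agreement matrix, and a YAML manifest
#' (rule, guideline, cut-point sets, package version) to `dir`. Identical
#' analyses produce byte-identical bundles.
#'
#' @param fit a `cutpoint_analysis`.
#' @param dir output directory (created if needed).
#' @param seed optional seed to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(fit, dir, seed = NULL) {
  stopifnot(inherits(fit, "cutpoint_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(fit$exclusions, "exclusion_log.csv")
  wr(fit$day_summaries, "day_summaries.csv")
  wr(fit$period_summaries, "period_summaries.csv")
  wr(fit$tables$intensity, "intensity_minutes_by_sex_period.csv")
  wr(fit$tables$active, "active_classification.csv")
  wr(fit$agreement, "agreement_matrix.csv")
  manifest <- list(
    package = "accelcut",
    version = as.character(utils::packageVersion("accelcut")),
    rule = unclass(fit$rule),
    guideline_minutes = fit$guideline_minutes,
    cutpoint_sets = lapply(fit$sets, unclass),
    seed = seed)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' The configuration drives an end-to-end run: `mode` (`simulate` or
#' `read`), a `simulate:` block of [sim_config] fields or an `input_dir`,
#' an optional `rule:` block of [valid_day_rule] fields,
#' `guideline_minutes`, a `cutpoints:` list selecting sets by
#' `{name, axis}` (with optional `sb_upper_cpm`/`mvpa_lower_cpm` for custom
#' sets; built-ins cannot be overridden), and `out_dir`.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mode <- match.arg(cfg$mode, c("simulate", "read"))
  if (mode == "read" && !dir.exists(cfg$input_dir %||% ""))
    stop("input_dir does not exist: ", cfg$input_dir)
  rule <- do.call(valid_day_rule, cfg$rule %||% list())
  sets <- if (is.null(cfg$cutpoints)) default_cutpoint_sets()
  else lapply(cfg$cutpoints, function(s) {
    if (is.null(s$sb_upper_cpm)) get_cutpoint_set(s$name, s$axis)
    else cutpoint_set(s$name, s$axis, s$sb_upper_cpm, s$mvpa_lower_cpm)
  })
  structure(list(mode = mode,
                 sim = if (mode == "simulate")
                   do.call(sim_config, cfg$simulate %||% list()),
                 input_dir = cfg$input_dir,
                 rule = rule, sets = sets,
                 guideline_minutes = cfg$guideline_minutes %||% 60,
                 out_dir = cfg$out_dir),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a full configured run
#'
#' Simulates or reads the cohort, runs [cutpoint_analysis], and (when the
#' configuration names an `out_dir`) writes the output bundle.
#'
#' @param config a `run_config` from [read_run_config], or a path to one.
#' @return the `cutpoint_analysis` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cohort <- if (config$mode == "simulate") simulate_cohort(config$sim)
            else read_cohort(config$input_dir)
  fit <- cutpoint_analysis(cohort, sets = config$sets, rule = config$rule,
                           guideline_minutes = config$guideline_minutes)
  if (!is.null(config$out_dir))
    write_analysis(fit, config$out_dir,
                   seed = if (config$mode == "simulate") config$sim$seed)
  invisible(fit)
}
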
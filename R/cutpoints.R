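# Built-in registry of published preschool cut-point sets, in counts per
# minute. Each set gives an upper bound for sedentary behaviour (counts
# strictly below -> sedentary) and a lower bound for MVPA (counts at or above
# -> MVPA); the half-open band between is light activity. Pate published no
# vector-magnitude thresholds.
.cutpoint_registry <- list(
  vertical = list(
    pate      = c(sb_upper_cpm = 800,  mvpa_lower_cpm = 1680),
    butte     = c(sb_upper_cpm = 239,  mvpa_lower_cpm = 2120),
    johansson = c(sb_upper_cpm = 580,  mvpa_lower_cpm = 3480)
  ),
  vector_magnitude = list(
    butte     = c(sb_upper_cpm = 820,  mvpa_lower_cpm = 1908),
    johansson = c(sb_upper_cpm = 2136, mvpa_lower_cpm = 6144)
  )
)

#' Retrieve a published cut-point set
#'
#' The built-in registry holds the three preschool cut-point sets (Pate,
#' Butte, Johansson) on the vertical axis and the Butte and Johansson sets on
#' the vector magnitude. Built-in sets are immutable; additional sets can be
#' supplied at analysis time through the run configuration without touching
#' the registry.
#'
#' @param name one of `"pate"`, `"butte"`, `"johansson"` (or a custom name
#'   present in `extra`).
#' @param axis `"vertical"` or `"vector_magnitude"`.
#' @param extra optional named list of user cut-point sets, as produced by
#'   [cutpoint_set]; cannot override a built-in (name, axis) pair.
#' @return a `cutpoint_set` object.
#' @examples
#' get_cutpoint_set("pate", "vertical")
#' @export
get_cutpoint_set <- function(name, axis = c("vertical", "vector_magnitude"),
                             extra = NULL) {
  axis <- match.arg(axis)
  builtin <- .cutpoint_registry[[axis]][[name]]
  if (!is.null(builtin))
    return(cutpoint_set(name, axis, builtin[["sb_upper_cpm"]],
                        builtin[["mvpa_lower_cpm"]]))
  for (s in extra) {
    if (inherits(s, "cutpoint_set") && s$name == name && s$axis == axis)
      return(s)
  }
  if (name == "pate" && axis == "vector_magnitude")
    stop("cut-point set 'pate' is not defined on the vector magnitude ",
         "in its source study")
  stop("unknown cut-point set: (", name, ", ", axis, ")")
}

#' Construct a cut-point set
#'
#' @param name set label.
#' @param axis `"vertical"` or `"vector_magnitude"` — which per-epoch signal
#'   the thresholds apply to.
#' @param sb_upper_cpm sedentary upper bound, counts per minute (exclusive).
#' @param mvpa_lower_cpm MVPA lower bound, counts per minute (inclusive).
#' @return a `cutpoint_set` object.
#' @export
cutpoint_set <- function(name, axis, sb_upper_cpm, mvpa_lower_cpm) {
  axis <- match.arg(axis, c("vertical", "vector_magnitude"))
  stopifnot(sb_upper_cpm > 0, mvpa_lower_cpm > 0)
  if (sb_upper_cpm >= mvpa_lower_cpm)
    stop("sb_upper_cpm must be below mvpa_lower_cpm")
  builtin <- .cutpoint_registry[[axis]][[name]]
  if (!is.null(builtin) &&
      !(builtin[["sb_upper_cpm"]] == sb_upper_cpm &&
        builtin[["mvpa_lower_cpm"]] == mvpa_lower_cpm))
    stop("built-in cut-point set (", name, ", ", axis,
         ") cannot be overridden")
  structure(list(name = name, axis = axis,
                 sb_upper_cpm = sb_upper_cpm,
                 mvpa_lower_cpm = mvpa_lower_cpm),
            class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat("<cutpoint_set> ", x$name, " [", x$axis, "]: sedentary < ",
      x$sb_upper_cpm, " cpm, MVPA >= ", x$mvpa_lower_cpm, " cpm\n", sep = "")
  invisible(x)
}

#' Names of the built-in cut-point sets on an axis
#' @param axis `"vertical"` or `"vector_magnitude"`.
#' @return character vector of set names.
#' @export
builtin_cutpoint_names <- function(axis = c("vertical", "vector_magnitude")) {
  axis <- match.arg(axis)
  names(.cutpoint_registry[[axis]])
}

#' Cut-point thresholds rescaled to the analysis epoch
#'
#' Cut-points are published in counts per minute; a 5-s epoch sees 1/12 of a
#' minute, so thresholds scale by `epoch_len_s / 60`. The scaled values are
#' exact rationals (e.g. 800/12 cpm-equivalents per 5-s epoch); comparisons in
#' [classify_epoch] are done by cross-multiplication so no rounding ever
#' enters the boundary.
#'
#' @param set a `cutpoint_set`.
#' @param epoch_len_s epoch length in seconds, a divisor of 60.
#' @return named numeric vector `c(sb_upper, mvpa_lower)` on the per-epoch
#'   count scale.
#' @export
epoch_thresholds <- function(set, epoch_len_s) {
  stopifnot(inherits(set, "cutpoint_set"))
  check_epoch_len(epoch_len_s)
  c(sb_upper = set$sb_upper_cpm * epoch_len_s / 60,
    mvpa_lower = set$mvpa_lower_cpm * epoch_len_s / 60)
}

#' Classify epoch counts into intensity categories
#'
#' Boundary convention, mirroring how the source thresholds are published:
#' sedentary strictly below the sedentary upper bound, MVPA at or above the
#' MVPA lower bound, light in between. The comparison is
#' `count * 60 < sb_upper_cpm * epoch_len_s` (and likewise for MVPA), i.e.
#' exact rational arithmetic on the cpm scale — integer axis counts never hit
#' floating-point boundary drift.
#'
#' @param count non-negative per-epoch count(s) (vectorised).
#' @param set a `cutpoint_set`.
#' @param epoch_len_s epoch length in seconds.
#' @return factor with levels `sedentary`, `light`, `mvpa`.
#' @examples
#' classify_epoch(c(799, 800, 1680), get_cutpoint_set("pate"), 60)
#' @export
classify_epoch <- function(count, set, epoch_len_s) {
  stopifnot(inherits(set, "cutpoint_set"))
  check_epoch_len(epoch_len_s)
  if (anyNA(count) || any(count < 0)) stop("counts must be non-negative")
  lhs <- count * 60
  lab <- ifelse(lhs < set$sb_upper_cpm * epoch_len_s, "sedentary",
                ifelse(lhs >= set$mvpa_lower_cpm * epoch_len_s,
                       "mvpa", "light"))
  factor(lab, levels = c("sedentary", "light", "mvpa"))
}

#' Label the worn epochs of a series under one cut-point set
#'
#' Applies [classify_epoch] to the signal the set is calibrated on (vertical
#' axis counts or vector magnitude); non-worn epochs carry no label (`NA`).
#'
#' @param series a [count_series].
#' @param set a `cutpoint_set`.
#' @param wear logical vector from [wear_mask] (TRUE = worn). If `NULL`,
#'   every epoch is treated as worn.
#' @return factor of length `length(series)` with levels
#'   `sedentary`/`light`/`mvpa`; `NA` for non-worn epochs.
#' @export
classify_series <- function(series, set, wear = NULL) {
  stopifnot(inherits(series, "count_series"))
  signal <- if (set$axis == "vertical") series$counts[, 1L] else series$vm
  lab <- classify_epoch(signal, set, series$epoch_len_s)
  if (!is.null(wear)) {
    stopifnot(length(wear) == length(lab))
    lab[!wear] <- NA
  }
  lab
}
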
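#' Epoch-level tri-axial count series
#'
#' A `count_series` holds one child's accelerometer recording as a fixed-stride
#' sequence of epoch counts on three axes, together with the derived vector
#' magnitude (the Euclidean norm of the three axis counts per epoch).
#'
#' @param child_id single character id.
#' @param start POSIXct timestamp of the first epoch (epoch intervals are
#'   half-open `[t, t + epoch_len_s)`, so day assignment at midnight is
#'   unambiguous).
#' @param epoch_len_s epoch length in seconds; must divide 60.
#' @param axis1,axis2,axis3 non-negative integer count vectors of equal
#'   length; `axis1` is the vertical axis.
#' @return An object of class `count_series`: a list with elements
#'   `child_id`, `start`, `epoch_len_s`, `counts` (integer matrix, columns
#'   `axis1`, `axis2`, `axis3`) and `vm` (numeric vector magnitude, recomputed
#'   from the axes and never stored independently).
#' @examples
#' cs <- count_series("c1", as.POSIXct("2024-01-01", tz = "UTC"), 5,
#'                    c(0L, 10L), c(0L, 3L), c(0L, 4L))
#' cs$vm  # 0, sqrt(125)
#' @export
count_series <- function(child_id, start, epoch_len_s, axis1, axis2, axis3) {
  stopifnot(length(child_id) == 1L, inherits(start, "POSIXct"))
  check_epoch_len(epoch_len_s)
  n <- length(axis1)
  if (length(axis2) != n || length(axis3) != n)
    stop("axis count vectors must have equal length")
  counts <- cbind(axis1 = as.integer(axis1), axis2 = as.integer(axis2),
                  axis3 = as.integer(axis3))
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0L)) stop("counts must be non-negative")
  structure(list(child_id = as.character(child_id),
                 start = start,
                 epoch_len_s = as.integer(epoch_len_s),
                 counts = counts,
                 vm = sqrt(rowSums(counts^2))),
            class = "count_series")
}

# Sub-minute epochs must divide 60 so cpm thresholds rescale exactly;
# reintegrated epochs may be whole-minute multiples that divide the day.
check_epoch_len <- function(epoch_len_s) {
  ok <- length(epoch_len_s) == 1L && !is.na(epoch_len_s) && epoch_len_s > 0 &&
    (60 %% epoch_len_s == 0 ||
       (epoch_len_s %% 60 == 0 && 86400 %% epoch_len_s == 0))
  if (!ok)
    stop("epoch_len_s must divide 60, or be a whole-minute divisor of 86400",
         " (got ", epoch_len_s, ")")
  invisible(epoch_len_s)
}

#' @export
print.count_series <- function(x, ...) {
  n <- nrow(x$counts)
  cat("<count_series> child ", x$child_id, ": ", n, " epochs of ",
      x$epoch_len_s, " s from ",
      format(x$start, "%Y-%m-%d %H:%M:%S %Z"), "\n", sep = "")
  if (n > 0)
    cat("  vertical cpm (overall mean): ",
        round(mean(x$counts[, 1]) * 60 / x$epoch_len_s, 1), "\n", sep = "")
  invisible(x)
}

#' @export
length.count_series <- function(x) nrow(x$counts)

#' Epoch start timestamps of a count series
#' @param series a `count_series`.
#' @return POSIXct vector, one entry per epoch.
#' @export
epoch_times <- function(series) {
  series$start + (seq_len(nrow(series$counts)) - 1L) * series$epoch_len_s
}

#' Calendar date of each epoch
#' @param series a `count_series`.
#' @return Date vector (date of the epoch start, in the recording's clock).
#' @export
epoch_dates <- function(series) {
  as.Date(epoch_times(series), tz = "UTC")
}
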
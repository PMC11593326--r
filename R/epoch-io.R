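#' Read an epoch count CSV
#'
#' Reads the canonical epoch dialect: a UTF-8 CSV with header
#' `timestamp,axis1,axis2,axis3`, ISO-8601 timestamps at a constant stride,
#' and non-negative integer counts. The vector magnitude is computed on load,
#' never read from disk.
#'
#' @param path file path.
#' @param child_id id to attach; defaults to the file name without extension.
#' @return a [count_series].
#' @export
read_epoch_csv <- function(path, child_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "integer", "integer",
                                       "integer"))
  if (!identical(names(df), c("timestamp", "axis1", "axis2", "axis3")))
    stop("expected header 'timestamp,axis1,axis2,axis3' in ", path)
  if (is.null(child_id))
    child_id <- sub("\\.[^.]*$", "", basename(path))
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt))
    ts[alt] <- as.POSIXct(strptime(df$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop("unparseable timestamp at data row ", bad, " of ", path)
  }
  if (nrow(df) == 0L)
    stop("empty epoch file (no stride can be inferred): ", path)
  for (ax in c("axis1", "axis2", "axis3")) {
    if (anyNA(df[[ax]]))
      stop("non-integer count in column ", ax, " at data row ",
           which(is.na(df[[ax]]))[1L], " of ", path)
    if (any(df[[ax]] < 0L))
      stop("negative count in column ", ax, " at data row ",
           which(df[[ax]] < 0L)[1L], " of ", path)
  }
  if (nrow(df) >= 2L) {
    strides <- diff(as.numeric(ts))
    if (any(strides != strides[1L])) {
      bad <- which(strides != strides[1L])[1L] + 1L
      stop("non-constant stride at data row ", bad, " of ", path,
           " (expected ", strides[1L], " s, got ", strides[bad - 1L], " s)")
    }
    epoch_len_s <- strides[1L]
  } else {
    epoch_len_s <- 5L  # single row: stride unobservable, assume default epoch
  }
  count_series(child_id, ts[1L], epoch_len_s,
               df$axis1, df$axis2, df$axis3)
}

#' Write an epoch count CSV
#'
#' Inverse of [read_epoch_csv]: one row per epoch, header
#' `timestamp,axis1,axis2,axis3`, LF line endings, no locale-dependent
#' formatting. The vector magnitude is not written (it is derived).
#'
#' @param series a [count_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "count_series"))
  ts <- format(epoch_times(series), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df <- data.frame(timestamp = ts,
                   axis1 = series$counts[, 1L],
                   axis2 = series$counts[, 2L],
                   axis3 = series$counts[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Reintegrate a count series to a longer epoch
#'
#' Sums axis counts within each target window and recomputes the vector
#' magnitude from the summed axes. Published cut-points are expressed in
#' counts per minute, so 60-s reintegration is the usual route to cpm-scale
#' reporting; classification itself stays at the native epoch.
#'
#' @param series a [count_series].
#' @param target_epoch_s target epoch in seconds; must be a multiple of the
#'   series' epoch length and divide 86400, and the series length must be a
#'   whole number of target windows.
#' @return a [count_series] at the target epoch length.
#' @export
reintegrate <- function(series, target_epoch_s) {
  stopifnot(inherits(series, "count_series"))
  if (target_epoch_s %% series$epoch_len_s != 0)
    stop("target_epoch_s (", target_epoch_s,
         ") is not a multiple of the series epoch (", series$epoch_len_s, ")")
  if (86400 %% target_epoch_s != 0)
    stop("target_epoch_s must divide 86400")
  k <- target_epoch_s %/% series$epoch_len_s
  if (k == 1L) return(series)
  n <- nrow(series$counts)
  if (n %% k != 0)
    stop("series length ", n, " is not a whole number of ",
         target_epoch_s, "-s windows")
  grp <- rep(seq_len(n %/% k), each = k)
  agg <- rowsum(series$counts, grp, reorder = FALSE)
  count_series(series$child_id, series$start, target_epoch_s,
               agg[, 1L], agg[, 2L], agg[, 3L])
}
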
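#' 2x2 cross-classification of two binary labelings
#'
#' @param flags_first,flags_second named logical vectors (TRUE = active) over
#'   the same set of children.
#' @return a `crosstab_2x2` object: counts `a` (both active), `b` (first
#'   only), `c` (second only), `d` (both inactive), and `n`.
#' @export
crosstab <- function(flags_first, flags_second) {
  if (!is.null(names(flags_first)) || !is.null(names(flags_second))) {
    if (!setequal(names(flags_first), names(flags_second)))
      stop("the two labelings cover different child sets")
    flags_second <- flags_second[names(flags_first)]
  } else if (length(flags_first) != length(flags_second)) {
    stop("the two labelings cover different child sets")
  }
  contingency_2x2(sum(flags_first & flags_second),
                  sum(flags_first & !flags_second),
                  sum(!flags_first & flags_second),
                  sum(!flags_first & !flags_second))
}

#' Construct a 2x2 contingency table
#' @param a both-active count.
#' @param b first-active / second-inactive count.
#' @param c first-inactive / second-active count.
#' @param d both-inactive count.
#' @return a `crosstab_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(as.list(c(cells, n = sum(cells))), class = "crosstab_2x2")
}

#' @export
print.crosstab_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(first = c("active", "inactive"),
                              second = c("active", "inactive")))
  print(m)
  invisible(x)
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_o = (a + d)/n` and `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. When a
#' classifier is constant, `p_o = p_e` and kappa is exactly 0 — agreement
#' with an all-inactive classifier is never better than chance. In the fully
#' degenerate case `p_e = 1` (all mass in one cell) the convention is kappa 1
#' when observed agreement is also perfect, otherwise 0, with a warning.
#'
#' @param table a `crosstab_2x2`.
#' @return kappa, full precision (see [truncate3] for the reporting scale).
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "crosstab_2x2"))
  if (table$n < 1) stop("empty table")
  n <- table$n
  po <- (table$a + table$d) / n
  pe <- ((table$a + table$b) * (table$a + table$c) +
           (table$c + table$d) * (table$b + table$d)) / n^2
  if (pe == 1) {
    warning("degenerate table: expected agreement is 1")
    return(if (po == 1) 1 else 0)
  }
  # a constant classifier (degenerate margin) gives po == pe, hence kappa 0
  # exactly; compute it as such rather than through floating division
  if ((table$a + table$b) %in% c(0, n) || (table$a + table$c) %in% c(0, n))
    return(0)
  (po - pe) / (1 - pe)
}

#' Percent raw agreement for a 2x2 table
#' @param table a `crosstab_2x2`.
#' @param digits rounding for reporting (default 2, the printed convention).
#' @return percent agreement `100 (a + d) / n`.
#' @export
percent_agreement <- function(table, digits = 2) {
  stopifnot(inherits(table, "crosstab_2x2"))
  if (table$n < 1) stop("empty table")
  round(100 * (table$a + table$d) / table$n, digits)
}

#' Qualitative kappa band
#'
#' Standard qualitative interpretation: `<= 0` no agreement, `(0, 0.20)`
#' weak, `[0.20, 0.40)` reasonable, `[0.40, 0.60)` moderate, `[0.60, 0.80)`
#' substantial, `[0.80, 1.00]` excellent.
#'
#' @param kappa value in `[-1, 1]`.
#' @return character label.
#' @export
band_kappa <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1)
    stop("kappa must lie in [-1, 1]")
  if (kappa <= 0) "no agreement"
  else if (kappa < 0.20) "weak"
  else if (kappa < 0.40) "reasonable"
  else if (kappa < 0.60) "moderate"
  else if (kappa < 0.80) "substantial"
  else "excellent"
}

#' Truncate to three decimals
#'
#' Agreement studies commonly print kappa truncated (not rounded) to three
#' decimals; reconstructed values match the printed ones only under
#' truncation. Truncation is toward zero; a tiny epsilon absorbs binary
#' representation error (e.g. a value stored as 0.5759999999 for 0.576).
#'
#' @param x numeric.
#' @return x truncated to 3 decimals.
#' @export
truncate3 <- function(x) {
  sign(x) * floor(abs(x) * 1000 + 1e-9) / 1000
}

#' Reconstruct a 2x2 table from marginals and raw agreement
#'
#' Published comparisons often print only each classifier's active totals and
#' the percent raw agreement. Those three numbers (plus n) determine the full
#' table: with agreement count `A = round(pct * n / 100)`, the both-active
#' cell is `a = (first + second + A - n) / 2`, and the remaining cells follow
#' from the marginals. The solution is verified by brute force over all
#' feasible `a` and must be unique and non-negative.
#'
#' @param n number of children.
#' @param first_active_total,second_active_total active counts under each
#'   classifier.
#' @param percent_agreement raw agreement in percent.
#' @return a `crosstab_2x2`.
#' @examples
#' reconstruct_2x2(74, 58, 44, 81.08)  # a=44 b=14 c=0 d=16
#' @export
reconstruct_2x2 <- function(n, first_active_total, second_active_total,
                            percent_agreement) {
  stopifnot(n >= 1, first_active_total >= 0, second_active_total >= 0,
            first_active_total <= n, second_active_total <= n)
  A <- round(percent_agreement * n / 100)
  # brute-force scan: feasible a with consistent cells and agreement A
  sols <- list()
  for (a in 0:min(first_active_total, second_active_total)) {
    b <- first_active_total - a
    c <- second_active_total - a
    d <- n - a - b - c
    if (d >= 0 && a + d == A)
      sols[[length(sols) + 1L]] <- c(a, b, c, d)
  }
  if (length(sols) == 0L)
    stop("infeasible marginals: no 2x2 table has totals (",
         first_active_total, ", ", second_active_total, ") with agreement ",
         A, "/", n)
  if (length(sols) > 1L)
    stop("marginals do not determine the table uniquely")
  s <- sols[[1L]]
  contingency_2x2(s[1L], s[2L], s[3L], s[4L])
}

#' Pairwise agreement of active/inactive classifications
#'
#' For each sex x period x unordered pair of cut-point sets, cross-tabulates
#' the per-child active flags and reports the cell counts, percent agreement,
#' Cohen's kappa (truncated to 3 decimals for reporting) and its qualitative
#' band.
#'
#' @param period_sums row-bound [period_summary] output across sets/periods.
#' @param metadata cohort metadata (`child_id`, `sex`); if `NULL` the
#'   analysis is not split by sex.
#' @return data.frame: `sex`, `period`, `set_first`, `set_second`, `n`,
#'   `a`, `b`, `c`, `d`, `pct_agreement`, `kappa`, `band`.
#' @export
agreement_matrix <- function(period_sums, metadata = NULL) {
  ps <- period_sums
  ps$set_label <- paste(ps$set_name, ps$axis, sep = ".")
  ps$sex <- if (is.null(metadata)) "all"
            else metadata$sex[match(ps$child_id, metadata$child_id)]
  out <- list()
  for (sx in unique(ps$sex)) for (pd in unique(ps$period)) {
    g <- ps[ps$sex == sx & ps$period == pd, ]
    sets <- unique(g$set_label)
    if (length(sets) < 2) next
    for (i in seq_along(sets)[-length(sets)]) for (j in (i + 1):length(sets)) {
      f1 <- g[g$set_label == sets[i], ]
      f2 <- g[g$set_label == sets[j], ]
      common <- intersect(f1$child_id, f2$child_id)
      if (length(common) == 0) next
      t <- crosstab(stats::setNames(f1$active[match(common, f1$child_id)],
                                    common),
                    stats::setNames(f2$active[match(common, f2$child_id)],
                                    common))
      kap <- cohen_kappa(t)
      out[[length(out) + 1L]] <- data.frame(
        sex = sx, period = pd,
        set_first = sets[i], set_second = sets[j],
        n = t$n, a = t$a, b = t$b, c = t$c, d = t$d,
        pct_agreement = percent_agreement(t),
        kappa = truncate3(kap), band = band_kappa(kap),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
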
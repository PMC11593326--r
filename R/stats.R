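#' Pearson chi-square for a 2x2 table
#'
#' Two-sided Pearson chi-square on one degree of freedom, WITHOUT Yates
#' continuity correction (the convention that reproduces the printed
#' sex-difference p-values in cut-point comparison tables).
#'
#' @param table 2x2 numeric matrix of counts (rows = groups, columns =
#'   active/inactive), or a `crosstab_2x2`.
#' @return named vector `c(statistic, p)`.
#' @export
chi2_2x2 <- function(table) {
  if (inherits(table, "crosstab_2x2"))
    table <- matrix(c(table$a, table$b, table$c, table$d), 2, byrow = TRUE)
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("a zero margin leaves the chi-square p-value undefined")
  ct <- stats::chisq.test(table, correct = FALSE)
  c(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' A-priori sample size for a paired t-test
#'
#' Smallest n whose two-sided one-sample t-test on paired differences reaches
#' the target power, computed from the noncentral t distribution: with
#' standardized effect `dz`, the test statistic under the alternative is
#' noncentral t with `df = n - 1` and noncentrality `dz * sqrt(n)`; power is
#' the rejection probability at the two-sided critical value
#' `t(1 - alpha/2, n - 1)`.
#'
#' @param effect_size_dz standardized paired difference (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param n_max search bound; exceeding it raises an error ("unreachable
#'   power").
#' @return list with `n` (required subjects), `critical_t` (two-sided
#'   critical value at `df = n - 1`) and `power` (achieved power at `n`).
#' @examples
#' paired_t_sample_size(0.5, 0.05, 0.95)  # n = 54, critical t ~= 2.006
#' @export
paired_t_sample_size <- function(effect_size_dz, alpha = 0.05, power = 0.95,
                                 n_max = 1e6) {
  stopifnot(effect_size_dz > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    pw <- paired_t_power(n, effect_size_dz, alpha)
    if (pw >= power)
      return(list(n = n, critical_t = stats::qt(1 - alpha / 2, n - 1),
                  power = pw))
  }
  stop("target power unreachable within n_max = ", n_max)
}

#' Power of the two-sided paired t-test at sample size n
#' @param n number of pairs.
#' @param effect_size_dz standardized paired difference.
#' @param alpha two-sided significance level.
#' @return rejection probability under the alternative.
#' @export
paired_t_power <- function(n, effect_size_dz, alpha = 0.05) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- effect_size_dz * sqrt(n)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Mean with t-based confidence interval
#'
#' @param values numeric sample, n >= 2.
#' @param level confidence level.
#' @return named vector `c(mean, se, lower, upper)` with
#'   `mean +- t(1 - (1-level)/2, n-1) * se`.
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  stopifnot(n >= 2)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, n - 1)
  c(mean = m, se = se, lower = m - tq * se, upper = m + tq * se)
}

#' Bonferroni-corrected pairwise paired comparisons with letter groups
#'
#' Runs all pairwise paired t-tests between the columns (one column per
#' cut-point set, one row per child), multiplies each p-value by the number
#' of pairs (capped at 1), and assigns similarity letters: columns connected
#' by any chain of non-significant differences share a letter (connected
#' components of the non-significance graph — the compact-letter-display
#' convention), with letters ordered by descending mean.
#'
#' @param x numeric matrix or data.frame, children x sets, no missing values.
#' @param alpha significance level after correction.
#' @param conf_level level for the per-set confidence intervals.
#' @return list with `groups` (data.frame: `set`, `mean`, `se`, `lower`,
#'   `upper`, `letter`) and `pairs` (data.frame: `set1`, `set2`,
#'   `p_adjusted`).
#' @export
pairwise_letters <- function(x, alpha = 0.05, conf_level = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 paired observations")
  k <- ncol(x)
  sets <- colnames(x)
  if (is.null(sets)) sets <- paste0("set", seq_len(k))
  n_pairs <- k * (k - 1) / 2
  pairs <- list()
  adj <- diag(TRUE, k)  # non-significance graph (self-loops)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diffs <- x[, i] - x[, j]
    # (near-)constant differences: t.test refuses, but the limit is clear —
    # a zero shift is perfect similarity, a non-zero one is t -> infinity
    p <- if (stats::sd(diffs) <= 1e-10 * max(1, abs(mean(diffs)))) {
      if (abs(mean(diffs)) <= 1e-10) 1 else 0
    } else stats::t.test(x[, i], x[, j], paired = TRUE)$p.value
    p_adj <- min(1, p * n_pairs)
    ns <- p_adj >= alpha
    adj[i, j] <- adj[j, i] <- ns
    pairs[[length(pairs) + 1L]] <- data.frame(set1 = sets[i], set2 = sets[j],
                                              p_adjusted = p_adj,
                                              stringsAsFactors = FALSE)
  }
  # connected components of the non-significance graph
  comp <- seq_len(k)
  repeat {
    new <- comp
    for (i in seq_len(k)) for (j in seq_len(k))
      if (adj[i, j]) new[i] <- min(new[i], new[j], comp[i], comp[j])
    if (identical(new, comp)) break
    comp <- new
  }
  means <- colMeans(x)
  comp_order <- unique(comp[order(-means)])
  letter <- LETTERS[match(comp, comp_order)]
  groups <- do.call(rbind, lapply(seq_len(k), function(i) {
    ci <- mean_ci(x[, i], level = conf_level)
    data.frame(set = sets[i], mean = ci[["mean"]], se = ci[["se"]],
               lower = ci[["lower"]], upper = ci[["upper"]],
               letter = letter[i], stringsAsFactors = FALSE)
  }))
  groups <- groups[order(-groups$mean), ]
  rownames(groups) <- NULL
  list(groups = groups, pairs = do.call(rbind, pairs))
}
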
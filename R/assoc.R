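#' Container for a single association result
#'
#' @param estimate point estimate (odds ratio, statistic, correlation).
#' @param ci_low,ci_high 95% confidence bounds (`NA` when not defined).
#' @param p_value two-sided p-value.
#' @param n_used number of observations used.
#' @param method label describing estimator and CI method.
#' @param extra optional named list of method-specific fields.
#' @export
assoc_result <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                         p_value = NA_real_, n_used = NA_integer_,
                         method = "", extra = list()) {
  structure(c(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                   p_value = p_value, n_used = as.integer(n_used),
                   method = method), extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s: estimate=%.4g", x$method, x$estimate))
  if (!is.na(x$ci_low)) cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci_low, x$ci_high))
  if (!is.na(x$p_value)) cat(sprintf(", p=%.3g", x$p_value))
  if (!is.na(x$n_used)) cat(sprintf(", n=%d", x$n_used))
  cat("\n")
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' Sample (cross-product) odds ratio `ad / bc` with a Woolf confidence
#' interval (normal approximation on the log odds ratio) and a two-sided
#' normal test of log OR = 0. When any cell is zero the standard
#' Haldane-Anscombe continuity correction (+0.5 to every cell) is applied
#' and flagged in the method label. `method = "exact"` instead returns the
#' conditional maximum-likelihood estimate with an exact CI
#' (via [stats::fisher.test()]).
#'
#' The table is laid out as `a` exposed-and-outcome, `b` exposed-only,
#' `c` outcome-only, `d` neither; the estimate is invariant to swapping
#' exposure with outcome.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param method `"woolf"` (default) or `"exact"`.
#' @return an [assoc_result()].
#' @export
odds_ratio_2x2 <- function(a, b, c, d, method = c("woolf", "exact")) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_input("cell counts must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop_input("all-zero 2x2 table")

  if (method == "exact") {
    ft <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))
    return(assoc_result(unname(ft$estimate), ft$conf.int[1], ft$conf.int[2],
                        ft$p.value, n, method = "odds_ratio_exact"))
  }

  label <- "odds_ratio_woolf"
  if (any(cells == 0)) {
    cells <- cells + 0.5
    label <- "odds_ratio_woolf_haldane"
  }
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  zc <- stats::qnorm(0.975)
  ci <- exp(log(est) + c(-1, 1) * zc * se)
  p <- 2 * stats::pnorm(-abs(log(est)) / se)
  assoc_result(est, ci[1], ci[2], p, n, method = label)
}

#' Odds ratios within levels of a moderator (optionally by stratum)
#'
#' Cross-tabulates a binary outcome against a binary exposure within each
#' level of a categorical moderator, on complete cases within the level,
#' and returns one odds ratio per level — and per stratum level when a
#' stratum column (e.g. gender) is given. Levels with an empty table
#' margin are flagged undefined rather than dropped.
#'
#' @param table a cohort table.
#' @param outcome,exposure names of binary factor columns.
#' @param moderator name of a categorical column.
#' @param stratum optional name of a further grouping column; results are
#'   reported per moderator level overall and within each stratum level.
#' @param method passed to [odds_ratio_2x2()].
#' @return data.frame of class `stratified_or_table`: moderator level,
#'   stratum (`"all"` for the pooled rows), n, estimate, ci_low, ci_high,
#'   p_value, defined.
#' @export
stratified_or <- function(table, outcome, exposure, moderator, stratum = NULL,
                          method = "woolf") {
  for (col in c(outcome, exposure, moderator, stratum)) {
    if (!col %in% names(table)) stop_input("unknown column '", col, "'")
  }
  # overall rows use complete cases on the analysis triple; stratum-specific
  # rows additionally require an observed stratum
  tab <- suppressMessages(complete_case_filter(table, c(outcome, exposure, moderator)))

  one_stratum <- function(dat, mod_level, stratum_label) {
    sub <- dat[dat[[moderator]] == mod_level, , drop = FALSE]
    y <- factor(sub[[outcome]]); x <- factor(sub[[exposure]])
    ct <- table(x, y)
    if (!all(dim(ct) == c(2, 2)) || any(rowSums(ct) == 0) || any(colSums(ct) == 0)) {
      return(data.frame(moderator_level = mod_level, stratum = stratum_label,
                        n = nrow(sub), estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_, defined = FALSE))
    }
    # orient so "a" is exposure level 2 & outcome level 2 (present/present)
    res <- odds_ratio_2x2(ct[2, 2], ct[2, 1], ct[1, 2], ct[1, 1], method = method)
    data.frame(moderator_level = mod_level, stratum = stratum_label, n = nrow(sub),
               estimate = res$estimate, ci_low = res$ci_low, ci_high = res$ci_high,
               p_value = res$p_value, defined = TRUE)
  }

  mod_levels <- levels(factor(tab[[moderator]]))
  rows <- list()
  for (ml in mod_levels) {
    rows[[length(rows) + 1]] <- one_stratum(tab, ml, "all")
    if (!is.null(stratum)) {
      for (sl in levels(factor(tab[[stratum]]))) {
        sub <- tab[!is.na(tab[[stratum]]) & tab[[stratum]] == sl, , drop = FALSE]
        rows[[length(rows) + 1]] <- one_stratum(sub, ml, sl)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stratified_or_table", "data.frame")
  out
}

#' Pearson chi-squared test for equal proportions
#'
#' Tests whether a binary outcome has the same proportion across groups
#' (standard Pearson X^2 on the groups-by-2 table, no continuity
#' correction). A flag is raised when any expected cell is below 1.
#'
#' @param successes vector of success counts per group.
#' @param totals vector of group sizes.
#' @return an [assoc_result()] with the X^2 statistic (df in `extra`).
#' @export
chisq_equal_proportions <- function(successes, totals) {
  if (length(successes) < 2 || length(successes) != length(totals)) {
    stop_input("need success and total counts for at least 2 groups")
  }
  if (any(successes < 0) || any(totals < successes)) {
    stop_input("counts must satisfy 0 <= successes <= totals")
  }
  tab <- cbind(successes, totals - successes)
  if (all(colSums(tab) > 0)) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low_expected <- any(expected < 1)
  } else low_expected <- TRUE
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  assoc_result(unname(ct$statistic), p_value = ct$p.value, n_used = sum(totals),
               method = "pearson_chisq_equal_proportions",
               extra = list(df = unname(ct$parameter),
                            low_expected_flag = low_expected))
}

#' Two-sample Wilcoxon rank-sum test for ordinal data
#'
#' Reports the rank-sum of the first sample. For small inputs (total n at
#' or below `exact_max`) the two-sided p-value is computed by exact
#' enumeration of all assignments of the pooled values to the two groups
#' (valid under ties), doubling the smaller tail and capping at 1. Larger
#' samples use the tie-corrected normal approximation without continuity
#' correction.
#'
#' @param x,y numeric or ordered-factor samples (ordinal level codes).
#' @param exact_max largest pooled size for exact enumeration (default 10).
#' @return an [assoc_result()] with the rank-sum of `x` as estimate.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  if (is.factor(x)) x <- as.integer(x)
  if (is.factor(y)) y <- as.integer(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop_input("both samples must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])

  if (n <= exact_max) {
    sums <- utils::combn(n, n1, function(idx) sum(r[idx]))
    p_lo <- mean(sums <= w + 1e-9)
    p_hi <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "wilcoxon_rank_sum_exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "wilcoxon_rank_sum_normal_tie_corrected"
  }
  assoc_result(w, p_value = p, n_used = n, method = method,
               extra = list(n_x = n1, n_y = n2))
}

#' Spearman correlation with a percentile bootstrap CI
#'
#' Spearman's rho on complete pairs, with a percentile bootstrap CI over
#' `B` resamples of the pairs and an asymptotic p-value. A constant input
#' vector leaves rho undefined and is flagged in the method label.
#'
#' @param x,y paired samples (numeric or ordered factors).
#' @param B number of bootstrap resamples (default 200).
#' @param seed integer seed for the resampling.
#' @return an [assoc_result()].
#' @export
spearman_bootstrap_ci <- function(x, y, B = 200, seed = NULL) {
  if (B < 1) stop_input("B must be >= 1")
  if (is.factor(x)) x <- as.integer(x)
  if (is.factor(y)) y <- as.integer(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_input("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(assoc_result(NA_real_, n_used = n,
                        method = "spearman_undefined_constant_input"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  pv <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  assoc_result(rho, ci[1], ci[2], pv, n,
               method = sprintf("spearman_percentile_bootstrap_B%d", B))
}
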
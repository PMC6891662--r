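# Classical statistics used for the assay comparisons: one-way ANOVA with
# Tukey HSD, Levene's homogeneity statistic (reported, never gating), and
# the Pearson chi-square test on 2x2 counts. Implemented from the
# sum-of-squares / observed-expected decompositions directly; only the
# reference distributions (F, studentized range, chi-square) come from R's
# distribution functions.

# coerce a list of samples or a (group, value) data frame to a named list
.as_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (is.null(groups$group) || is.null(groups$value))
      stop("data frame input needs 'group' and 'value' columns")
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2)
    stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two observations")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' One-way analysis of variance with Tukey's HSD
#'
#' Classical between/within sum-of-squares decomposition:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` with the p-value from the F
#' distribution. All pairwise group contrasts are assessed with Tukey's
#' honestly-significant-difference test via studentized-range quantiles
#' (Tukey-Kramer standard error for unequal group sizes). Levene's
#' statistic (absolute deviations from group means) is reported alongside
#' as a homogeneity-of-variance check, but never alters the ANOVA itself.
#'
#' @param groups A list of numeric vectors (one per group, each of length
#'   `>= 2`) or a long data frame with `group` and `value` columns.
#' @param alpha Significance level for flagging Tukey pairs (default 0.05).
#' @return An object of class `anova_result`: `F`, `df_between` (`k - 1`),
#'   `df_within` (`N - k`), `p`, `group_means`, `group_n`, `ms_within`,
#'   `tukey_pairs` (data frame `group1, group2, diff, q, p_adj,
#'   significant`), `levene` (`statistic`, `p`), and a `degenerate` flag
#'   set when the within-group variance is zero while means differ (p is
#'   then reported below machine minimum).
#' @examples
#' one_way_anova(list(ctrl = c(5, 6, 5.5), a = c(7, 8, 7.5), b = c(5, 5.2, 5.1)))
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  groups <- .as_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - m[i])^2),
                    numeric(1)))
  df_b <- k - 1L; df_w <- N - k
  msb <- ssb / df_b; msw <- ssw / df_w
  degenerate <- msw == 0 && ssb > 0
  F <- if (msw == 0) { if (ssb > 0) Inf else 0 } else msb / msw
  p <- if (degenerate) 0 else pf(F, df_b, df_w, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  tukey <- data.frame(
    group1 = names(groups)[pairs[1, ]], group2 = names(groups)[pairs[2, ]],
    diff = m[pairs[2, ]] - m[pairs[1, ]])
  se <- sqrt(msw / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  tukey$q <- ifelse(se > 0, abs(tukey$diff) / se,
                    ifelse(tukey$diff == 0, 0, Inf))
  tukey$p_adj <- ifelse(is.finite(tukey$q),
                        ptukey(tukey$q, k, df_w, lower.tail = FALSE), 0)
  tukey$significant <- tukey$p_adj < alpha
  rownames(tukey) <- NULL

  # Levene (center = mean) on absolute deviations, reported only
  absdev <- lapply(seq_len(k), function(i) abs(groups[[i]] - m[i]))
  lm_ <- vapply(absdev, mean, numeric(1))
  lgrand <- sum(unlist(absdev)) / N
  lssb <- sum(n * (lm_ - lgrand)^2)
  lssw <- sum(vapply(seq_len(k), function(i) sum((absdev[[i]] - lm_[i])^2),
                     numeric(1)))
  lF <- if (lssw == 0) { if (lssb > 0) Inf else 0 } else
    (lssb / df_b) / (lssw / df_w)
  lp <- if (is.finite(lF)) pf(lF, df_b, df_w, lower.tail = FALSE) else 0

  structure(list(F = F, df_between = df_b, df_within = df_w, p = p,
                 group_means = m, group_n = n, ss_between = ssb,
                 ss_within = ssw, ms_within = msw, tukey_pairs = tukey,
                 levene = list(statistic = lF, p = lp),
                 degenerate = degenerate, alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " (degenerate: zero within-group variance)" else ""))
  cat("Group means:\n"); print(round(x$group_means, 4))
  cat(sprintf("Levene homogeneity: F = %.4g, p = %.4g\n",
              x$levene$statistic, x$levene$p))
  cat("Tukey HSD pairs:\n"); print(x$tukey_pairs, digits = 4)
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' `chi2 = sum((O - E)^2 / E)` with expected counts from the margins and
#' one degree of freedom. The Yates continuity correction is off by
#' default — the assay comparisons involve thousands of cells, where the
#' correction is negligible and the uncorrected statistic is standard — but
#' can be switched on.
#'
#' @param table A 2x2 matrix of nonnegative integer counts with positive
#'   margins (e.g. spread/round by treatment/control).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return An object of class `chisq_result`: `chi2`, `df` (always 1),
#'   `p`, `table`, `expected`, `correct`.
#' @examples
#' chi_square_2x2(matrix(c(300, 150, 200, 350), 2))
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column margins must be positive")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  corr <- if (correct) 0.5 else 0
  chi2 <- sum(pmax(abs(table - E) - corr, 0)^2 / E)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = 1L, p = p, table = table,
                 expected = E, correct = correct),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square%s: chi2(1) = %.4g, p = %.4g\n",
              if (x$correct) " (Yates-corrected)" else "", x$chi2, x$p))
  invisible(x)
}
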
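#' Two-sided p-value for a zero intercept (group-A family)
#'
#' Tests `intercept = 0` against `intercept != 0` using the t-statistic
#' `intercept / intercept_se` on `n - 2` degrees of freedom:
#' `p = 2 * F_df(-|t|)` with `F_df` the t cumulative distribution function.
#' Degenerate fits yield p = 1.
#'
#' @param fit A [fit_gene_regression()] result, or a fit table from
#'   [fit_all_genes()] (vectorized).
#' @return p-value(s) in \[0, 1\].
#' @export
null_intercept_pvalue <- function(fit) {
  if (is.data.frame(fit)) {
    p <- 2 * stats::pt(-abs(fit$t_intercept), fit$df)
    p[fit$degenerate] <- 1
    return(p)
  }
  fit <- .as_fit(fit)
  if (isTRUE(fit$degenerate)) return(1)
  2 * stats::pt(-abs(fit$t_intercept), fit$df)
}

#' One-sided upper-tail p-value against a calibrated level (group-B family)
#'
#' Tests the intercept against the calibrated level `lam` via the shifted
#' t-statistic `t = (intercept - lam) / intercept_se` on `n - 2` degrees of
#' freedom, reporting the upper tail `p = 1 - F_df(t)`. Small values occur
#' when the fitted intercept lies far above `lam`. Degenerate fits yield
#' p = 1; an exact fit (`intercept_se = 0`) yields 0, 0.5 or 1 by the sign
#' of `intercept - lam`.
#'
#' @param fit A [fit_gene_regression()] result, or a fit table from
#'   [fit_all_genes()] (vectorized).
#' @param lam Calibrated level(s), finite, in contrast units.
#' @param tail `"upper"` (default): `p = 1 - F_df(t)`, small when the
#'   intercept sits far above `lam`; `"lower"` mirrors it. The upper tail is
#'   the printed form of the test; the flag exists because the hypothesis
#'   "intercept > lambda" can be read with either rejection direction.
#' @return p-value(s) in \[0, 1\].
#' @export
alternative_pvalue <- function(fit, lam, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  upper <- tail == "upper"
  if (!all(is.finite(lam))) stop("'lam' must be finite")
  if (is.data.frame(fit)) {
    tshift <- (fit$intercept - lam) / fit$intercept_se
    zero_se <- !fit$degenerate & !is.na(fit$intercept_se) & fit$intercept_se == 0
    tshift[zero_se] <- ifelse(fit$intercept[zero_se] == lam[zero_se], 0,
                              sign(fit$intercept[zero_se] - lam[zero_se]) * Inf)
    p <- stats::pt(tshift, fit$df, lower.tail = !upper)
    p[fit$degenerate] <- 1
    return(p)
  }
  fit <- .as_fit(fit)
  if (isTRUE(fit$degenerate)) return(1)
  if (fit$intercept_se == 0) {
    d <- fit$intercept - lam
    p0 <- if (d == 0) 0.5 else if (d > 0) 0 else 1
    return(if (upper) p0 else 1 - p0)
  }
  stats::pt((fit$intercept - lam) / fit$intercept_se, fit$df,
            lower.tail = !upper)
}

.check_pvec <- function(pvals) {
  if (length(pvals) == 0) return(invisible(pvals))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  invisible(pvals)
}

.check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("'level' must be a single number strictly between 0 and 1")
  invisible(level)
}

#' Bonferroni rejections controlling the familywise error rate
#'
#' Rejects hypothesis j when `p[j] <= level / m` for a family of m
#' p-values (via [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param level Familywise error level in (0, 1).
#' @return Sorted integer indices of the rejected hypotheses.
#' @export
bonferroni_reject <- function(pvals, level) {
  .check_level(level)
  .check_pvec(pvals)
  if (length(pvals) == 0) return(integer(0))
  which(stats::p.adjust(pvals, method = "bonferroni") <= level)
}

#' Benjamini-Hochberg rejections controlling the false discovery rate
#'
#' Step-up rule: with sorted p-values p_(1) <= ... <= p_(m), find the
#' largest k with `p_(k) <= k * level / m` and reject every hypothesis with
#' `p <= p_(k)`; ties at the critical value share its fate. Implemented via
#' [stats::p.adjust()], whose BH-adjusted values reproduce exactly this set.
#'
#' @inheritParams bonferroni_reject
#' @param level Target false discovery rate in (0, 1).
#' @return Sorted integer indices of the rejected hypotheses.
#' @export
bh_reject <- function(pvals, level) {
  .check_level(level)
  .check_pvec(pvals)
  if (length(pvals) == 0) return(integer(0))
  which(stats::p.adjust(pvals, method = "BH") <= level)
}

#' Assemble the per-gene table of both p-value families
#'
#' @param gene_names Character vector, length m.
#' @param p_null p-values of the zero-intercept family (group A).
#' @param p_alt p-values of the calibrated alternative family (group B).
#' @param lambda Calibrated levels, length m.
#' @return An object of class `gene_test_table`: a data frame with columns
#'   `gene`, `p_null`, `p_alt`, `lambda`.
#' @export
gene_test_table <- function(gene_names, p_null, p_alt, lambda) {
  m <- length(gene_names)
  if (length(p_null) != m || length(p_alt) != m || length(lambda) != m)
    stop("gene_names, p_null, p_alt and lambda must have equal length")
  .check_pvec(p_null)
  .check_pvec(p_alt)
  structure(data.frame(gene = as.character(gene_names), p_null = p_null,
                       p_alt = p_alt, lambda = lambda,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("gene_test_table", "data.frame"))
}

#' Apply the dual-family multiple-testing correction
#'
#' The two families (m zero-intercept p-values, m calibrated-alternative
#' p-values) are corrected separately, each at level `alpha / 2`, so that
#' the overall type I error stays below `alpha`.
#'
#' @param table A [gene_test_table()].
#' @param alpha Overall error budget in (0, 1); each family is tested at
#'   `alpha / 2`. Default 0.05.
#' @param correction `"bh"` (false discovery rate, default) or
#'   `"bonferroni"` (familywise error rate).
#' @return An object of class `rejection_sets`: list with `correction`,
#'   `alpha`, `rejected_null` and `rejected_alt` (sorted integer index
#'   sets into the table's rows).
#' @export
evaluate_hypotheses <- function(table, alpha = 0.05,
                                correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  .check_level(alpha)
  reject <- if (correction == "bh") bh_reject else bonferroni_reject
  structure(list(correction = correction, alpha = alpha,
                 rejected_null = reject(table$p_null, alpha / 2),
                 rejected_alt = reject(table$p_alt, alpha / 2)),
            class = "rejection_sets")
}

#' @export
print.rejection_sets <- function(x, ...) {
  cat(sprintf("Rejections (%s, alpha = %g, %g per family):\n",
              if (x$correction == "bh") "FDR/Benjamini-Hochberg"
              else "FWER/Bonferroni",
              x$alpha, x$alpha / 2))
  cat("  zero-intercept family:", length(x$rejected_null), "rejected\n")
  cat("  alternative family:   ", length(x$rejected_alt), "rejected\n")
  invisible(x)
}

#' Report the genes rejected in both families
#'
#' The findings are the intersection of the two rejection sets: genes whose
#' zero-intercept hypothesis is rejected in group A and whose calibrated
#' alternative-level hypothesis is rejected in group B. An empty
#' intersection is a valid report. Output is sorted by gene name so
#' repeated runs diff cleanly, and it is tagged with the error criterion
#' (FWER vs FDR) the correction controls.
#'
#' @param sets A [evaluate_hypotheses()] result.
#' @param table The [gene_test_table()] the sets were computed from.
#' @return An object of class `findings`: a data frame with columns `gene`,
#'   `p_null`, `p_alt`, `lambda`, plus attributes `correction`, `criterion`
#'   ("FWER" or "FDR") and `alpha`.
#' @export
report_findings <- function(sets, table) {
  stopifnot(inherits(sets, "rejection_sets"))
  idx <- intersect(sets$rejected_null, sets$rejected_alt)
  out <- table[idx, c("gene", "p_null", "p_alt", "lambda"), drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            correction = sets$correction,
            criterion = if (sets$correction == "bh") "FDR" else "FWER",
            alpha = sets$alpha,
            class = c("findings", "data.frame"))
}

#' @export
print.findings <- function(x, ...) {
  cat(sprintf("Findings under %s control (%s, alpha = %g): %d gene(s)\n",
              attr(x, "criterion"), attr(x, "correction"), attr(x, "alpha"),
              nrow(x)))
  if (nrow(x)) print.data.frame(x, digits = 7)
  else cat("  (empty set)\n")
  invisible(x)
}
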
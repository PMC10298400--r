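#' Dual-hypothesis test of longitudinal expression contrasts
#'
#' The main fitting function. For each gene of a two-group study design the
#' contrast (timepoint-2 minus timepoint-1 expression) is regressed on age
#' with an intercept, separately in the two groups. Group A supplies the
#' zero-intercept family: a two-sided t-test of `intercept = 0`. Group B
#' supplies the alternative family: its fitted intercept is first degraded
#' until the fit retains only the fraction `pi` of its original R-squared,
#' giving a per-gene level `lambda`, and the one-sided upper-tail t-test of
#' the intercept against `lambda` is carried out. The two families of m
#' p-values are corrected separately at `alpha / 2` each (Bonferroni or
#' Benjamini-Hochberg), and the genes rejected in both families are the
#' findings.
#'
#' @param design A [study_design()], e.g. from [build_contrasts()] or
#'   [simulate_study()].
#' @param alpha Overall error budget, split as `alpha / 2` per family.
#'   Default 0.05.
#' @param pi R-squared fraction retained by the calibrated intercept, in
#'   (0, 1). Default 0.35.
#' @param correction `"bh"` (FDR control, default) or `"bonferroni"`
#'   (FWER control).
#' @param direction Calibration root: `"below"` (default) or `"above"` the
#'   fitted group-B intercept.
#' @param method Calibration solver: `"closed_form"` (default) or
#'   `"binary_search"`.
#' @return An object of class `contrast_test`: a list with elements
#'   `fits_A`, `fits_B` (per-gene fit tables), `calibration`, `table` (the
#'   [gene_test_table()]), `rejections`, `findings`, `config`, `n1`, `n2`,
#'   `m` and `gene_names`. Supported methods: `print`, `summary`, `coef`,
#'   `plot`, [results_table()].
#' @examples
#' sim <- simulate_study(n1 = 10, n2 = 10, m = 20, signal_genes = 1:3,
#'                       noise_sd = 0.5, seed = 7)
#' ct <- contrast_test(sim$design)
#' summary(ct)
#' @seealso [run_pipeline()] for the file-based interface.
#' @export
contrast_test <- function(design, alpha = 0.05, pi = 0.35,
                          correction = c("bh", "bonferroni"),
                          direction = c("below", "above"),
                          method = c("closed_form", "binary_search")) {
  stopifnot(inherits(design, "study_design"))
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  method <- match.arg(method)
  .check_level(alpha)
  .check_pi(pi)

  fits_A <- fit_all_genes(design$contrast_A)
  fits_B <- fit_all_genes(design$contrast_B)
  cal <- calibrate_all(fits_B, pi = pi, direction = direction, method = method)
  table <- gene_test_table(design$gene_names,
                           p_null = null_intercept_pvalue(fits_A),
                           p_alt = alternative_pvalue(fits_B, cal$lambda),
                           lambda = cal$lambda)
  sets <- evaluate_hypotheses(table, alpha = alpha, correction = correction)
  findings <- report_findings(sets, table)

  structure(list(fits_A = fits_A, fits_B = fits_B, calibration = cal,
                 table = table, rejections = sets, findings = findings,
                 config = list(alpha = alpha, pi = pi, correction = correction,
                               direction = direction, method = method),
                 n1 = nrow(design$contrast_A$values),
                 n2 = nrow(design$contrast_B$values),
                 m = design$m, gene_names = design$gene_names),
            class = "contrast_test")
}

#' @export
print.contrast_test <- function(x, ...) {
  cat("Dual-hypothesis contrast test\n")
  cat(sprintf("  %d genes; group A n = %d, group B n = %d\n", x$m, x$n1, x$n2))
  cat(sprintf("  alpha = %g (%g per family), pi = %g, correction = %s\n",
              x$config$alpha, x$config$alpha / 2, x$config$pi,
              x$config$correction))
  cat(sprintf("  rejected: %d (zero-intercept family), %d (alternative family)\n",
              length(x$rejections$rejected_null),
              length(x$rejections$rejected_alt)))
  cat(sprintf("  findings (both families): %d gene(s)\n", nrow(x$findings)))
  invisible(x)
}

#' Summarize a contrast test
#'
#' @param object A [contrast_test()] result.
#' @param ... Unused.
#' @return An object of class `summary.contrast_test`.
#' @export
summary.contrast_test <- function(object, ...) {
  structure(list(
    m = object$m, n1 = object$n1, n2 = object$n2,
    config = object$config,
    degenerate_A = sum(object$fits_A$degenerate),
    degenerate_B = sum(object$fits_B$degenerate),
    uncalibrated = sum(!object$calibration$converged),
    n_reject_null = length(object$rejections$rejected_null),
    n_reject_alt = length(object$rejections$rejected_alt),
    findings = object$findings),
    class = "summary.contrast_test")
}

#' @export
print.summary.contrast_test <- function(x, ...) {
  cat("Dual-hypothesis contrast test\n")
  cat(sprintf("  genes: %d   group sizes: n1 = %d, n2 = %d\n", x$m, x$n1, x$n2))
  cat(sprintf("  alpha = %g (%g per family), pi = %g, correction = %s,\n",
              x$config$alpha, x$config$alpha / 2, x$config$pi, x$config$correction))
  cat(sprintf("  calibration: direction = %s, method = %s\n",
              x$config$direction, x$config$method))
  cat(sprintf("  degenerate fits: %d (A), %d (B); uncalibrated genes: %d\n",
              x$degenerate_A, x$degenerate_B, x$uncalibrated))
  cat(sprintf("  rejections: %d zero-intercept, %d alternative\n",
              x$n_reject_null, x$n_reject_alt))
  print(x$findings)
  invisible(x)
}

#' Per-group regression coefficients of a contrast test
#'
#' @param object A [contrast_test()] result.
#' @param ... Unused.
#' @return Data frame with per-gene slopes and intercepts for both groups.
#' @export
coef.contrast_test <- function(object, ...) {
  data.frame(gene = object$gene_names,
             slope_A = object$fits_A$slope, intercept_A = object$fits_A$intercept,
             slope_B = object$fits_B$slope, intercept_B = object$fits_B$intercept,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sorted p-value distributions of the two families
#'
#' Plots the sorted p-values of the zero-intercept family (left) and the
#' calibrated-alternative family (right), the standard diagnostic for this
#' pipeline: the null family should hug the uniform diagonal under no
#' signal, while the alternative family typically shows step-like behavior
#' with p-values piled near 0 and/or 1.
#'
#' @param x A [contrast_test()] result.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.contrast_test <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(sort(x$table$p_null), ylim = c(0, 1), pch = 20, cex = 0.4,
                 xlab = "sorted index", ylab = "p-value",
                 main = "Zero-intercept family", ...)
  graphics::abline(0, 1 / max(1, x$m), col = "grey60", lty = 2)
  graphics::plot(sort(x$table$p_alt), ylim = c(0, 1), pch = 20, cex = 0.4,
                 xlab = "sorted index", ylab = "p-value",
                 main = "Alternative family", ...)
  invisible(x)
}

#' Full per-gene results table of a contrast test
#'
#' @param x A [contrast_test()] result.
#' @return Data frame with columns `gene`, `p_null`, `p_alt`, `lambda`,
#'   `reject_null`, `reject_alt`, `reported`.
#' @export
results_table <- function(x) {
  stopifnot(inherits(x, "contrast_test"))
  out <- as.data.frame(x$table)
  out$reject_null <- seq_len(nrow(out)) %in% x$rejections$rejected_null
  out$reject_alt <- seq_len(nrow(out)) %in% x$rejections$rejected_alt
  out$reported <- out$reject_null & out$reject_alt
  out
}
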
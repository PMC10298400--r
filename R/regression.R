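#' Per-gene ordinary least squares of a contrast on age
#'
#' Fits the simple linear model `contrast = slope * age + intercept + error`
#' for one gene by ordinary least squares, using centered sums of squares
#' (numerically stable at this problem size, no normal-equation inversion).
#' The intercept and its standard error are what the downstream hypothesis
#' tests consume.
#'
#' Degenerate inputs are flagged rather than treated as errors: a constant
#' age vector (slope unidentifiable) or a zero total sum of squares (flat
#' response) sets `degenerate = TRUE`, with `slope = 0`,
#' `intercept = mean(y)` and `r_squared = 0`. Degenerate fits propagate
#' p-values of 1 downstream, so one flat gene does not abort a whole panel.
#'
#' @param y Numeric response vector (contrasts), length n >= 3, finite.
#' @param a Numeric age vector, same length, finite.
#' @return An object of class `gene_fit`: a list with elements `slope`,
#'   `intercept`, `intercept_se` (s * sqrt(1/n + abar^2/Saa)), `t_intercept`,
#'   `r_squared`, `rss`, `tss`, `n`, `df` (= n - 2) and `degenerate`.
#' @examples
#' fit_gene_regression(c(1, 0.5, 2.5, 2), c(0, 1, 2, 3))
#' @export
fit_gene_regression <- function(y, a) {
  n <- length(y)
  if (length(a) != n) stop("'y' and 'a' must have equal length")
  if (n < 3) stop("need at least 3 observations (got ", n,
                  "); the fit would leave no residual degree of freedom")
  if (!all(is.finite(y)) || !all(is.finite(a))) stop("non-finite input")
  abar <- mean(a)
  ybar <- mean(y)
  Saa <- sum((a - abar)^2)
  tss <- sum((y - ybar)^2)
  if (Saa == 0 || tss == 0) {
    # constant ages or flat response: intercept falls back to the mean
    rss <- if (Saa == 0) tss else 0
    fit <- list(slope = 0, intercept = ybar, intercept_se = NA_real_,
                t_intercept = NA_real_, r_squared = 0, rss = rss, tss = tss,
                n = n, df = n - 2L, degenerate = TRUE)
    class(fit) <- "gene_fit"
    return(fit)
  }
  Say <- sum((a - abar) * (y - ybar))
  slope <- Say / Saa
  intercept <- ybar - slope * abar
  rss <- max(tss - slope * Say, 0)
  r2 <- 1 - rss / tss
  s2 <- rss / (n - 2)
  se <- sqrt(s2 * (1 / n + abar^2 / Saa))
  t <- if (se > 0) intercept / se else sign(intercept) * Inf
  if (se == 0 && intercept == 0) t <- 0
  fit <- list(slope = slope, intercept = intercept, intercept_se = se,
              t_intercept = t, r_squared = r2, rss = rss, tss = tss,
              n = n, df = n - 2L, degenerate = FALSE)
  class(fit) <- "gene_fit"
  fit
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("Gene fit (n = %d, df = %d%s)\n", x$n, x$df,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  slope      %.6g\n", x$slope))
  cat(sprintf("  intercept  %.6g (se %.6g, t %.6g)\n",
              x$intercept, x$intercept_se, x$t_intercept))
  cat(sprintf("  R-squared  %.6g (rss %.6g, tss %.6g)\n", x$r_squared, x$rss, x$tss))
  invisible(x)
}

#' Fit the age regression to every gene of a contrast matrix
#'
#' Vectorized over genes: element j equals
#' `fit_gene_regression(values[, j], ages)`, in `gene_names` order.
#'
#' @param contrasts A [contrast_matrix()].
#' @return A data frame with one row per gene and columns `gene`, `slope`,
#'   `intercept`, `intercept_se`, `t_intercept`, `r_squared`, `rss`, `tss`,
#'   `n`, `df`, `degenerate`.
#' @export
fit_all_genes <- function(contrasts) {
  stopifnot(inherits(contrasts, "contrast_matrix"))
  Y <- contrasts$values
  a <- contrasts$ages
  n <- nrow(Y)
  m <- ncol(Y)
  if (n < 3) stop("group ", contrasts$group, " has fewer than 3 samples")
  if (m == 0) return(.fit_table(character(0), numeric(0), numeric(0), numeric(0),
                                numeric(0), numeric(0), numeric(0), numeric(0),
                                n, logical(0)))
  abar <- mean(a)
  ac <- a - abar
  Saa <- sum(ac^2)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  tss <- colSums(Yc^2)
  if (Saa == 0) {
    return(.fit_table(contrasts$gene_names, rep(0, m), ybar, rep(NA_real_, m),
                      rep(NA_real_, m), rep(0, m), tss, tss, n, rep(TRUE, m)))
  }
  Say <- drop(crossprod(ac, Yc))
  slope <- Say / Saa
  intercept <- ybar - slope * abar
  rss <- pmax(tss - slope * Say, 0)
  degen <- tss == 0
  slope[degen] <- 0
  intercept[degen] <- ybar[degen]
  rss[degen] <- 0
  r2 <- ifelse(degen, 0, 1 - rss / tss)
  se <- sqrt(rss / (n - 2) * (1 / n + abar^2 / Saa))
  t <- ifelse(se > 0, intercept / se,
              ifelse(intercept == 0, 0, sign(intercept) * Inf))
  se[degen] <- NA_real_
  t[degen] <- NA_real_
  .fit_table(contrasts$gene_names, slope, intercept, se, t, r2, rss, tss, n, degen)
}

.fit_table <- function(gene, slope, intercept, se, t, r2, rss, tss, n, degen) {
  n <- rep_len(as.integer(n), length(gene))
  data.frame(gene = gene, slope = slope, intercept = intercept,
             intercept_se = se, t_intercept = t, r_squared = r2,
             rss = rss, tss = tss, n = n, df = n - 2L, degenerate = degen,
             stringsAsFactors = FALSE, row.names = NULL)
}

# coerce a gene_fit or a one-row slice of a fit table to a plain list
.as_fit <- function(fit) {
  if (inherits(fit, "gene_fit")) return(unclass(fit))
  if (is.data.frame(fit) && nrow(fit) == 1) return(as.list(fit))
  if (is.list(fit) && all(c("intercept", "rss", "tss", "n") %in% names(fit)))
    return(fit)
  stop("'fit' must be a gene_fit or a one-row fit table")
}

#' Export a per-gene fit table to delimited text
#'
#' @param fits Data frame as returned by [fit_all_genes()].
#' @param path Output path (`.csv` comma, otherwise tab).
#' @return The path, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  out <- fits
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = .sniff_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
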
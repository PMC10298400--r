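# substream seeds derived from one root seed so that, e.g., enlarging the
# gene panel never perturbs the age draws
.substreams <- function(seed, k) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single integer")
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

#' Generate a synthetic two-timepoint contrast study with known truth
#'
#' Emulates the study layout the pipeline targets: two groups of children
#' with ages drawn uniformly from an open interval, and per-gene contrasts
#' following the working model
#' `contrast = intercept_g + slope_g * age + Normal(0, noise_sd^2)` with
#' group-specific gene parameters. Genes listed in `signal_genes` receive a
#' nonzero group-A intercept (the planted departure from baseline); all
#' other group-A intercepts are exactly 0. Both timepoint matrices are also
#' emitted (`expr_t1` is an arbitrary Normal baseline, `expr_t2 = expr_t1 +
#' contrast`), so the full file-based pipeline including
#' [build_contrasts()] can be exercised end to end.
#'
#' Defaults mirror the motivating pediatric MODS cohort: group sizes 22 and
#' 23, a 469-gene panel, ages in (0, 16) years.
#'
#' @param n1,n2 Group sizes (>= 3). Defaults 22 and 23.
#' @param m Gene count. Default 469.
#' @param age_range Open interval for the uniform age draws, years.
#'   Default `c(0, 16)`.
#' @param noise_sd Standard deviation of the contrast noise. Default 1.
#' @param signal_genes Integer indices of genes with a nonzero group-A
#'   intercept. Default none (global null for the zero-intercept family).
#' @param slope_sd Standard deviation of the Normal(0, slope_sd) per-gene,
#'   per-group age slopes. Default 0.5.
#' @param signal_intercept_mean,signal_intercept_sd Normal parameters of
#'   the planted group-A intercepts. Defaults 2 and 0.5.
#' @param intercept_B_sd Standard deviation of the Normal(0, .) group-B
#'   intercepts. Default 0 (point mass at zero).
#' @param baseline_mean,baseline_sd Normal parameters of the synthetic
#'   timepoint-1 expression filler. Defaults 5 and 1.
#' @param seed Root seed; identical seeds give bit-identical studies.
#' @return An object of class `simulated_study`: list with `design`
#'   ([study_design()]), `expr_t1`, `expr_t2` ([expression_matrix()] over
#'   all n1 + n2 samples), `metadata` (data frame), `truth` (per-gene true
#'   slopes/intercepts per group) and `config`.
#' @examples
#' sim <- simulate_study(n1 = 6, n2 = 6, m = 4, signal_genes = 1, seed = 42)
#' sim$truth
#' @export
simulate_study <- function(n1 = 22, n2 = 23, m = 469, age_range = c(0, 16),
                           noise_sd = 1, signal_genes = integer(0),
                           slope_sd = 0.5, signal_intercept_mean = 2,
                           signal_intercept_sd = 0.5, intercept_B_sd = 0,
                           baseline_mean = 5, baseline_sd = 1, seed = 1) {
  if (n1 < 3 || n2 < 3) stop("group sizes must be at least 3")
  if (m < 1) stop("'m' must be at least 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (length(age_range) != 2 || age_range[1] < 0 || diff(age_range) <= 0)
    stop("'age_range' must be an increasing interval within (0, Inf)")
  signal_genes <- as.integer(signal_genes)
  if (length(signal_genes) && (min(signal_genes) < 1 || max(signal_genes) > m))
    stop("'signal_genes' must be indices in 1..m")

  ss <- .substreams(seed, 5)
  n <- n1 + n2
  gene_names <- sprintf("gene_%0*d", nchar(m), seq_len(m))
  sample_ids <- c(sprintf("A%0*d", nchar(n1), seq_len(n1)),
                  sprintf("B%0*d", nchar(n2), seq_len(n2)))

  set.seed(ss[1])
  ages <- stats::runif(n, age_range[1], age_range[2])

  set.seed(ss[2])
  slope_A <- stats::rnorm(m, 0, slope_sd)
  slope_B <- stats::rnorm(m, 0, slope_sd)
  intercept_A <- numeric(m)
  if (length(signal_genes))
    intercept_A[signal_genes] <- stats::rnorm(length(signal_genes),
                                              signal_intercept_mean,
                                              signal_intercept_sd)
  intercept_B <- if (intercept_B_sd > 0) stats::rnorm(m, 0, intercept_B_sd)
                 else numeric(m)

  set.seed(ss[3])
  noise_A <- matrix(stats::rnorm(n1 * m, 0, noise_sd), n1, m)
  set.seed(ss[4])
  noise_B <- matrix(stats::rnorm(n2 * m, 0, noise_sd), n2, m)

  ages_A <- ages[seq_len(n1)]
  ages_B <- ages[n1 + seq_len(n2)]
  YA <- outer(ages_A, slope_A) + matrix(intercept_A, n1, m, byrow = TRUE) + noise_A
  YB <- outer(ages_B, slope_B) + matrix(intercept_B, n2, m, byrow = TRUE) + noise_B
  dimnames(YA) <- list(sample_ids[seq_len(n1)], gene_names)
  dimnames(YB) <- list(sample_ids[n1 + seq_len(n2)], gene_names)

  set.seed(ss[5])
  S <- matrix(stats::rnorm(n * m, baseline_mean, baseline_sd), n, m,
              dimnames = list(sample_ids, gene_names))
  R <- S + rbind(YA, YB)

  metadata <- data.frame(sample_id = sample_ids,
                         group = factor(rep(c("A", "B"), c(n1, n2)),
                                        levels = c("A", "B")),
                         age = ages, stringsAsFactors = FALSE)
  design <- study_design(contrast_matrix(YA, "A", ages_A),
                         contrast_matrix(YB, "B", ages_B))
  structure(list(
    design = design,
    expr_t1 = expression_matrix(S, timepoint_label = "t1"),
    expr_t2 = expression_matrix(R, timepoint_label = "t2"),
    metadata = metadata,
    truth = data.frame(gene = gene_names, slope_A = slope_A,
                       intercept_A = intercept_A, slope_B = slope_B,
                       intercept_B = intercept_B, signal = seq_len(m) %in% signal_genes,
                       stringsAsFactors = FALSE),
    config = list(n1 = n1, n2 = n2, m = m, age_range = age_range,
                  noise_sd = noise_sd, signal_genes = signal_genes,
                  slope_sd = slope_sd,
                  signal_intercept_mean = signal_intercept_mean,
                  signal_intercept_sd = signal_intercept_sd,
                  intercept_B_sd = intercept_B_sd, seed = seed)),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Synthetic contrast study:", x$config$n1, "+", x$config$n2,
      "samples,", x$config$m, "genes,",
      length(x$config$signal_genes), "signal gene(s), seed", x$config$seed, "\n")
  invisible(x)
}

#' Pooled-bootstrap resampling of a contrast study
#'
#' Reproduces the null-like showcase resampling scheme: for each group
#' separately, all n_i x m contrast values are flattened into one pool and
#' n_i x m new values are drawn from it i.i.d. with replacement —
#' deliberately destroying per-gene structure — while the original group
#' sizes and gene count are kept. New ages are drawn with replacement from
#' the pooled original ages of both groups.
#'
#' @param design A [study_design()].
#' @param seed Root seed; identical seeds give bit-identical designs.
#' @return A new [study_design()] of the same dimensions.
#' @export
bootstrap_study <- function(design, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  ss <- .substreams(seed, 3)
  age_pool <- c(design$contrast_A$ages, design$contrast_B$ages)
  n1 <- nrow(design$contrast_A$values)
  n2 <- nrow(design$contrast_B$values)
  m <- design$m

  set.seed(ss[1])
  ages_A <- sample(age_pool, n1, replace = TRUE)
  ages_B <- sample(age_pool, n2, replace = TRUE)

  set.seed(ss[2])
  pool_A <- as.vector(design$contrast_A$values)
  YA <- matrix(sample(pool_A, n1 * m, replace = TRUE), n1, m,
               dimnames = dimnames(design$contrast_A$values))
  set.seed(ss[3])
  pool_B <- as.vector(design$contrast_B$values)
  YB <- matrix(sample(pool_B, n2 * m, replace = TRUE), n2, m,
               dimnames = dimnames(design$contrast_B$values))

  study_design(contrast_matrix(YA, "A", ages_A),
               contrast_matrix(YB, "B", ages_B))
}

#' Type-I error and power of the pipeline by simulation
#'
#' Runs the full pipeline on `reps` independently generated synthetic
#' studies and summarizes, per replicate and overall: the raw per-gene
#' rejection rate of the zero-intercept test at level `alpha` among
#' non-signal genes (type-I error), the same rate among signal genes
#' (power), and the rate at which non-signal genes enter the findings
#' (false reporting rate).
#'
#' @param reps Number of replicates (>= 1).
#' @param alpha Raw per-gene level for the type-I/power counts, and the
#'   overall budget handed to [contrast_test()]. Default 0.05.
#' @param correction Passed to [contrast_test()].
#' @param seed Root seed; replicate seeds are derived from it.
#' @param ... Generator settings passed to [simulate_study()] (`n1`, `n2`,
#'   `m`, `signal_genes`, `noise_sd`, ...).
#' @return An object of class `pipeline_validation`: list with `per_rep`
#'   (data frame of per-replicate rates), `type1`, `power`,
#'   `false_report_rate` (overall means; `power` is `NA` without signal
#'   genes) and `settings`.
#' @export
estimate_error_rates <- function(reps, alpha = 0.05,
                                 correction = c("bh", "bonferroni"),
                                 seed = 1, ...) {
  correction <- match.arg(correction)
  if (reps < 1) stop("'reps' must be at least 1")
  rep_seeds <- .substreams(seed, reps)
  args <- list(...)
  rows <- vector("list", reps)
  tot_null <- tot_null_rej <- tot_sig <- tot_sig_rej <- 0
  tot_false_rep <- 0
  for (r in seq_len(reps)) {
    sim <- do.call(simulate_study, c(args, list(seed = rep_seeds[r])))
    ct <- contrast_test(sim$design, alpha = alpha, correction = correction)
    is_sig <- sim$truth$signal
    raw_rej <- ct$table$p_null <= alpha
    reported <- results_table(ct)$reported
    rows[[r]] <- data.frame(
      rep = r,
      type1 = if (any(!is_sig)) mean(raw_rej[!is_sig]) else NA_real_,
      power = if (any(is_sig)) mean(raw_rej[is_sig]) else NA_real_,
      false_report_rate = if (any(!is_sig)) mean(reported[!is_sig]) else NA_real_)
    tot_null <- tot_null + sum(!is_sig)
    tot_null_rej <- tot_null_rej + sum(raw_rej[!is_sig])
    tot_sig <- tot_sig + sum(is_sig)
    tot_sig_rej <- tot_sig_rej + sum(raw_rej[is_sig])
    tot_false_rep <- tot_false_rep + sum(reported[!is_sig])
  }
  structure(list(
    per_rep = do.call(rbind, rows),
    type1 = if (tot_null) tot_null_rej / tot_null else NA_real_,
    power = if (tot_sig) tot_sig_rej / tot_sig else NA_real_,
    false_report_rate = if (tot_null) tot_false_rep / tot_null else NA_real_,
    settings = c(args, list(reps = reps, alpha = alpha,
                            correction = correction, seed = seed))),
    class = "pipeline_validation")
}

#' @export
print.pipeline_validation <- function(x, ...) {
  cat("Pipeline validation over", nrow(x$per_rep), "replicate(s)\n")
  cat(sprintf("  raw type-I error (non-signal genes): %.4f\n", x$type1))
  if (!is.na(x$power))
    cat(sprintf("  raw power (signal genes):            %.4f\n", x$power))
  cat(sprintf("  false reporting rate (findings):     %.5f\n",
              x$false_report_rate))
  invisible(x)
}
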
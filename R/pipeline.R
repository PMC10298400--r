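# serialize a results/findings data frame: numbers at 17 significant digits
# so reruns are byte-identical and round-trips exact
.write_results_tsv <- function(df, path, header_lines = character(0)) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 17, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full contrast-testing pipeline on files
#'
#' End-to-end orchestration: read the two timepoint expression matrices and
#' the sample metadata, build the per-group contrast matrices, fit the
#' per-gene age regressions in both groups, calibrate the group-B
#' alternative levels, compute both p-value families, apply the dual
#' multiple-testing correction at `alpha / 2` per family, and report the
#' genes rejected in both families. Writes `results.tsv` (per-gene table),
#' `findings.tsv` and `manifest.json` (every configuration value needed to
#' rerun the analysis) into `outdir`. An empty findings table is a valid
#' outcome.
#'
#' @param expr_t1,expr_t2 Paths to the timepoint-1 and timepoint-2
#'   expression matrices (TSV/CSV, see [read_expression_matrix()]).
#' @param metadata Path to the sample metadata table.
#' @param outdir Output directory, created if needed.
#' @param alpha,pi,correction,direction,method Passed to [contrast_test()].
#' @param group_labels Mapping of metadata group labels onto A/B, see
#'   [read_sample_metadata()].
#' @param orientation Orientation of the expression files, see
#'   [read_expression_matrix()].
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic); optional.
#' @return The [contrast_test()] object, invisibly.
#' @export
run_pipeline <- function(expr_t1, expr_t2, metadata, outdir,
                         alpha = 0.05, pi = 0.35,
                         correction = c("bh", "bonferroni"),
                         direction = c("below", "above"),
                         method = c("closed_form", "binary_search"),
                         group_labels = c(A = "A", B = "B"),
                         orientation = c("samples-as-rows", "genes-as-rows"),
                         seed = NULL) {
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  method <- match.arg(method)
  orientation <- match.arg(orientation)

  S <- read_expression_matrix(expr_t1, orientation = orientation,
                              timepoint_label = "t1")
  R <- read_expression_matrix(expr_t2, orientation = orientation,
                              timepoint_label = "t2")
  meta <- read_sample_metadata(metadata, group_labels = group_labels)
  design <- build_contrasts(R, S, meta)
  ct <- contrast_test(design, alpha = alpha, pi = pi, correction = correction,
                      direction = direction, method = method)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(sprintf("alpha=%.17g", alpha), sprintf("pi=%.17g", pi),
           paste0("correction=", correction),
           if (!is.null(seed)) paste0("seed=", seed))
  .write_results_tsv(results_table(ct), file.path(outdir, "results.tsv"), hdr)
  .write_results_tsv(ct$findings, file.path(outdir, "findings.tsv"), hdr)
  manifest <- list(
    inputs = list(expr_t1 = expr_t1, expr_t2 = expr_t2, metadata = metadata),
    parameters = list(alpha = alpha, pi = pi, correction = correction,
                      direction = direction, method = method,
                      group_labels = as.list(group_labels),
                      orientation = orientation, seed = seed),
    design = list(n1 = ct$n1, n2 = ct$n2, m = ct$m),
    counts = list(degenerate_A = sum(ct$fits_A$degenerate),
                  degenerate_B = sum(ct$fits_B$degenerate),
                  rejected_null = length(ct$rejections$rejected_null),
                  rejected_alt = length(ct$rejections$rejected_alt),
                  findings = nrow(ct$findings)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(ct)
}
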
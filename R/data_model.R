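#' Construct a validated expression matrix
#'
#' An expression matrix holds already-quantified expression values for one
#' timepoint, with samples as rows and genes as columns. Values must be
#' finite (missing data are not supported anywhere in the pipeline) and
#' sample/gene identifiers must be unique.
#'
#' @param values Numeric matrix, samples as rows, genes as columns.
#' @param sample_ids Character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param gene_names Character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @param timepoint_label Free-text label for the timepoint ("t1", "t2", ...).
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   `dimnames` set and a `timepoint_label` attribute.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
#' expression_matrix(m, timepoint_label = "t1")
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_names = colnames(values),
                              timepoint_label = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(sample_ids) || is.null(gene_names))
    stop("sample and gene identifiers are required")
  sample_ids <- as.character(sample_ids)
  gene_names <- as.character(gene_names)
  if (length(sample_ids) != nrow(values))
    stop("number of sample_ids (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(gene_names) != ncol(values))
    stop("number of gene_names (", length(gene_names),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_names))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at sample '", sample_ids[bad[1]], "', gene '",
         gene_names[bad[2]], "' (missing data are not supported)")
  }
  dimnames(values) <- list(sample_ids, gene_names)
  structure(values, timepoint_label = timepoint_label,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix", if (nzchar(attr(x, "timepoint_label")))
    paste0("[", attr(x, "timepoint_label"), "]") else "", ":",
    nrow(x), "samples x", ncol(x), "genes\n")
  invisible(x)
}

# delimiter from file extension: .csv -> comma, anything else -> tab
.sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects one header row and one identifier column (the first). TSV or CSV
#' is chosen by file extension (`.csv` means comma, anything else tab). The
#' returned matrix is always samples-as-rows, regardless of the file's
#' orientation.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples-as-rows"` (default: header lists genes,
#'   first column lists sample ids) or `"genes-as-rows"` (the transpose).
#' @param timepoint_label Passed through to [expression_matrix()].
#' @return An [expression_matrix()] in samples-as-rows orientation.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples-as-rows", "genes-as-rows"),
                                   timepoint_label = "") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = .sniff_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 2) stop("expected an id column plus at least one data column in ", path)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num))[1]
      stop("non-numeric value '", col[bad], "' at row '", ids[bad],
           "', column '", names(body)[j], "' in ", path)
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      stop("missing value at row '", ids[bad], "', column '", names(body)[j],
           "' in ", path, " (missing data are not supported)")
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (orientation == "genes-as-rows") mat <- t(mat)
  expression_matrix(mat, timepoint_label = timepoint_label)
}

# shared writer: one id column named by id_col, 17 significant digits so
# write/read round-trips are exact for doubles
.write_delim_matrix <- function(values, path, id_col = "id") {
  sep <- .sniff_sep(path)
  df <- data.frame(rownames(values),
                   apply(values, 2, function(v) format(v, digits = 17, trim = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(values))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()] (samples-as-rows dialect). Values
#' are serialized with 17 significant digits, so a write/read round trip
#' reproduces them bit-identically.
#'
#' @param x An [expression_matrix()] (or plain numeric matrix with dimnames).
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  .write_delim_matrix(unclass(x), path, id_col = "sample_id")
}

#' Read a sample metadata table
#'
#' The table must contain columns `sample_id`, `group` and `age`. Group
#' labels are mapped onto the canonical labels "A" and "B" via `group_labels`,
#' so study-specific labels (e.g. "Prolonged MODS" / "MODS Recovery") can be
#' used in the file. Ages must be finite and strictly positive (years).
#'
#' @param path Path to a TSV/CSV file with columns sample_id, group, age.
#' @param group_labels Named character vector `c(A = ..., B = ...)` giving
#'   the file's labels for the two groups.
#' @return A data frame with columns `sample_id` (character), `group`
#'   (factor with levels A, B) and `age` (numeric), validated.
#' @export
read_sample_metadata <- function(path, group_labels = c(A = "A", B = "B")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = .sniff_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df, group_labels = group_labels)
}

#' Validate a sample metadata data frame
#'
#' @param df Data frame with columns `sample_id`, `group`, `age`.
#' @inheritParams read_sample_metadata
#' @return The validated data frame with `group` recoded to factor A/B.
#' @export
sample_metadata <- function(df, group_labels = c(A = "A", B = "B")) {
  need <- c("sample_id", "group", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("A", "B") %in% names(group_labels)))
    stop("'group_labels' must name both 'A' and 'B'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  grp <- as.character(df$group)
  unknown <- setdiff(unique(grp), unname(group_labels[c("A", "B")]))
  if (length(unknown))
    stop("unknown group label(s) in metadata: ", paste(unknown, collapse = ", "))
  df$group <- factor(ifelse(grp == group_labels[["A"]], "A", "B"), levels = c("A", "B"))
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || !all(is.finite(df$age)))
    stop("non-numeric or missing age in metadata")
  if (any(df$age <= 0)) {
    bad <- df$sample_id[df$age <= 0][1]
    stop("age must be strictly positive (years); offending sample: ", bad)
  }
  df[, need]
}

#' Construct a per-group contrast matrix
#'
#' Holds the timepoint-2 minus timepoint-1 expression differences for the
#' samples of one group, together with their ages.
#'
#' @param values Numeric matrix (group samples x genes) of contrasts, with
#'   dimnames.
#' @param group `"A"` or `"B"`.
#' @param ages Numeric vector of ages, aligned index-wise with the rows.
#' @return An object of class `contrast_matrix`: a list with elements
#'   `values`, `group`, `sample_ids`, `gene_names`, `ages`.
#' @export
contrast_matrix <- function(values, group, ages) {
  group <- match.arg(group, c("A", "B"))
  if (!is.matrix(values) || !is.numeric(values) || !all(is.finite(values)))
    stop("contrast values must be a finite numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("contrast matrix needs sample and gene identifiers as dimnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (length(ages) != nrow(values))
    stop("length of 'ages' (", length(ages), ") does not match sample count (",
         nrow(values), ")")
  if (!all(is.finite(ages)) || any(ages <= 0))
    stop("ages must be finite and strictly positive")
  structure(list(values = values, group = group,
                 sample_ids = rownames(values), gene_names = colnames(values),
                 ages = as.numeric(ages)),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat("Contrast matrix, group", x$group, ":", nrow(x$values), "samples x",
      ncol(x$values), "genes\n")
  invisible(x)
}

#' Write a contrast matrix to delimited text
#'
#' Same dialect as [write_expression_matrix()], for inspection of the
#' intermediate contrasts.
#' @param x A [contrast_matrix()].
#' @param path Output path (`.csv` comma, otherwise tab).
#' @return The path, invisibly.
#' @export
write_contrast_matrix <- function(x, path) {
  .write_delim_matrix(x$values, path, id_col = "sample_id")
}

#' Construct a two-group study design
#'
#' @param contrast_A,contrast_B [contrast_matrix()] objects for groups A and
#'   B. They must cover the same genes in the same order.
#' @return An object of class `study_design`: list with `contrast_A`,
#'   `contrast_B`, `m` (shared gene count) and `gene_names`.
#' @export
study_design <- function(contrast_A, contrast_B) {
  stopifnot(inherits(contrast_A, "contrast_matrix"),
            inherits(contrast_B, "contrast_matrix"))
  if (contrast_A$group != "A" || contrast_B$group != "B")
    stop("contrast_A must be group A and contrast_B group B")
  if (!identical(contrast_A$gene_names, contrast_B$gene_names))
    stop("the two groups must share identical gene names in identical order")
  structure(list(contrast_A = contrast_A, contrast_B = contrast_B,
                 m = length(contrast_A$gene_names),
                 gene_names = contrast_A$gene_names),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Two-group contrast study design\n",
      " group A:", nrow(x$contrast_A$values), "samples\n",
      " group B:", nrow(x$contrast_B$values), "samples\n",
      " genes:  ", x$m, "\n")
  invisible(x)
}

#' Build per-group contrast matrices from two timepoint matrices
#'
#' Computes the componentwise difference Y = R - S between the expression
#' matrices at the second and first timepoints, aligning samples and genes
#' by identifier (never by position), and partitions the samples into the
#' two groups given by the metadata. Ordinary least squares with an
#' intercept needs at least one residual degree of freedom, so each group
#' must contain at least 3 samples.
#'
#' @param R [expression_matrix()] at the later timepoint.
#' @param S [expression_matrix()] at the earlier timepoint; must hold the
#'   same samples and genes as `R` (any order).
#' @param meta Sample metadata (data frame as from [read_sample_metadata()],
#'   or convertible via [sample_metadata()]).
#' @return A [study_design()].
#' @examples
#' sim <- simulate_study(n1 = 4, n2 = 4, m = 3, seed = 1)
#' d <- build_contrasts(sim$expr_t2, sim$expr_t1, sim$metadata)
#' d
#' @export
build_contrasts <- function(R, S, meta) {
  if (!inherits(meta, "data.frame")) stop("'meta' must be a data frame")
  if (!is.factor(meta$group) || !identical(levels(meta$group), c("A", "B")))
    meta <- sample_metadata(meta)
  if (!setequal(rownames(R), rownames(S)))
    stop("timepoint matrices do not hold the same samples")
  if (!setequal(colnames(R), colnames(S)))
    stop("timepoint matrices do not hold the same genes")
  # align S onto R's ordering by identifier
  S_al <- unclass(S)[rownames(R), colnames(R), drop = FALSE]
  not_in_meta <- setdiff(rownames(R), meta$sample_id)
  if (length(not_in_meta))
    stop("sample(s) in expression matrices but absent from metadata: ",
         paste(not_in_meta, collapse = ", "))
  Y <- unclass(R) - S_al
  attr(Y, "timepoint_label") <- NULL
  meta <- meta[match(rownames(Y), meta$sample_id), ]
  pieces <- lapply(c("A", "B"), function(g) {
    keep <- meta$group == g
    if (sum(keep) < 3)
      stop("group ", g, " has ", sum(keep),
           " sample(s); at least 3 are required for a regression with intercept")
    contrast_matrix(Y[keep, , drop = FALSE], group = g, ages = meta$age[keep])
  })
  study_design(pieces[[1]], pieces[[2]])
}
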
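test_that("expression matrix construction enforces its invariants", {
  m <- matrix(1:6 / 2, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
  em <- expression_matrix(m, timepoint_label = "t1")
  expect_s3_class(em, "expression_matrix")
  expect_identical(dim(em), c(3L, 2L))

  bad <- m; bad[2, 1] <- NA
  expect_error(expression_matrix(bad), "non-finite")
  dup <- m; rownames(dup) <- c("s1", "s1", "s3")
  expect_error(expression_matrix(dup), "duplicate sample")
  dupg <- m; colnames(dupg) <- c("g1", "g1")
  expect_error(expression_matrix(dupg), "duplicate gene")
})

test_that("delimited readers parse both orientations and reject bad cells", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "expr.tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\t4", "s2\t2\t5", "s3\t3\t6"), f1)
  em <- read_expression_matrix(f1)
  expect_identical(rownames(em), c("s1", "s2", "s3"))
  expect_identical(colnames(em), c("g1", "g2"))
  expect_equal(unclass(em)[, "g2"], c(s1 = 4, s2 = 5, s3 = 6))

  # same content transposed reads identically under genes-as-rows
  f2 <- file.path(d, "expr_t.tsv")
  writeLines(c("gene\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t4\t5\t6"), f2)
  emt <- read_expression_matrix(f2, orientation = "genes-as-rows")
  expect_equal(unclass(emt), unclass(em), ignore_attr = TRUE)
  expect_identical(dimnames(emt), dimnames(em))

  f3 <- file.path(d, "bad.tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\tNA", "s2\t2\t5", "s3\t3\t6"), f3)
  expect_error(read_expression_matrix(f3), "missing|non-numeric")
  f4 <- file.path(d, "bad2.tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\toops", "s2\t2\t5"), f4)
  expect_error(read_expression_matrix(f4), "non-numeric.*oops|oops")
})

test_that("write/read round trip reproduces values bit-identically", {
  d <- withr::local_tempdir()
  set.seed(4)
  m <- matrix(rnorm(12) * 10^sample(-5:5, 12, TRUE), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  em <- expression_matrix(m)
  for (ext in c("tsv", "csv")) {
    f <- file.path(d, paste0("rt.", ext))
    write_expression_matrix(em, f)
    back <- read_expression_matrix(f)
    expect_identical(unclass(back)[, ], unclass(em)[, ])
  }
})

test_that("metadata validation maps group labels and rejects bad ages", {
  df <- data.frame(sample_id = c("s1", "s2"), group = c("rec", "pro"),
                   age = c(4.5, 12))
  md <- sample_metadata(df, group_labels = c(A = "pro", B = "rec"))
  expect_identical(as.character(md$group), c("B", "A"))
  expect_error(sample_metadata(data.frame(sample_id = "s1", group = "A", age = 0)),
               "strictly positive")
  expect_error(sample_metadata(data.frame(sample_id = c("s1", "s1"),
                                          group = c("A", "B"), age = c(1, 2))),
               "duplicate")
  expect_error(sample_metadata(data.frame(sample_id = "s1", group = "C", age = 1)),
               "unknown group")
})

test_that("build_contrasts aligns by identifier, never by position", {
  set.seed(21)
  n <- 10; m <- 5
  ids <- paste0("s", 1:n); genes <- paste0("g", 1:m)
  R <- expression_matrix(matrix(rnorm(n * m), n, m, dimnames = list(ids, genes)))
  Sm <- matrix(rnorm(n * m), n, m, dimnames = list(ids, genes))
  # shuffle both rows and columns of S; alignment must undo it
  Sshuf <- expression_matrix(Sm[sample(n), sample(m)])
  meta <- data.frame(sample_id = ids,
                     group = rep(c("A", "B"), each = n / 2),
                     age = runif(n, 1, 15))
  d <- build_contrasts(R, Sshuf, meta)
  # oracle: explicit alignment, componentwise difference taken directly
  expected <- unclass(R)[, ] - Sm[rownames(R), colnames(R)]
  got <- rbind(d$contrast_A$values, d$contrast_B$values)[rownames(R), ]
  expect_identical(got, expected)
})

test_that("build_contrasts partitions samples and validates group sizes", {
  set.seed(22)
  n <- 8; m <- 3
  ids <- paste0("s", 1:n); genes <- paste0("g", 1:m)
  mk <- function() expression_matrix(matrix(rnorm(n * m), n, m,
                                            dimnames = list(ids, genes)))
  R <- mk(); S <- mk()
  meta <- data.frame(sample_id = ids, group = rep(c("A", "B"), each = 4),
                     age = runif(n, 1, 15))
  d <- build_contrasts(R, S, meta)
  # every sample in exactly one group
  expect_setequal(c(d$contrast_A$sample_ids, d$contrast_B$sample_ids), ids)
  expect_length(intersect(d$contrast_A$sample_ids, d$contrast_B$sample_ids), 0)
  # identical timepoints give all-zero contrasts
  dz <- build_contrasts(R, R, meta)
  expect_true(all(dz$contrast_A$values == 0) && all(dz$contrast_B$values == 0))
  # group with < 3 samples rejected
  meta_bad <- meta; meta_bad$group <- c(rep("A", 6), rep("B", 2))
  expect_error(build_contrasts(R, S, meta_bad), "group B.*at least 3")
  # sample missing from metadata rejected
  expect_error(build_contrasts(R, S, meta[-1, ]), "absent from metadata")
  # ages must follow the sample partition
  expect_identical(d$contrast_A$ages, meta$age[match(d$contrast_A$sample_ids,
                                                     meta$sample_id)])
})
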
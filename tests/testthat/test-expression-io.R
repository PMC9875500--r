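test_that("dense TSV round-trips values and identifiers", {
  vals <- matrix(0:5, 2, 3, byrow = TRUE,
                 dimnames = list(c("GA", "GB"), c("c1", "c2", "c3")))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(vals), vals),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  em <- load_expression(f, "dense_tsv")
  expect_s3_class(em, "expression_matrix")
  expect_identical(dim(em), c(2L, 3L))
  expect_equal(unname(em$values), matrix(0:5, 2, 3, byrow = TRUE))
  expect_identical(rownames(em$values), c("GA", "GB"))
  expect_false(em$normalized)
})

test_that("triplet (MatrixMarket) input fills unlisted positions with zero", {
  m <- Matrix::sparseMatrix(i = 1L, j = 2L, x = 4, dims = c(2L, 3L))
  mf <- withr::local_tempfile(fileext = ".mtx")
  gf <- withr::local_tempfile()
  cf <- withr::local_tempfile()
  Matrix::writeMM(m, mf)
  writeLines(c("gene1", "gene2"), gf)
  writeLines(c("cell1", "cell2", "cell3"), cf)
  em <- load_expression(mf, "triplet", genes_path = gf, cells_path = cf)
  expect_equal(em$values[["gene1", "cell2"]], 4)
  expect_equal(sum(em$values), 4)
  expect_error(load_expression(mf, "triplet"), "genes_path")
})

test_that("duplicate and invalid entries are rejected with names/locations", {
  vals <- matrix(1, 2, 2, dimnames = list(c("GA", "GA"), c("c1", "c2")))
  expect_error(expression_matrix(vals), "GA")
  vals2 <- matrix(c(1, -3, 2, 4), 2, 2,
                  dimnames = list(c("GA", "GB"), c("c1", "c2")))
  expect_error(expression_matrix(vals2), "GB.*c1")
  vals3 <- matrix(1, 2, 2, dimnames = list(c("GA", "GB"), c("c1", "c1")))
  expect_error(expression_matrix(vals3), "c1")
})

test_that("log-normalization is ln(1+x), monotone, and invertible", {
  set.seed(41)
  vals <- matrix(runif(9, 0, 10), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  vals[1, 1] <- 0
  vals[1, 2] <- exp(1) - 1
  em <- expression_matrix(vals)
  nm <- normalize_log1p(em)
  expect_true(nm$normalized)
  expect_equal(nm$values[1, 1], 0)
  expect_equal(nm$values[1, 2], 1)
  expect_equal(nm$values, log(1 + vals))      # elementwise scalar oracle
  expect_equal(expm1(nm$values), vals, tolerance = 1e-12)
  ord <- order(vals)
  expect_identical(order(nm$values), ord)     # strict monotonicity
  expect_error(normalize_log1p(nm), "already normalized")
})

test_that("stage assembly enforces the minimum-cells rule and drops unlabelled cells", {
  set.seed(42)
  vals <- matrix(abs(rnorm(60)), 2, 30,
                 dimnames = list(c("GA", "GB"), sprintf("c%02d", 1:30)))
  em <- normalize_log1p(expression_matrix(vals))
  labels <- data.frame(cell_id = colnames(vals),
                       stage_label = rep(c("s1", "s2", "s3"), each = 10))
  ss <- assemble_stage_series(em, labels, c("s1", "s2", "s3"))
  expect_identical(length(ss$stage_order), 3L)
  expect_identical(as.integer(table(ss$stages)), rep(10L, 3))

  # a 6-cell stage violates the n > 6 criterion at the default threshold
  short <- labels[c(1:6, 11:30), ]
  expect_error(assemble_stage_series(em, short, c("s1", "s2", "s3")),
               "'s1' has 6 cells")
  expect_silent(suppressMessages(
    assemble_stage_series(em, short, c("s1", "s2", "s3"), min_cells = 6)))

  # unlabelled cells are dropped with a count, not errored
  partial <- labels[-c(1, 2, 11, 12, 21), ]
  expect_message(ss2 <- assemble_stage_series(em, partial, c("s1", "s2", "s3")),
                 "5 unlabelled")
  expect_identical(ncol(ss2$matrix$values), 25L)

  expect_error(assemble_stage_series(em, transform(labels, stage_label = "sX"),
                                     c("s1", "s2", "s3")), "sX")
})

test_that("stage assembly is invariant to label-table row order", {
  set.seed(43)
  vals <- matrix(abs(rnorm(40)), 2, 20,
                 dimnames = list(c("GA", "GB"), sprintf("c%02d", 1:20)))
  em <- normalize_log1p(expression_matrix(vals))
  labels <- data.frame(cell_id = colnames(vals),
                       stage_label = rep(c("s1", "s2"), each = 10))
  a <- assemble_stage_series(em, labels, c("s1", "s2"))
  b <- assemble_stage_series(em, labels[sample(nrow(labels)), ], c("s1", "s2"))
  expect_identical(a$stages, b$stages)
  expect_identical(a$matrix$values, b$matrix$values)
})
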
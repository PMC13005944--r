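test_that("expression files round-trip and parse missing cells as missing", {
  x <- random_expr(10, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  expect_equal(read_expression(path), x)

  lines <- c("sample_id\tP1\tP2", "A\t1.5\t", "B\t2\t3", "C\t0\t4")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, p2)
  m <- read_expression(p2)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["A", "P2"]))
})

test_that("transposed files read back to the same matrix", {
  x <- random_expr(6, 4, seed = 7)
  p <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(protein_id = colnames(x), t(x), check.names = FALSE)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(p, orientation = "proteins_in_rows"), x)
})

test_that("malformed expression input is rejected", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tP1\tP2", "A\t1\t2", "A\t3\t4"), p)
  expect_error(read_expression(p), "duplicate")
  writeLines(c("sample_id\tP1\tP2", "A\t1\tlow", "B\t3\t4"), p)
  expect_error(read_expression(p), "non-numeric")
})

test_that("clinical tables parse events, drop missing times, reject negatives", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time,event", "A,12.5,1", "B,3,0", "C,,1"), p)
  expect_message(cl <- read_clinical(p, "OS"), "1 row")
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$event, c(1L, 0L))
  expect_equal(attr(cl, "endpoint"), "OS")

  writeLines(c("sample_id,time,event", "A,-3,1"), p)
  expect_error(read_clinical(p, "OS"), "negative")
})

test_that("cohort construction validates ids, labels and clinical coverage", {
  x <- random_expr(5, 3)
  cl <- data.frame(sample_id = rownames(x)[1:4], time = 1:4, event = c(0, 1, 0, 1))
  co <- cohort(x, list(OS = cl), labels = rep(1:2, length.out = 5))
  expect_s3_class(co, "srps_cohort")
  expect_equal(n_samples(co), 5L)
  sv <- cohort_survival(co, "OS")
  expect_equal(sv$time, 1:4)

  expect_error(cohort(x, list(OS = transform(cl, sample_id = paste0("Z", 1:4)))),
               "absent")
  expect_error(cohort(x, labels = c(1, 2)), "one entry per sample")
  sub <- cohort_subset(co, c("S03", "S01"))
  expect_equal(rownames(sub$expr), c("S03", "S01"))
  expect_equal(unname(sub$labels), c(1L, 1L))
})

test_that("quantile normalization gives every sample the same sorted profile", {
  x <- random_expr(8, 30, na_frac = 0.1, seed = 3)
  qn <- quantile_normalize(x)
  sorted <- apply(qn, 1, function(r) sort(r[!is.na(r)]))
  # complete rows must agree exactly; rows with missing values share the grid
  complete <- which(rowSums(is.na(qn)) == 0)
  for (i in complete[-1])
    expect_equal(sorted[[i]], sorted[[complete[1]]], tolerance = 1e-12)
  expect_equal(is.na(qn), is.na(x))
})

test_that("preprocess_pair filters, standardizes and aligns the protein space", {
  set.seed(11)
  # protein P01 detected in only 2 of 10 samples -> filtered at the 30% rule
  xs <- random_expr(10, 8, seed = 5)
  xs[3:10, 1] <- NA
  xt <- random_expr(10, 8, seed = 6)
  mk <- function(x) cohort(x)
  pp <- preprocess_pair(mk(xs), mk(xt))
  expect_false("P01" %in% colnames(pp$source$expr))
  expect_identical(colnames(pp$source$expr), colnames(pp$target$expr))
  # population z-score: mean 0, SD 1
  expect_lt(max(abs(colMeans(pp$source$expr))), 1e-9)
  sds <- sqrt(colMeans(sweep(pp$source$expr, 2, colMeans(pp$source$expr))^2))
  expect_lt(max(abs(sds - 1)), 1e-9)
  expect_true(pp$source$preprocessed)
})

test_that("protein-set arithmetic: shared proteins intersected with a signature", {
  xs <- random_expr(12, 80, seed = 1)
  xt <- random_expr(12, 80, seed = 2)
  colnames(xs) <- sprintf("P%03d", 1:80)
  colnames(xt) <- sprintf("P%03d", 31:110)  # shares P031..P080 = 50 proteins
  sig <- sprintf("P%03d", c(60:71, 100:107))  # 20 ids, 12 within shared range
  expect_equal(sum(sig %in% intersect(colnames(xs), colnames(xt))), 12L)
  pp <- preprocess_pair(cohort(xs), cohort(xt), signature = sig)
  expect_equal(ncol(pp$source$expr), 12L)
  expect_error(preprocess_pair(cohort(xs), cohort(xt), signature = "PX"),
               "signature")
})

test_that("re-applying the filter/intersect steps to preprocessed output is a no-op", {
  xs <- random_expr(10, 20, na_frac = 0.15, seed = 8)
  xt <- random_expr(10, 20, na_frac = 0.15, seed = 9)
  pp <- preprocess_pair(cohort(xs), cohort(xt))
  x1 <- pp$source$expr
  detected <- colMeans(!is.na(x1)) >= 0.3
  expect_true(all(detected))
  expect_identical(intersect(colnames(pp$source$expr), colnames(pp$target$expr)),
                   colnames(pp$source$expr))
})

test_that("signature and GMT readers parse plain-text inputs", {
  p <- withr::local_tempfile()
  writeLines(c("P1", "", "P2 ", "P1"), p)
  expect_equal(read_signature(p), c("P1", "P2"))
  g <- withr::local_tempfile(fileext = ".gmt")
  writeLines("setA\tdesc\tP1\tP2\tP3", g)
  gs <- read_gmt(g)
  expect_equal(gs$setA, c("P1", "P2", "P3"))
})

test_that("align_to_source standardizes by source statistics and keeps shifts", {
  set.seed(2)
  xs <- random_expr(30, 5, seed = 2)
  xt <- xs + 3  # constant shift
  rownames(xt) <- sprintf("T%02d", 1:30)
  al <- align_to_source(cohort(xs), cohort(xt))
  expect_lt(max(abs(colMeans(al$source$expr))), 1e-9)
  expect_gt(min(colMeans(al$target$expr)), 1)  # shift survives
  al2 <- align_to_source(cohort(xs), cohort(xt), clip = 0.5)
  expect_lte(max(abs(al2$target$expr)), 0.5)
})
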
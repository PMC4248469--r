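test_that("classification follows the TP/FP/FN definitions", {
  truth <- tibble::tibble(read = 1:100, pos = 10L, true = "A", observed = "G")
  perfect <- tibble::tibble(read = 1:100, pos = 10L, to = "A")
  s <- classify_corrections(perfect, truth)
  expect_equal(c(s$TP, s$FP, s$FN), c(100, 0, 0))
  expect_equal(s$gain, 1)

  # 90 fixed, 10 missed
  s2 <- classify_corrections(perfect[1:90, ], truth)
  expect_equal(c(s2$TP, s2$FP, s2$FN), c(90, 0, 10))
  expect_equal(s2$recall, 0.9)
  expect_equal(s2$precision, 1.0)
  expect_equal(s2$f_score, 2 * 0.9 / 1.9, tolerance = 1e-12)
  expect_equal(s2$gain, 0.9)

  # 90 fixed, 10 missed, 10 spurious
  spurious <- tibble::tibble(read = 1:10, pos = 50L, to = "C")
  s3 <- classify_corrections(dplyr::bind_rows(perfect[1:90, ], spurious), truth)
  expect_equal(c(s3$TP, s3$FP, s3$FN), c(90, 10, 10))
  expect_equal(s3$recall, 0.9)
  expect_equal(s3$precision, 0.9)
  expect_equal(s3$f_score, 0.9)
  expect_equal(s3$gain, 0.8)
})

test_that("a wrong substitution at an error position is FN, not FP", {
  truth <- tibble::tibble(read = 1L, pos = 5L, true = "A", observed = "G")
  wrong <- tibble::tibble(read = 1L, pos = 5L, to = "C")
  s <- classify_corrections(wrong, truth)
  expect_equal(c(s$TP, s$FP, s$FN), c(0, 0, 1))
})

test_that("conservation and gain bounds hold on random evaluations", {
  set.seed(81)
  for (i in 1:20) {
    n_err <- sample(5:50, 1)
    truth <- tibble::tibble(read = sample(1:30, n_err, TRUE),
                            pos = sample(1:90, n_err, TRUE),
                            true = sample(c("A", "C", "G", "T"), n_err, TRUE))
    truth <- dplyr::distinct(truth, read, pos, .keep_all = TRUE)
    n_ed <- sample(0:40, 1)
    edits <- tibble::tibble(read = sample(1:30, n_ed, TRUE),
                            pos = sample(1:90, n_ed, TRUE),
                            to = sample(c("A", "C", "G", "T"), n_ed, TRUE))
    edits <- dplyr::distinct(edits, read, pos, .keep_all = TRUE)
    s <- classify_corrections(edits, truth)
    expect_equal(s$TP + s$FN, nrow(truth))  # conservation
    expect_lte(s$gain, s$recall)
    if (s$FP == 0) expect_equal(s$gain, s$recall)
    if (!is.na(s$f_score)) {
      expect_gte(s$f_score, min(s$recall, s$precision))
      expect_lte(s$f_score, max(s$recall, s$precision))
    }
  }
})

test_that("end-to-end evaluation against a run object checks read ids", {
  g <- sim_genome(20000, seed = 82)
  s <- sim_reads(g, coverage = 20, read_len = 80, mean_error = 0.01, seed = 82)
  run <- run_correction(s$reads, k = 15, genome_size = 20000, coverage = 20,
                        seed = 82)
  ev <- classify_corrections(run, s$truth)
  expect_equal(ev$TP + ev$FN, nrow(s$truth))
  expect_gt(ev$recall, 0.5)
  truth_bad <- s$truth
  truth_bad$id <- rev(truth_bad$id)
  expect_error(classify_corrections(run, truth_bad), "mismatch")
})

test_that("summary tables format percentages to two decimals", {
  expect_equal(nrow(eval_table(list())), 0)
  s <- list(TP = 9985L, FP = 0L, FN = 15L, recall = 0.9985, precision = 1,
            f_score = 0.99924943, gain = 0.9985)
  class(s) <- "eval_summary"
  tab <- eval_table(list(s), labels = "run1")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$recall, 99.85)
  expect_equal(tab$precision, 100)
  path <- tempfile(fileext = ".tsv")
  eval_table_tsv(list(s), labels = "run1", path = path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$gain, 99.85)
})
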
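test_that("PSI point estimation follows the length-normalized ratio", {
  expect_equal(estimatePsi(20, 10, lenInc = 2, lenSkip = 1), 0.5)
  expect_equal(estimatePsi(0, 7, 2, 1), 0)
  expect_equal(estimatePsi(5, 0, 2, 1), 1)
  expect_true(is.na(estimatePsi(0, 0, 2, 1)))
  expect_error(estimatePsi(1, 1, lenInc = 0), "length")

  # equal lengths reduce to the raw read ratio
  ic <- 0:20; sc <- 20:0
  expect_equal(estimatePsi(ic, sc, 3, 3), ic / (ic + sc))

  # strictly increasing in ic at fixed sc; swap symmetry psi -> 1 - psi
  psi <- estimatePsi(0:30, 7, 2, 1)
  expect_true(all(diff(psi) > 0))
  expect_equal(estimatePsi(11, 4, 2, 1), 1 - estimatePsi(4, 11, 1, 2))
})

test_that("survival table reader validates and maps columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\ttime\tevent", "a\t10\t1", "b\t5\t0",
               "c\t7\t1"), path)
  tab <- readSurvivalTable(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$event), 2)
  expect_equal(tab$patient_id, c("a", "b", "c"))

  # dialect remapping of the event column
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\ttime\tstatus", "a\t10\t1", "b\t5\t0"), path2)
  expect_error(readSurvivalTable(path2), "event")
  tab2 <- readSurvivalTable(path2, dialect = c(event = "status"))
  expect_equal(tab2$event, c(1, 0))

  # row-addressable invariant violations
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\ttime\tevent", "a\t0\t1", "b\t5\t0"), path3)
  expect_error(readSurvivalTable(path3), "row.*1")
})

test_that("counts table reader parses paired IC/SC columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tl_inc\tl_skip\tp1_IC\tp1_SC\tp2_IC\tp2_SC",
               "ex1\t2\t1\t4\t1\t0\t3"), path)
  cnt <- readCountsTable(path)
  expect_equal(colnames(cnt$inclusion), c("p1", "p2"))
  expect_equal(unname(cnt$inclusion["ex1", ] + cnt$skipping["ex1", ]),
               c(5L, 3L))

  # empty exon set is fine
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("exon_id\tl_inc\tl_skip\tp1_IC\tp1_SC", path2)
  expect_equal(nrow(readCountsTable(path2)$inclusion), 0L)

  # non-integer count names the exon and patient
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tl_inc\tl_skip\tp1_IC\tp1_SC",
               "ex1\t2\t1\t2.5\t1"), path3)
  expect_error(readCountsTable(path3), "ex1.*p1")
})

test_that("dataset join drops unmatched patients with a warning", {
  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tl_inc\tl_skip\tp1_IC\tp1_SC\tp2_IC\tp2_SC",
               "ex1\t2\t1\t4\t1\t2\t3"), cpath)
  spath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\ttime\tevent", "p1\t10\t1", "p3\t4\t0"), spath)
  expect_warning(expect_warning(
    sds <- readSpliceSurvDataSet(cpath, spath), "p2"), "p3")
  expect_equal(colnames(sds), "p1")
  expect_equal(unname(survivalTimes(sds)), 10)
})

test_that("results tables round-trip at 10-decimal precision", {
  res <- data.frame(exon_id = c("a", "b"), beta = c(-1.234567890123, 0),
                    loglik_alt = c(-10.1, -2), loglik_null = c(-12.3, -2),
                    lrt = c(4.4, 0), pvalue = c(0.036, 1),
                    fdr = c(0.072, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeResultsTable(res, path)
  expect_equal(length(readLines(path)), 3L)
  back <- readResultsTable(path)
  expect_equal(back$beta, res$beta, tolerance = 1e-10)
  expect_equal(back$pvalue, res$pvalue, tolerance = 1e-10)

  # empty results give a header-only file
  writeResultsTable(res[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("counts/survival writers round-trip through the readers", {
  co <- simulateCohort(simScenario(nSubjects = 6L, nExons = 3L,
                                   altFraction = 0, meanDepth = 15,
                                   seed = 2L))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeCountsTable(inclusionCounts(co), skippingCounts(co), 2, 1, cpath)
  back <- readCountsTable(cpath)
  expect_equal(unname(back$inclusion), unname(inclusionCounts(co)))
  spath <- withr::local_tempfile(fileext = ".tsv")
  writeSurvivalTable(colnames(inclusionCounts(co)), co@time[1, ],
                     co@event[1, ], spath)
  tab <- readSurvivalTable(spath)
  expect_equal(tab$time, unname(co@time[1, ]))
})

test_that("SpliceSurvDataSet validity rejects bad inputs", {
  ic <- matrix(1:4, 2, 2); sc <- matrix(1:4, 2, 2)
  expect_error(SpliceSurvDataSet(ic, sc, time = c(1, -1),
                                 event = c(0, 1)), "positive")
  expect_error(SpliceSurvDataSet(ic, sc, time = c(1, 2),
                                 event = c(0, 2)), "event")
  sds <- SpliceSurvDataSet(ic, sc, time = c(1, 2), event = c(0, 1))
  expect_s4_class(sds, "SpliceSurvDataSet")
  expect_equal(dim(psiValues(sds)), c(2L, 2L))
})
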
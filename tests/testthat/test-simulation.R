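test_that("synthetic cohorts are reproducible byte for byte from the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- tinyCohort(d1, seed = 99)
  c2 <- tinyCohort(d2, seed = 99)
  for (i in seq_len(nrow(c1$manifest))) {
    expect_identical(readLines(c1$manifest$path[i]), readLines(c2$manifest$path[i]))
  }
  expect_equal(c1$truth$planted_flag, c2$truth$planted_flag)
  expect_identical(readLines(file.path(d1, "proteome.fasta")),
                   readLines(file.path(d2, "proteome.fasta")))
  ## a different seed changes the reads
  c3 <- tinyCohort(withr::local_tempdir(), seed = 100)
  expect_false(identical(readLines(c1$manifest$path[1]),
                         readLines(c3$manifest$path[1])))
})

test_that("full-rate planting puts the whole epitope in every case read", {
  d <- withr::local_tempdir()
  ## with full-length fragments only 40 distinct planted reads exist
  ## (2 offsets x 20 flank letters), so stay below that
  cc <- simulateCohort(d, nCases = 2L, nControls = 2L, readsPerSample = 30L,
                       nDecoys = 3L, decoyLength = 80L, epitopeLength = 11L,
                       minFragment = 11L, plantRate = 1, prevalence = 1,
                       seed = 4)
  epi <- substr(cc$proteome$sequence[1], cc$truth$epitope_start[1],
                cc$truth$epitope_end[1])
  expect_equal(nchar(epi), 11L)
  for (p in cc$manifest$path[cc$manifest$cohort == "case"]) {
    reads <- readLines(p)
    expect_true(all(grepl(epi, reads, fixed = TRUE)))
  }
  ## constituent 5-mers of the epitope are hugely enriched in cases
  rs <- suppressMessages(loadReads(cc$manifest$path[1], minReads = 1L))
  kt <- kmerEnrich(rs)
  e5 <- enrichmentOf(kt, substring(epi, 1:7, 5:11))
  expect_true(all(e5 > 10))

  ## an exhausted planted-read space warns and falls back to background reads
  expect_warning(
    simulateCohort(withr::local_tempdir(), nCases = 1L, nControls = 2L,
                   readsPerSample = 200L, nDecoys = 2L, decoyLength = 60L,
                   epitopeLength = 11L, minFragment = 11L, plantRate = 1,
                   prevalence = 1, seed = 8),
    "saturated")
})

test_that("unplanted cohorts leave cases exchangeable with controls", {
  d <- withr::local_tempdir()
  cc <- simulateCohort(d, nCases = 3L, nControls = 3L, readsPerSample = 500L,
                       nDecoys = 2L, decoyLength = 50L, plantRate = 0,
                       prevalence = 0, seed = 5)
  expect_true(all(!cc$truth$planted_flag))
  ## same generator for both cohorts: read-length and composition match
  caseReads <- readLines(cc$manifest$path[1])
  ctrlReads <- readLines(cc$manifest$path[4])
  expect_true(all(nchar(c(caseReads, ctrlReads)) == 12))
  p <- ksCompareP(table(strsplit(paste(caseReads, collapse = ""), "")[[1]]),
                  table(strsplit(paste(ctrlReads, collapse = ""), "")[[1]]))
  expect_gt(p, 0.001)
})

test_that("magnitude scaling multiplies case values only", {
  expect_equal(scaleMagnitude(c(2, 4), 0.5), c(1, 2))
  expect_equal(scaleMagnitude(c(2, 4), 1), c(2, 4))
  expect_equal(scaleMagnitude(c(2, 4), 0), c(0, 0))
  expect_equal(outlierSum(scaleMagnitude(c(5, 8, 100), 0), c(1, 2, 3, 4)), 0)
})

test_that("prevalence resampling draws from the right pools", {
  vals <- c(7, 7, 5)
  set.seed(20)
  out <- resamplePrevalence(vals, 1, threshold = 6)
  expect_true(all(out == 7))
  out <- resamplePrevalence(vals, 0, threshold = 6)
  expect_true(all(out == 5))
  ## values equal to the threshold belong to the low pool
  out <- resamplePrevalence(c(8, 6, 6), 0, threshold = 6)
  expect_true(all(out == 6))
  expect_error(resamplePrevalence(c(1, 2), 0.5, threshold = 6), "high pool")
  expect_error(resamplePrevalence(c(8, 9), 0.5, threshold = 6), "low pool")

  set.seed(21)
  big <- resamplePrevalence(c(rep(10, 3), rep(1, 5)), 0.5, threshold = 6)
  expect_true(all(big %in% c(10, 1)))
  frac <- mean(replicate(200, mean(resamplePrevalence(c(rep(10, 3), rep(1, 5)),
                                                      0.5, threshold = 6) > 6)))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (200 * 8)))
  ## fixed-count mode hits the target exactly per draw
  fc <- resamplePrevalence(rep(c(10, 1), c(4, 4)), 0.5, threshold = 6,
                           fixedCount = TRUE)
  expect_equal(sum(fc > 6), 4L)
})

test_that("power curves rise with magnitude and collapse at zero signal", {
  set.seed(22)
  ctrl <- rlnorm(50)
  case <- c(rlnorm(12), rlnorm(8, meanlog = 3))
  pc <- powerCurve(case, ctrl, axis = "magnitude", grid = c(0.25, 1, 2),
                   nPerm = 300, seed = 6)
  expect_equal(nrow(pc), 3L)
  expect_true(all(diff(pc$neg_log10_os_p) > -1))  # rises up to MC noise
  expect_gt(pc$neg_log10_os_p[3], pc$neg_log10_os_p[1])

  one <- powerCurve(case, ctrl, axis = "magnitude", grid = 1, nPerm = 300,
                    seed = 6)
  expect_equal(nrow(one), 1L)

  pr <- powerCurve(case, ctrl, axis = "prevalence", grid = c(0.2, 0.9),
                   highThreshold = 6, nResamples = 40, nPerm = 200, seed = 7)
  expect_equal(nrow(pr), 2L)
  expect_gt(pr$neg_log10_os_p[2], pr$neg_log10_os_p[1])
  expect_true(all(pr$os_p_q25 <= pr$os_p + 1e-12))
})
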
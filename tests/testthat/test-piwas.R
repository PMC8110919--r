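## Score-mode fixtures: a sample table plus an all-zero-mean, unit-sd
## background make normalized values equal raw enrichments, so window
## arithmetic can be tested with known numbers.
valueTable <- function(kmers, E, k = 5L) {
  entries <- data.frame(kmer = kmers, k = as.integer(k), n = 1L, e = 1 / E,
                        E = E, F = NA_real_, stringsAsFactors = FALSE)
  new("KmerTable", sampleId = "s", entries = entries,
      aaFreqs = stats::setNames(rep(1 / 20, 20), AA20), readCount = 10L)
}

test_that("tiling yields one value per valid kmer start and masks non-standard letters", {
  tab <- valueTable("AAAAA", 2)
  v <- tileProtein("AAAAAAA", tab, mode = "raw")
  expect_length(v$k5, 3)   # L - k + 1 = 3 starts
  expect_equal(v$k5, rep(2, 3))
  expect_length(v$k6, 2)
  expect_equal(v$k6, c(0, 0))  # no 6-mers in the table

  ## shorter than k: empty track, score 0
  v <- tileProtein("ACD", tab, mode = "raw")
  expect_length(v$k5, 0)
  sc <- piwasScore("ACD", tab, mode = "raw")
  expect_equal(sc$score, 0)
  expect_true(is.na(sc$loc))

  ## an X at position 3 zeroes every 5-mer window covering it
  tabx <- valueTable(c("AAXAA", "AAAAA"), c(5, 5))
  v <- tileProtein("AAXAAAAA", tabx, mode = "raw")
  expect_equal(v$k5[1:3], c(0, 0, 0))
  expect_equal(v$k5[4], 5)
})

test_that("window maximum matches the worked example and degenerate cases", {
  got <- piwasWindowMax(c(1, 2, 3), c(10, 20), w = 1)
  expect_equal(got$score, 33)
  expect_equal(got$loc, 1L)
  expect_equal(piwasWindowMax(rep(0, 5), rep(0, 4), w = 2),
               list(score = 0, loc = 1L))
  ## window wider than the protein: one window covering everything
  v5 <- c(1, 4, 2); v6 <- c(7, 3)
  got <- piwasWindowMax(v5, v6, w = 100)
  expect_equal(got$score, sum(v5, v6))
  expect_equal(got$loc, 1L)
})

test_that("window maximum equals the exhaustive scan on random instances", {
  set.seed(77)
  for (i in 1:60) {
    L <- sample(5:50, 1)
    v5 <- rnorm(L - 4)
    v6 <- if (L >= 6) rnorm(L - 5) else numeric()
    w <- sample(0:8, 1)
    got <- piwasWindowMax(v5, v6, w)
    want <- oracleWindowScore(v5, v6, w)
    expect_identical(got$loc, want$loc)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("increasing any single kmer value never decreases the score", {
  set.seed(13)
  v5 <- rnorm(20); v6 <- rnorm(19)
  base <- piwasWindowMax(v5, v6, 5)$score
  for (i in seq_along(v5)) {
    bumped <- v5; bumped[i] <- bumped[i] + 0.7
    expect_gte(piwasWindowMax(bumped, v6, 5)$score, base)
  }
})

test_that("a zero-valued prefix shifts the location by its length", {
  set.seed(14)
  v5 <- abs(rnorm(12)) + 1; v6 <- abs(rnorm(11)) + 1
  m <- 8L
  base <- piwasWindowMax(v5, v6, 2)
  shifted <- piwasWindowMax(c(rep(0, m), v5), c(rep(0, m), v6), 2)
  expect_equal(shifted$loc, base$loc + m)
  expect_equal(shifted$score, base$score, tolerance = 1e-12)
})

test_that("cohort scoring is long-form and invariant to proteome order", {
  set.seed(31)
  tabs <- lapply(c("s1", "s2"), function(id)
    kmerEnrich(PeptideReadSet(id, randomReads(50))))
  names(tabs) <- c("s1", "s2")
  prot <- data.frame(protein_id = c("p1", "p2", "p3"),
                     description = "",
                     sequence = vapply(c(40, 25, 33), randomProtein, ""),
                     length = c(40L, 25L, 33L), stringsAsFactors = FALSE)
  sc <- scoreCohort(prot, tabs, mode = "raw")
  expect_equal(nrow(sc), 6L)
  expect_setequal(names(sc), c("sample_id", "protein_id", "piwas_score", "piwas_loc"))

  perm <- prot[c(3, 1, 2), ]
  sc2 <- scoreCohort(perm, tabs, mode = "raw")
  key <- function(df) df[order(df$sample_id, df$protein_id), ]
  expect_equal(key(sc)[, 3:4], key(sc2)[, 3:4], ignore_attr = TRUE)

  ## matches the single-protein path exactly
  one <- piwasScore(prot$sequence[2], tabs$s1, mode = "raw")
  row <- sc[sc$sample_id == "s1" & sc$protein_id == "p2", ]
  expect_equal(row$piwas_score, one$score)
  expect_equal(row$piwas_loc, one$loc)
})

test_that("raw and normalized modes agree under an affine background", {
  set.seed(32)
  tab <- kmerEnrich(PeptideReadSet("s", randomReads(40)))
  seqn <- randomProtein(30)
  ## constant background (mean 0, sd 1 via floor): F = E exactly
  bg <- new("ControlBackground", controlIds = c("c1", "c2"),
            entries = data.frame(kmer = character(), k = integer(),
                                 mean = numeric(), sd = numeric(),
                                 n_controls = integer()),
            sdFloor = 1)
  raw <- piwasScore(seqn, tab, mode = "raw")
  norm <- piwasScore(seqn, tab, mode = "normalized", background = bg)
  expect_equal(norm$score, raw$score, tolerance = 1e-12)
  expect_equal(norm$loc, raw$loc)
})

test_that("epitope extraction spans w + 6 residues with C-terminal truncation", {
  expect_equal(extractEpitope("ACDEFGHIKLMNPQRS", 3, w = 5), "DEFGHIKLMNP")
  expect_equal(nchar(extractEpitope("ACDEFGHIKLMNPQRS", 3, w = 5)), 11L)
  expect_equal(extractEpitope("ACDEFGHIKLMN", 9, w = 5), "KLMN")
  expect_error(extractEpitope("ACDEFGHIKLMN", 9L + 5L, w = 5), "valid window start")
})

test_that("dominant epitopes cluster case locations within the window width", {
  seqn <- randomProtein(120, seed = 55)
  ep <- dominantEpitopes(seqn, locs = rep(40L, 5), scores = rep(10, 5))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$loc, 40L)
  expect_equal(ep$support, 5L)
  expect_equal(ep$epitope, substr(seqn, 40, 50))

  ep <- dominantEpitopes(seqn, locs = c(40L, 41L, 92L), scores = c(8, 9, 7), w = 5)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$loc, c(40L, 92L))
  expect_equal(ep$support, c(2L, 1L))

  ## nobody above threshold: empty, not an error
  ep <- dominantEpitopes(seqn, locs = c(10L, 20L), scores = c(1, 2), threshold = 6)
  expect_equal(nrow(ep), 0L)
})
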
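test_that("consensus PWMs place matchProb mass and rows sum to one", {
  p <- makePWM("GATA", 1)
  expect_equal(unname(p@prob[cbind(1:4, match(c("G", "A", "T", "A"),
                                              c("A", "C", "G", "T")))]),
               rep(1, 4))
  u <- makePWM("GATA", 0.25)
  expect_equal(unname(u@prob), matrix(0.25, 4, 4))
  r <- makePWM("ACGTACGT", 0.77)
  expect_equal(rowSums(r@prob), rep(1, 8))
  expect_error(makePWM("GAXA", 0.9), "illegal")
  expect_error(makePWM("GATA", 0.1), "matchProb")
})

test_that("background generation is seeded and honours dinucleotide sources", {
  a <- generateBackground(8, 3, seed = 1)
  b <- generateBackground(8, 3, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generateBackground(8, 3, seed = 2)))

  # first-order chain from ACAC... has zero mass on G->G (and on G at all)
  src <- strrep("AC", 30)
  out <- generateBackground(200, 5, seed = 3, dinucSource = src)
  expect_false(any(grepl("GG", out)))
  counts <- Reduce(`+`, lapply(out, dinucCounts))
  expect_equal(sum(counts[c("AC", "CA")]), sum(counts))

  expect_error(generateBackground(1, 1), ">= 2")
  expect_error(generateBackground(10, 1, dinucSource = "A"), "at least 2")
})

test_that("motif planting replaces exactly the stated window", {
  s <- strrep("C", 10)
  out <- plantMotif(s, makePWM("GATA"), position = "center")
  # centre = floor((10-4)/2) = 3 (0-based) -> positions 4..7 (1-based)
  expect_equal(out, "CCCGATACCC")
  expect_equal(nchar(out), 10L)
  expect_equal(plantMotif(s, makePWM("GATA"), position = 1), "GATACCCCCC")
  expect_error(plantMotif("ACG", makePWM("GATA")), "wider")
  expect_error(plantMotif(s, makePWM("GATA"), position = 8), "out of bounds")
  u <- makePWM("AAAA", 0.25)
  expect_identical(plantMotif(s, u, seed = 5), plantMotif(s, u, seed = 5))
})

test_that("simulated datasets satisfy their structural invariants", {
  ds <- simulateAccessibility(nTypes = 3, cellsPerType = 40, nPeaks = 120,
                              peakLength = 80, seed = 5)
  expect_true(all(ds@truth %in% c(0, 1)))
  expect_true(all(ds@binary[ds@dropout == 1] == 0))
  X <- SummarizedExperiment::assay(ds@counts)
  expect_true(all(X > 0))
  # detected entries carry Normal(8,1)-scale signal
  expect_gt(min(X[ds@binary == 1]), 2)
  # dropout density ~ delta among accessible entries (99% binomial CI)
  p <- mean(ds@dropout[ds@truth == 1])
  n <- sum(ds@truth == 1)
  expect_lt(abs(p - 0.3), 2.58 * sqrt(0.3 * 0.7 / n))
  # bit-identical under the same seed
  ds2 <- simulateAccessibility(nTypes = 3, cellsPerType = 40, nPeaks = 120,
                               peakLength = 80, seed = 5)
  expect_identical(X, SummarizedExperiment::assay(ds2@counts))
  expect_identical(as.character(ds@sequences), as.character(ds2@sequences))
})

test_that("planted motifs drive cell-type-specific accessibility in truth", {
  ds <- simulateAccessibility(nTypes = 3, cellsPerType = 60, nPeaks = 300,
                              peakLength = 120, seed = 21)
  motifs <- ds@design$motifNames
  for (t in 1:3) {
    peaks <- which(ds@motifTable$motif == motifs[t])
    own <- ds@cellTypes == levels(ds@cellTypes)[t]
    expect_gt(mean(ds@truth[peaks, own]), mean(ds@truth[peaks, !own]) + 0.5)
  }
})

test_that("degenerate dropout settings behave as designed", {
  two <- lapply(c("TGATAAGG", "CACGTGAC"), makePWM, matchProb = 0.9)
  ds0 <- simulateAccessibility(nTypes = 2, cellsPerType = 25, nPeaks = 60,
                               peakLength = 60, motifs = two,
                               activity = rbind(c(0.95, 0.02),
                                                c(0.02, 0.95)),
                               dropoutRate = 0, seed = 2)
  expect_equal(sum(ds0@dropout), 0)
  ds1 <- simulateAccessibility(nTypes = 2, cellsPerType = 25, nPeaks = 60,
                               peakLength = 60, motifs = two,
                               activity = rbind(c(0.95, 0.02),
                                                c(0.02, 0.95)),
                               dropoutRate = 1,
                               captureRange = c(1, 1), seed = 2)
  expect_true(all(ds1@binary == 0)) # every accessible site dropped
  X <- SummarizedExperiment::assay(ds1@counts)
  expect_lt(mean(X), 2) # counts are pure Gamma noise
})

test_that("fixture export round-trips through the loaders", {
  two <- lapply(c("TGATAAGG", "CACGTGAC"), makePWM, matchProb = 0.9)
  act2 <- rbind(c(0.95, 0.02), c(0.02, 0.95))
  ds <- simulateAccessibility(nTypes = 2, cellsPerType = 20, nPeaks = 40,
                              peakLength = 60, motifs = two,
                              activity = act2, seed = 8)
  d <- tempfile()
  man <- writeFixture(ds, d)
  expect_true(all(c("peaks.fa", "matrix.mtx", "cell_types.tsv") %in%
                  man$file))
  back <- readPeakCellMatrix(d)
  expect_identical(SummarizedExperiment::assay(back),
                   SummarizedExperiment::assay(ds@counts))
  g <- readGenomeFasta(file.path(d, "peaks.fa"))
  expect_identical(as.character(g), as.character(ds@sequences))
  peaks <- readPeakBed(file.path(d, "peaks.bed"))
  expect_identical(extractPeakSequences(g, peaks, 60),
                   unname(as.character(ds@sequences)))
  # different seed -> different content checksums
  ds2 <- simulateAccessibility(nTypes = 2, cellsPerType = 20, nPeaks = 40,
                               peakLength = 60, motifs = two,
                               activity = act2, seed = 9)
  d2 <- tempfile()
  man2 <- writeFixture(ds2, d2)
  expect_false(man$md5[man$file == "matrix.mtx"] ==
               man2$md5[man2$file == "matrix.mtx"])
})
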
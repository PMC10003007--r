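test_that("FASTA reading normalises case, maps ambiguity codes, keys by token", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "AANRGT"), fa)
  g <- readGenomeFasta(fa)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGT")
  expect_equal(as.character(g[["chr2"]]), "AANNGT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(readGenomeFasta(fa), "duplicate")
  writeLines(character(), fa)
  expect_error(readGenomeFasta(fa))
})

test_that("BED peaks honour half-open coordinates and skip header lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "chr1\t10\t20\tp1", "chr1\t30\t45\tp2\t0\t-"),
             bed)
  gr <- readPeakBed(bed)
  expect_length(gr, 2)
  expect_equal(GenomicRanges::start(gr), c(11L, 31L))
  expect_equal(GenomicRanges::end(gr), c(20L, 45L))
  expect_equal(GenomicRanges::width(gr)[1], 10L)
  expect_equal(as.character(GenomicRanges::strand(gr)), c("*", "-"))

  writeLines("chr1\t20\t10", bed)
  expect_error(readPeakBed(bed), "start >= end")
  writeLines("chr1\t1.5\t10", bed)
  expect_error(readPeakBed(bed), "non-integer")
})

test_that("sequence extraction centres, pads with N, and errors off-contig", {
  contig <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(contig, "chr1"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20)) # [10,20)
  expect_equal(extractPeakSequences(genome, gr, 10), substr(contig, 11, 20))

  # [0,4) widened to 8: centre floor((0+4)/2)=2 -> window [-2,6)
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4))
  expect_equal(extractPeakSequences(genome, gr2, 8),
               paste0("NN", substr(contig, 1, 6)))
  # right-side overhang
  gr3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(97, 100))
  out <- extractPeakSequences(genome, gr3, 8)
  expect_equal(nchar(out), 8L)
  expect_match(out, "NN$")

  grZ <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 4))
  expect_error(extractPeakSequences(genome, grZ, 8), "chrZ")

  # always exactly targetLength, any peak width
  for (w in c(1, 5, 50, 99)) {
    grW <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40, 39 + w))
    expect_equal(nchar(extractPeakSequences(genome, grW, 21)), 21L)
  }
})

test_that("one-hot encoding follows the A,C,G,T channel order and N rule", {
  b <- oneHotEncode("ACG")
  expect_equal(b@encoding[, , 1],
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  bn <- oneHotEncode("N")
  expect_equal(as.numeric(bn@encoding[1, , 1]), rep(0.25, 4))
  expect_error(oneHotEncode(c("AC", "ACG")), "same length")
  expect_error(oneHotEncode("AXGT"), "illegal character")
})

test_that("encode-decode is the identity on A/C/G/T strings", {
  seqs <- generateBackground(40, 25, seed = 9)
  expect_equal(oneHotDecode(oneHotEncode(seqs)), unname(seqs))
  expect_equal(oneHotDecode(oneHotEncode("ANGT")), "ANGT")
})

test_that("peak-by-cell MTX round trip is bit-exact and errors on mismatch", {
  m <- matrix(c(0, 2.25, 5.6789012345678901, 0, 1e-7, 8.1), 3, 2,
              dimnames = list(paste0("p", 1:3), paste0("c", 1:2)))
  pcm <- PeakCellMatrix(m, cellTypes = c("x", "y"))
  d <- tempfile()
  writePeakCellMatrix(pcm, d)
  back <- readPeakCellMatrix(d)
  expect_identical(SummarizedExperiment::assay(back, "counts"),
                   SummarizedExperiment::assay(pcm, "counts"))
  expect_equal(cellTypes(back), c("x", "y"))
  # another full cycle preserves bits again
  d2 <- tempfile()
  writePeakCellMatrix(back, d2)
  expect_identical(SummarizedExperiment::assay(readPeakCellMatrix(d2)),
                   SummarizedExperiment::assay(pcm))

  writeLines("p1", file.path(d, "peaks.tsv"))
  expect_error(readPeakCellMatrix(d), "identifiers")
  expect_error(readPeakCellMatrix(d, format = "h5ad"), "not supported")
})

test_that("binarize thresholds counts and leaves the input untouched", {
  m <- matrix(c(0, 2, 5, 0), 2, 2, dimnames = list(c("p1", "p2"),
                                                   c("c1", "c2")))
  pcm <- PeakCellMatrix(m)
  b <- binarize(pcm)
  expect_equal(unname(SummarizedExperiment::assay(b)),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(SummarizedExperiment::assay(pcm)["p1", "c2"], 5) # pure
  z <- matrix(0, 2, 2, dimnames = dimnames(m))
  expect_equal(unname(binarize(z)), unname(z))
  expect_error(binarize(matrix(-1)), "negative")
})

test_that("peak splitting is a reproducible partition with stated sizes", {
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, 991, 100), width = 10))
  s1 <- splitPeaks(peaks, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(lengths(attr(s1, "indices")),
               c(train = 8L, val = 1L, test = 1L))
  s2 <- splitPeaks(peaks, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(attr(s1, "indices"), attr(s2, "indices"))
  idx <- attr(s1, "indices")
  expect_setequal(unlist(idx), seq_along(peaks))
  expect_length(intersect(idx$train, idx$val), 0)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_length(intersect(idx$val, idx$test), 0)
  expect_error(splitPeaks(peaks, c(0.5, 0.5, 0.5)), "sum to 1")
})
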
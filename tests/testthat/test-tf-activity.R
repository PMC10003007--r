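test_that("JASPAR PFM parsing converts counts to probabilities", {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TESTA",
               "A [ 10  0  5  2 ]",
               "C [  0  0  5  2 ]",
               "G [  0 10  5  4 ]",
               "T [  0  0  5  2 ]"), f)
  lib <- readJasparPfm(f)
  p <- lib[["TESTA"]]
  expect_equal(unname(p@prob[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(p@prob[2, ]), c(0, 0, 1, 0))
  expect_equal(unname(p@prob[3, ]), rep(0.25, 4))
  expect_equal(unname(p@prob[4, ]), c(0.2, 0.2, 0.4, 0.2))
  expect_equal(rowSums(p@prob), rep(1, 4))
  expect_equal(p@consensus, "AGAG") # ties at uniform resolve to first base
  expect_equal(pwmWidth(p), 4L)

  writeLines(c(">MA0002.1 BAD", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(readJasparPfm(f), "4 base rows")
  writeLines(c(">MA0003.1 RAGGED", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), f)
  expect_error(readJasparPfm(f), "unequal")
})

test_that("dinucleotide shuffling preserves the dinucleotide multiset", {
  expect_equal(dinucShuffle("AAAA", seed = 1), "AAAA")
  set.seed(14)
  for (rep in 1:1000) {
    L <- sample(10:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    out <- dinucShuffle(s, seed = rep)
    expect_identical(dinucCounts(out), dinucCounts(s))
  }
  expect_error(dinucShuffle("A"), "at least 2 bp")
})

test_that("shuffles of an 8-mer stay within the brute-force valid set", {
  s <- "ACGTACGT"
  target <- dinucCounts(s)
  # enumerate every arrangement with the same dinucleotide counts by a
  # depth-first walk over the remaining-character multiset
  chars <- strsplit(s, "")[[1]]
  pool <- table(chars)
  valid <- character()
  walk <- function(prefix, left) {
    if (sum(left) == 0) {
      cand <- paste(prefix, collapse = "")
      if (identical(dinucCounts(cand), target))
        valid <<- c(valid, cand)
      return(invisible())
    }
    for (ch in names(left)[left > 0]) {
      left[ch] <- left[ch] - 1
      walk(c(prefix, ch), left)
      left[ch] <- left[ch] + 1
    }
  }
  walk(character(), pool)
  valid <- unique(valid)
  outs <- vapply(1:20, function(sd) dinucShuffle(s, seed = sd), "")
  expect_true(all(outs %in% valid))
  # a sequence whose transition graph branches admits multiple shuffles
  branchy <- "ACAGATACAGAT"
  outs2 <- vapply(1:20, function(sd) dinucShuffle(branchy, seed = sd), "")
  expect_gt(length(unique(outs2)), 1)
  expect_true(all(vapply(outs2, function(o)
    identical(dinucCounts(o), dinucCounts(branchy)), TRUE)))
})

test_that("ISM maps are centred per position and vanish for flat predictors", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  s <- generateBackground(16, 1, seed = 15)
  ism <- ismMap(m, s)
  sums <- apply(ism@scores, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-6)
  # centring over all four nucleotides puts the reference base at minus a
  # quarter of the summed alternative deltas
  refIdx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  for (pos in c(1, 8, 16)) {
    alt <- setdiff(1:4, refIdx[pos])
    raw <- ism@scores[pos, alt, 3] - ism@scores[pos, refIdx[pos], 3]
    expect_equal(ism@scores[pos, refIdx[pos], 3], -sum(raw) / 4,
                 tolerance = 1e-9)
  }
  # constant predictor: zero final layer gives identical outputs everywhere
  m@params$Wp[] <- 0
  ism0 <- ismMap(m, s)
  expect_equal(max(abs(ism0@scores)), 0)
})

test_that("PWM-ISM scores reduce to the expected dot products", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  s <- generateBackground(16, 1, seed = 16)
  ism <- ismMap(m, s)
  pwm <- makePWM("GATA")
  sc <- pwmIsmScore(ism, pwm, offset = 5)
  manual <- vapply(seq_len(5), function(cell)
    sum(pwm@prob * ism@scores[5:8, , cell]), 0)
  expect_equal(unname(sc), manual)
  # one-hot PWM: sum of ISM entries at the consensus bases
  idx <- match(strsplit("GATA", "")[[1]], c("A", "C", "G", "T"))
  expect_equal(unname(sc),
               vapply(1:5, function(cell)
                 sum(ism@scores[cbind(5:8, idx, cell)]), 0))
  # uniform PWM: forced to zero by the per-position centring
  expect_lt(max(abs(pwmIsmScore(ism, makePWM("AAAA", 0.25), 5))), 1e-9)
  # zeroed tensor: zero scores
  ism@scores[] <- 0
  expect_equal(unname(pwmIsmScore(ism, pwm, 5)), rep(0, 5))
  expect_error(pwmIsmScore(ism, pwm, 14), "out of range")
})

test_that("motif insertion influence is zero when the motif is already there", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  pwm <- makePWM("GATTACAG")
  s <- plantMotif(generateBackground(16, 1, seed = 17), pwm)
  expect_identical(plantMotif(s, pwm), s) # centre insertion is idempotent
  y1 <- predictAccessibility(m, oneHotEncode(s))
  y2 <- predictAccessibility(m, oneHotEncode(plantMotif(s, pwm)))
  expect_equal(y1, y2)
})

test_that("activity scores are the mean influence and are z-normalised", {
  cfg <- tiny_config()
  m <- tiny_model(cfg)
  peaks <- generateBackground(16, 6, seed = 18)
  act <- motifActivity(m, list(makePWM("GATTAC"), makePWM("CCGGTT")),
                       peaks, nBackground = 4, seed = 2)
  expect_equal(dim(act@activity), c(2L, 5L))
  for (nm in rownames(act@activity))
    expect_equal(act@activity[nm, ], colMeans(act@influence[[nm]]),
                 tolerance = 1e-9)
  expect_equal(unname(rowMeans(act@normalized)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(act@normalized, 1, sd)), c(1, 1),
               tolerance = 1e-9)
  # deterministic under a fixed seed
  act2 <- motifActivity(m, list(makePWM("GATTAC"), makePWM("CCGGTT")),
                        peaks, nBackground = 4, seed = 2)
  expect_identical(act@activity, act2@activity)
  expect_error(motifActivity(m, makePWM("GATTAC"), peaks, nBackground = 0),
               "at least one")
  expect_error(motifActivity(m, makePWM(strrep("A", 20)), peaks, 2),
               "wider")
})
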
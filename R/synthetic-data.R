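#' Generate background DNA sequences
#'
#' Without a `dinucSource`, bases are drawn i.i.d. uniformly from A/C/G/T.
#' With one, sequences are sampled from the first-order Markov chain
#' estimated from that source's dinucleotide frequencies, reproducing its
#' local composition.
#'
#' @param length sequence length (>= 2).
#' @param n number of sequences.
#' @param seed integer seed.
#' @param dinucSource optional template sequence (>= 2 bp) whose dinucleotide
#'   transition frequencies are used.
#' @return character vector of `n` sequences.
#' @export
generateBackground <- function(length, n = 1, seed = 0, dinucSource = NULL) {
  .assert(length >= 2, "background length must be >= 2 bp")
  trans <- NULL
  init <- rep(0.25, 4)
  if (!is.null(dinucSource)) {
    src <- strsplit(toupper(as.character(dinucSource)), "")[[1]]
    .assert(base::length(src) >= 2, "dinucSource must be at least 2 bp")
    i1 <- match(src[-base::length(src)], BASES)
    i2 <- match(src[-1], BASES)
    .assert(!anyNA(i1) && !anyNA(i2), "dinucSource must be over A/C/G/T")
    trans <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    for (k in seq_along(i1)) trans[i1[k], i2[k]] <- trans[i1[k], i2[k]] + 1
    rs <- rowSums(trans)
    init <- tabulate(i1, 4) / base::length(i1)
    trans[rs > 0, ] <- trans[rs > 0, , drop = FALSE] / rs[rs > 0]
    trans[rs == 0, ] <- 0.25 # unreachable states: uniform fallback
  }
  with_seed(seed, {
    vapply(seq_len(n), function(j) {
      if (is.null(trans)) {
        paste(sample(BASES, length, replace = TRUE), collapse = "")
      } else {
        s <- integer(length)
        s[1] <- sample.int(4, 1, prob = init)
        for (p in 2:length)
          s[p] <- sample.int(4, 1, prob = trans[s[p - 1], ])
        paste(BASES[s], collapse = "")
      }
    }, "")
  })
}

#' Plant a motif instance into a sequence
#'
#' Replaces a window of the sequence by a draw from the PWM (the consensus
#' when the PWM is deterministic); the rest of the sequence and its length
#' are unchanged.
#'
#' @param sequence host sequence.
#' @param pwm a [PWM] no wider than the sequence.
#' @param position `"center"` (window starts at floor((L - w) / 2), 0-based)
#'   or a 1-based start index.
#' @param seed optional integer seed for the PWM draw.
#' @return the modified sequence.
#' @export
plantMotif <- function(sequence, pwm, position = "center", seed = NULL) {
  L <- nchar(sequence)
  w <- pwmWidth(pwm)
  .assert(w <= L, "motif (", w, " bp) wider than sequence (", L, " bp)")
  start <- if (identical(position, "center")) (L - w) %/% 2L + 1L
           else as.integer(position)
  .assert(start >= 1 && start + w - 1L <= L,
          "motif window [", start, ", ", start + w - 1L,
          "] out of bounds for a ", L, " bp sequence")
  inst <- samplePWM(pwm, seed = seed)
  paste0(substr(sequence, 1, start - 1L), inst,
         substr(sequence, start + w, L))
}

#' Simulate a desk-scale scATAC-seq dataset with planted regulatory structure
#'
#' Generates peak sequences with at most one planted motif each, a clean
#' binary ground-truth accessibility matrix driven by a cell-type x motif
#' activity matrix, and an observed count matrix corrupted the way scATAC
#' data are: truly accessible sites are detected only with the cell's capture
#' efficiency and are additionally lost to dropout at rate `dropoutRate`;
#' detected sites carry truncated-Normal signal counts, everything else
#' low-magnitude Gamma noise. The binary detection matrix (exactly zero at
#' every dropped site) provides training labels; the continuous counts feed
#' the mixture-model denoiser.
#'
#' @param nTypes number of cell types.
#' @param cellsPerType cells per type.
#' @param nPeaks number of peaks.
#' @param peakLength peak sequence length in bp.
#' @param motifs list of [PWM]s planted in peaks (one motif per peak at
#'   most); default three distinct 10-bp motifs at match probability 0.9.
#'   Defaults emulate the sparse, shallow detection of real scATAC-seq:
#'   per-cell capture of open sites well below one half, so that the raw
#'   matrix carries depth-dominated rather than type-dominated structure.
#' @param activity cell-type x motif activity matrix with entries in [0, 1];
#'   default: each motif strongly active (0.95) in exactly one type and
#'   nearly silent (0.02) elsewhere.
#' @param motifFrac fraction of peaks carrying a motif.
#' @param motifPosition `"center"` plants each motif at the peak centre
#'   (ATAC peaks are summit-centred, where motif density concentrates);
#'   `"random"` draws a uniform position per peak.
#' @param p0 accessibility rate of motif-free peaks.
#' @param captureRange per-cell capture efficiency range (uniform draw).
#' @param dropoutRate dropout probability applied to accessible sites.
#' @param gammaShape,gammaRate Gamma noise component (mass near zero).
#' @param normalMean,normalSd truncated-Normal signal component.
#' @param seed integer seed; fixed seeds give bit-identical datasets.
#' @return a [SyntheticDataset].
#' @export
simulateAccessibility <- function(nTypes = 3, cellsPerType = 200,
                                  nPeaks = 1000, peakLength = 300,
                                  motifs = NULL, activity = NULL,
                                  motifFrac = 0.2,
                                  motifPosition = c("center", "random"),
                                  p0 = 0.01,
                                  captureRange = c(0.2, 0.5),
                                  dropoutRate = 0.3,
                                  gammaShape = 2, gammaRate = 2,
                                  normalMean = 8, normalSd = 1,
                                  seed = 0) {
  .assert(nTypes >= 2, "at least two cell types required")
  .assert(nPeaks >= 1 && cellsPerType >= 1, "empty design")
  motifPosition <- match.arg(motifPosition)
  if (is.null(motifs))
    motifs <- lapply(c("TGATAAGGTC", "CACGTGACCT", "TTCCGGAAGT"),
                     makePWM, matchProb = 0.9)
  nM <- length(motifs)
  motifNames <- vapply(motifs, function(p) p@name, "")
  if (is.null(activity)) {
    .assert(nM == nTypes,
            "default activity matrix needs one motif per cell type")
    activity <- matrix(0.02, nTypes, nM)
    diag(activity) <- 0.95
  }
  .assert(all(activity >= 0 & activity <= 1), "activity must lie in [0, 1]")
  .assert(all(apply(activity > 0.5, 2, any)),
          "every motif must be active in at least one cell type")
  nCells <- nTypes * cellsPerType

  with_seed(seed, {
    types <- rep(seq_len(nTypes), each = cellsPerType)
    capture <- runif(nCells, captureRange[1], captureRange[2])

    nMotifPeaks <- round(motifFrac * nPeaks)
    motifOf <- rep(NA_integer_, nPeaks)
    if (nMotifPeaks > 0)
      motifOf[sample.int(nPeaks, nMotifPeaks)] <-
        rep_len(seq_len(nM), nMotifPeaks)

    seqs <- generateBackground(peakLength, nPeaks,
                               seed = sample.int(.Machine$integer.max, 1))
    pos <- rep(NA_integer_, nPeaks)
    for (p in which(!is.na(motifOf))) {
      w <- pwmWidth(motifs[[motifOf[p]]])
      pos[p] <- if (motifPosition == "center") (peakLength - w) %/% 2L + 1L
                else sample.int(peakLength - w + 1L, 1)
      seqs[p] <- plantMotif(seqs[p], motifs[[motifOf[p]]], position = pos[p])
    }

    rate <- matrix(p0, nPeaks, nCells)
    mp <- which(!is.na(motifOf))
    if (length(mp))
      rate[mp, ] <- t(activity[types, motifOf[mp], drop = FALSE])
    truth <- matrix(rbinom(nPeaks * nCells, 1, rate), nPeaks, nCells)
    dropout <- matrix(0L, nPeaks, nCells)
    acc <- truth == 1
    dropout[acc] <- rbinom(sum(acc), 1, dropoutRate)
    capt <- matrix(rbinom(nPeaks * nCells, 1,
                          rep(capture, each = nPeaks)),
                   nPeaks, nCells)
    detected <- truth * (1L - dropout) * capt

    counts <- matrix(rgamma(nPeaks * nCells, gammaShape, gammaRate),
                     nPeaks, nCells)
    nDet <- sum(detected == 1)
    if (nDet) {
      sig <- rnorm(nDet, normalMean, normalSd)
      while (any(sig <= 0)) # truncation at zero by rejection
        sig[sig <= 0] <- rnorm(sum(sig <= 0), normalMean, normalSd)
      counts[detected == 1] <- sig
    }

    peakNames <- sprintf("peak_%04d", seq_len(nPeaks))
    cellNames <- sprintf("cell_%04d", seq_len(nCells))
    typeNames <- paste0("type", seq_len(nTypes))
    dimnames(truth) <- dimnames(dropout) <- dimnames(detected) <-
      dimnames(counts) <- list(peakNames, cellNames)
    names(seqs) <- peakNames

    pcm <- PeakCellMatrix(counts, cellTypes = typeNames[types])
    new("SyntheticDataset",
        sequences = Biostrings::DNAStringSet(seqs),
        counts = pcm,
        binary = detected * 1,
        truth = truth * 1,
        dropout = dropout * 1,
        cellTypes = factor(typeNames[types], levels = typeNames),
        motifTable = data.frame(
          peak = peakNames,
          motif = ifelse(is.na(motifOf), NA_character_,
                         motifNames[motifOf]),
          position = pos, stringsAsFactors = FALSE),
        design = list(nTypes = nTypes, cellsPerType = cellsPerType,
                      nPeaks = nPeaks, peakLength = peakLength,
                      motifFrac = motifFrac, p0 = p0,
                      captureRange = captureRange,
                      dropoutRate = dropoutRate,
                      gammaShape = gammaShape, gammaRate = gammaRate,
                      normalMean = normalMean, normalSd = normalSd,
                      activity = activity, motifNames = motifNames,
                      seed = seed))
  })
}

#' Write a synthetic dataset to standard on-disk formats
#'
#' Emits a FASTA of peak sequences, a BED of pseudo-coordinates (one contig
#' per peak), MTX + sidecars for the observed counts, TSVs of labels, truth,
#' binary detection and dropout masks, and a manifest of MD5 checksums.
#'
#' @param dataset a [SyntheticDataset].
#' @param dir output directory.
#' @return data.frame manifest (file, md5).
#' @export
writeFixture <- function(dataset, dir) {
  .assert(length(dataset@sequences) > 0, "empty dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "peaks.fa")
  Biostrings::writeXStringSet(dataset@sequences, fa)
  bed <- file.path(dir, "peaks.bed")
  L <- Biostrings::width(dataset@sequences)
  write.table(data.frame(names(dataset@sequences), 0L, L,
                         names(dataset@sequences)),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writePeakCellMatrix(dataset@counts, dir)
  lab <- file.path(dir, "cell_types.tsv")
  write.table(data.frame(cell = colnames(dataset@counts),
                         cell_type = as.character(dataset@cellTypes)),
              lab, sep = "\t", quote = FALSE, row.names = FALSE)
  extras <- c(binary = "binary.tsv", truth = "truth.tsv",
              dropout = "dropout.tsv")
  for (k in names(extras)) {
    f <- file.path(dir, extras[[k]])
    write.table(slot(dataset, k), f, sep = "\t", quote = FALSE)
  }
  files <- c(fa, bed, file.path(dir, c("matrix.mtx", "peaks.tsv",
                                       "barcodes.tsv")), lab,
             file.path(dir, extras))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
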
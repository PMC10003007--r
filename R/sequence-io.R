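#' Read a genome FASTA file
#'
#' Records are keyed by the first whitespace-separated token of their header.
#' Sequences are uppercased; IUPAC ambiguity codes other than A/C/G/T are
#' mapped to N.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] with one entry per contig.
#' @export
readGenomeFasta <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  .assert(length(seqs) > 0, "FASTA file contains no records: ", path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  .assert(!anyDuplicated(names(seqs)),
          "duplicate contig names in ", path, ": ",
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  .assert(all(Biostrings::width(seqs) > 0), "empty sequence in ", path)
  chars <- toupper(as.character(seqs))
  chars <- chartr("RYSWKMBDHV", "NNNNNNNNNN", chars)
  .assert(!any(grepl("[^ACGTN]", chars)),
          "sequences contain characters outside the IUPAC alphabet")
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(seqs)
  out
}

#' Read peak intervals from a BED file
#'
#' BED coordinates are 0-based half-open; the returned GRanges uses the usual
#' 1-based closed convention (start + 1). `track`, `browser` and `#` lines
#' are skipped. Columns 4 (name) and 6 (strand) are honoured when present.
#'
#' @param path path to a BED3+ file.
#' @return a [GenomicRanges::GRanges] in file order.
#' @export
readPeakBed <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  .assert(length(lines) > 0, "no peak records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  .assert(all(ncols >= 3), "BED lines need at least 3 tab-separated columns")
  chrom <- vapply(fields, `[`, "", 1)
  s <- vapply(fields, `[`, "", 2)
  e <- vapply(fields, `[`, "", 3)
  .assert(all(grepl("^[0-9]+$", s)) && all(grepl("^[0-9]+$", e)),
          "non-integer coordinates in ", path)
  s <- as.integer(s); e <- as.integer(e)
  bad <- which(s >= e)
  .assert(length(bad) == 0,
          "start >= end at line(s): ", paste(head(bad, 5), collapse = ", "))
  nm <- ifelse(ncols >= 4, vapply(fields, `[`, "", 4), NA_character_)
  st <- ifelse(ncols >= 6, vapply(fields, `[`, "", 6), "*")
  st[!st %in% c("+", "-", "*")] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e),
                               strand = st)
  if (any(!is.na(nm))) names(gr) <- nm
  gr
}

#' Extract fixed-length sequences centred on peaks
#'
#' Each peak is resized symmetrically about its midpoint
#' (floor((start + end) / 2) in 0-based coordinates) to exactly
#' `targetLength` bp, read from the + strand; positions falling outside the
#' contig are filled with N.
#'
#' @param genome a [Biostrings::DNAStringSet] as from [readGenomeFasta()].
#' @param peaks a [GenomicRanges::GRanges] as from [readPeakBed()].
#' @param targetLength window length L in bp.
#' @return character vector of sequences, all of length `targetLength`.
#' @export
extractPeakSequences <- function(genome, peaks, targetLength) {
  .assert(targetLength >= 1, "targetLength must be >= 1")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(chrom), names(genome))
  .assert(length(missing) == 0,
          "peaks on contigs absent from the genome: ",
          paste(missing, collapse = ", "))
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  center <- (start0 + end0) %/% 2L
  win0 <- center - targetLength %/% 2L
  win1 <- win0 + targetLength - 1L      # inclusive, 0-based
  lens <- setNames(Biostrings::width(genome), names(genome))
  gchar <- setNames(as.character(genome), names(genome))
  vapply(seq_along(peaks), function(i) {
    L <- lens[[chrom[i]]]
    lo <- max(win0[i], 0L)
    hi <- min(win1[i], L - 1L)
    core <- if (lo <= hi) substr(gchar[[chrom[i]]], lo + 1L, hi + 1L) else ""
    paste0(strrep("N", max(0L, -win0[i])), core,
           strrep("N", max(0L, win1[i] - (L - 1L))))
  }, "")
}

#' One-hot encode DNA sequences
#'
#' A, C, G, T map to unit vectors in channel order A, C, G, T; N maps to
#' 0.25 in every channel so each position keeps unit mass.
#'
#' @param sequences character vector or DNAStringSet of equal-length
#'   sequences over A/C/G/T/N.
#' @param ids per-sequence identifiers (defaults to names or seq numbers).
#' @return a [OneHotBatch].
#' @export
oneHotEncode <- function(sequences, ids = NULL) {
  sequences <- as.character(sequences)
  .assert(length(sequences) > 0, "no sequences to encode")
  L <- unique(nchar(sequences))
  .assert(length(L) == 1, "sequences must all have the same length")
  if (is.null(ids)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  }
  lut <- rbind(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0),
               T = c(0, 0, 0, 1), N = c(0.25, 0.25, 0.25, 0.25))
  enc <- array(0, dim = c(L, 4, length(sequences)))
  for (b in seq_along(sequences)) {
    ch <- strsplit(toupper(sequences[b]), "")[[1]]
    idx <- match(ch, rownames(lut))
    .assert(!anyNA(idx), "illegal character in sequence ", ids[b], ": ",
            paste(unique(ch[is.na(idx)]), collapse = ""))
    enc[, , b] <- lut[idx, ]
  }
  new("OneHotBatch", encoding = enc, ids = as.character(ids))
}

#' Decode a one-hot batch back to sequences
#'
#' Argmax per position (ties impossible for A/C/G/T; uniform rows decode
#' to N).
#'
#' @param batch a [OneHotBatch].
#' @return character vector of sequences.
#' @export
oneHotDecode <- function(batch) {
  enc <- batch@encoding
  apply(enc, 3, function(m) {
    idx <- max.col(m, ties.method = "first")
    idx[abs(m[cbind(seq_len(nrow(m)), idx)] - 0.25) < 1e-9] <- 5L
    paste(c(BASES, "N")[idx], collapse = "")
  })
}

#' Split peaks into train/validation/test sets
#'
#' Disjoint, exhaustive and reproducible under a fixed seed. Set sizes are
#' floor(fraction * n) with the remainder assigned in order of largest
#' fractional part (ties to the earlier set).
#'
#' @param peaks a GRanges, or anything with a length, to split by index.
#' @param fractions length-3 positive numeric summing to 1
#'   (train, validation, test).
#' @param seed integer seed.
#' @return named list of three objects of the same class as `peaks`; the
#'   `indices` attribute holds the index partition.
#' @export
splitPeaks <- function(peaks, fractions = c(0.8, 0.1, 0.1), seed = 0) {
  .assert(length(fractions) == 3 && all(fractions > 0),
          "fractions must be 3 positive numbers")
  .assert(abs(sum(fractions) - 1) <= 1e-9, "fractions must sum to 1")
  n <- length(peaks)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = sort(perm[seq_len(sizes[1])]),
              val = sort(perm[sizes[1] + seq_len(sizes[2])]),
              test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  out <- lapply(idx, function(i) peaks[i])
  attr(out, "indices") <- idx
  out
}
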
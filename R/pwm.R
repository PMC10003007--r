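#' Build a PWM from a consensus sequence
#'
#' The consensus base receives `matchProb` at each position, the three other
#' bases (1 - matchProb) / 3 each, so rows always sum to 1. `matchProb` =
#' 0.25 gives a fully uniform (uninformative) motif, 1 a deterministic one.
#'
#' @param consensus motif consensus over A/C/G/T.
#' @param matchProb probability of the consensus base, in [0.25, 1].
#' @param name motif identifier (defaults to the consensus).
#' @return a [PWM].
#' @export
makePWM <- function(consensus, matchProb = 1, name = consensus) {
  .assert(matchProb >= 0.25 && matchProb <= 1,
          "matchProb must lie in [0.25, 1]")
  ch <- strsplit(toupper(consensus), "")[[1]]
  idx <- match(ch, BASES)
  .assert(!anyNA(idx), "illegal consensus character: ",
          paste(unique(ch[is.na(idx)]), collapse = ""))
  p <- matrix((1 - matchProb) / 3, length(ch), 4,
              dimnames = list(NULL, BASES))
  p[cbind(seq_along(idx), idx)] <- matchProb
  new("PWM", name = name, prob = p, consensus = paste(ch, collapse = ""))
}

#' @describeIn makePWM consensus string of a PWM (argmax base per position).
#' @param pwm a [PWM].
#' @export
pwmConsensus <- function(pwm) {
  paste(BASES[max.col(pwm@prob, ties.method = "first")], collapse = "")
}

#' @describeIn makePWM motif width in bp.
#' @export
pwmWidth <- function(pwm) nrow(pwm@prob)

#' Sample a motif instance from a PWM
#'
#' @param pwm a [PWM].
#' @param seed optional integer seed.
#' @return a single sequence of the motif's width.
#' @export
samplePWM <- function(pwm, seed = NULL) {
  with_seed(seed, {
    paste(apply(pwm@prob, 1, function(p) sample(BASES, 1, prob = p)),
          collapse = "")
  })
}

#' Read motifs from a JASPAR-format PFM file
#'
#' Parses the four-row JASPAR text format
#' (`>ID NAME` header, then `A [ 1 2 ... ]` etc.); counts are converted to
#' probabilities by column sum.
#'
#' @param path path to a JASPAR PFM file (one or more motifs).
#' @return named list of [PWM] objects.
#' @export
readJasparPfm <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  .assert(length(starts) > 0, "no JASPAR records in ", path)
  out <- list()
  for (s in seq_along(starts)) {
    i <- starts[s]
    stop_at <- if (s < length(starts)) starts[s + 1] - 1 else length(lines)
    block <- lines[(i + 1):stop_at]
    .assert(length(block) == 4,
            "JASPAR record must have exactly 4 base rows, got ",
            length(block))
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    id <- hdr[1]
    nm <- if (length(hdr) > 1) hdr[2] else hdr[1]
    rows <- lapply(block, function(l) {
      base <- sub("^([ACGT]).*", "\\1", l)
      tail <- sub("^[ACGT]", "", l)
      nums <- regmatches(tail, gregexpr("[0-9.]+", tail))[[1]]
      list(base = base, counts = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, "", "base")
    .assert(setequal(bases, BASES), "expected one row per base A/C/G/T")
    lens <- vapply(rows, function(r) length(r$counts), 0L)
    .assert(length(unique(lens)) == 1, "rows of unequal length in motif ", id)
    counts <- do.call(cbind, lapply(rows[match(BASES, bases)],
                                    `[[`, "counts"))
    .assert(all(counts >= 0), "negative counts in motif ", id)
    p <- counts / rowSums(counts)
    colnames(p) <- BASES
    pw <- new("PWM", name = nm, prob = p,
              consensus = paste(BASES[max.col(p, ties.method = "first")],
                                collapse = ""))
    out[[nm]] <- pw
  }
  out
}
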
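#' Dinucleotide shuffle of a DNA sequence
#'
#' Uniform random Eulerian-walk shuffle (Altschul-Erickson construction):
#' the output preserves the exact dinucleotide multiset of the input — and
#' therefore its mononucleotide counts and terminal residues — while
#' destroying longer-range structure. Used to build realistic null
#' backgrounds for motif insertion.
#'
#' @param sequence a DNA sequence over A/C/G/T (length >= 2).
#' @param seed integer seed.
#' @return a shuffled sequence of the same length.
#' @export
dinucShuffle <- function(sequence, seed = 0) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(s)
  .assert(n >= 2, "sequence must be at least 2 bp for dinucleotide shuffling")
  code <- match(s, BASES)
  .assert(!anyNA(code), "sequence must be over A/C/G/T")
  with_seed(seed, {
    from <- code[-n]
    to <- code[-1]
    last <- code[n]
    verts <- sort(unique(code))
    edges <- split(to, factor(from, levels = verts)) # out-edges per vertex
    # choose a random last edge per non-terminal vertex such that the chosen
    # edges form paths leading into the terminal vertex
    lastEdge <- setNames(rep(NA_integer_, length(verts)), verts)
    repeat {
      for (v in verts) {
        if (v == last) next
        out <- edges[[as.character(v)]]
        lastEdge[as.character(v)] <- out[sample.int(length(out), 1)]
      }
      ok <- TRUE
      for (v in verts) {
        if (v == last) next
        cur <- v
        seen <- integer()
        while (cur != last) {
          if (cur %in% seen) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- lastEdge[as.character(cur)]
          if (is.na(cur)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute the remaining out-edges, append the reserved last edge
    pools <- lapply(verts, function(v) {
      out <- edges[[as.character(v)]]
      if (v != last) {
        drop1 <- match(lastEdge[as.character(v)], out)
        out <- out[-drop1]
      }
      out <- if (length(out) > 1) out[sample.int(length(out))] else out
      if (v != last) out <- c(out, lastEdge[as.character(v)])
      out
    })
    names(pools) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    walk <- integer(n)
    walk[1] <- code[1]
    for (i in 2:n) {
      v <- as.character(walk[i - 1])
      walk[i] <- pools[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
    }
    paste(BASES[walk], collapse = "")
  })
}

#' Dinucleotide count vector of a sequence
#'
#' @param sequence a DNA sequence.
#' @return named integer vector over the 16 dinucleotides.
#' @export
dinucCounts <- function(sequence) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  di <- paste0(s[-length(s)], s[-1])
  all16 <- as.vector(outer(BASES, BASES, paste0))
  table(factor(di, levels = all16))
}

#' Per-cell TF activity by motif insertion
#'
#' Backgrounds are dinucleotide shuffles of randomly sampled peak sequences;
#' each motif's consensus is inserted at the centre of every background, and
#' the influence score of a sequence is the difference in predicted
#' accessibility between the motif-inserted and background versions. The
#' per-cell activity is the mean influence across backgrounds; a per-TF
#' z-score across cells is kept alongside for display.
#'
#' @param model a trained [AccessModel].
#' @param motifs a [PWM] or list of PWMs.
#' @param peaks peak sequences (character or DNAStringSet) of the model's
#'   input length, sampled for backgrounds.
#' @param nBackground number of background sequences (>= 1).
#' @param seed integer seed.
#' @return an [ActivityResult].
#' @export
motifActivity <- function(model, motifs, peaks, nBackground = 50, seed = 0) {
  if (is(motifs, "PWM")) motifs <- list(motifs)
  .assert(length(motifs) > 0, "no motifs supplied")
  .assert(nBackground >= 1, "at least one background sequence required")
  peaks <- as.character(peaks)
  L <- model@config@inputLength
  .assert(all(nchar(peaks) == L),
          "peak sequences must match the model input length")
  for (m in motifs)
    .assert(pwmWidth(m) <= L, "motif ", m@name, " wider than the model input")
  sel <- with_seed(seed,
                   sample.int(length(peaks), nBackground,
                              replace = nBackground > length(peaks)))
  bg <- vapply(seq_along(sel),
               function(i) dinucShuffle(peaks[sel[i]], seed = seed + i), "")
  ybg <- predictAccessibility(model, oneHotEncode(bg), seed = seed)
  nm <- vapply(motifs, function(m) m@name, "")
  act <- matrix(NA_real_, length(motifs), ncol(ybg),
                dimnames = list(nm, colnames(ybg)))
  infl <- list()
  for (mi in seq_along(motifs)) {
    cons <- pwmConsensus(motifs[[mi]])
    ins <- vapply(bg, function(s) plantMotif(s, makePWM(cons)), "",
                  USE.NAMES = FALSE)
    yins <- predictAccessibility(model, oneHotEncode(ins), seed = seed)
    dif <- yins - ybg
    act[mi, ] <- colMeans(dif)
    infl[[nm[mi]]] <- dif
  }
  znorm <- t(apply(act, 1, function(r) {
    s <- sd(r)
    if (s < 1e-12) r * 0 else (r - mean(r)) / s
  }))
  new("ActivityResult", activity = act, normalized = znorm,
      influence = infl, nBackground = as.integer(nBackground),
      seed = as.integer(seed))
}

#' In-silico saturation mutagenesis of a sequence
#'
#' Every position is mutated to its three alternative nucleotides and the
#' change in predicted accessibility recorded per cell; the four scores at
#' each (position, cell) are then centred so they sum to zero (the reference
#' base's normalized score is minus the mean of the three alternatives'
#' raw changes).
#'
#' @param model a trained [AccessModel].
#' @param sequence the reference sequence (model input length).
#' @param seed integer seed for the sampled dependency measurement.
#' @return an [ISMResult].
#' @export
ismMap <- function(model, sequence, seed = 0) {
  sequence <- toupper(as.character(sequence))
  L <- model@config@inputLength
  .assert(nchar(sequence) == L,
          "sequence length must equal the model input length")
  refCh <- strsplit(sequence, "")[[1]]
  refIdx <- match(refCh, BASES)
  .assert(!anyNA(refIdx), "reference sequence must be over A/C/G/T")
  muts <- character()
  where <- list()
  for (p in seq_len(L)) {
    for (b in seq_len(4)) {
      if (b == refIdx[p]) next
      s <- sequence
      substr(s, p, p) <- BASES[b]
      muts <- c(muts, s)
      where[[length(muts)]] <- c(p, b)
    }
  }
  yref <- predictAccessibility(model, oneHotEncode(sequence), seed = seed)
  ymut <- predictAccessibility(model, oneHotEncode(muts), seed = seed)
  N <- ncol(yref)
  delta <- array(0, dim = c(L, 4, N))
  for (k in seq_along(where)) {
    pb <- where[[k]]
    delta[pb[1], pb[2], ] <- ymut[k, ] - yref[1, ]
  }
  # centre the four nucleotide scores at each (position, cell)
  mean4 <- apply(delta, c(1, 3), mean)
  for (b in seq_len(4)) delta[, b, ] <- delta[, b, ] - mean4
  new("ISMResult", scores = delta, reference = sequence)
}

#' PWM-ISM score of a motif match
#'
#' Per cell, the dot product between the PWM and the ISM scores over the
#' motif window starting at `offset`.
#'
#' @param ism an [ISMResult].
#' @param pwm a [PWM].
#' @param offset 1-based start position of the motif window.
#' @return named numeric vector, one score per cell.
#' @export
pwmIsmScore <- function(ism, pwm, offset) {
  w <- pwmWidth(pwm)
  L <- dim(ism@scores)[1]
  .assert(offset >= 1 && offset + w - 1 <= L,
          "motif window out of range for the ISM map")
  win <- ism@scores[offset:(offset + w - 1), , , drop = FALSE]
  apply(win, 3, function(m) sum(pwm@prob * m))
}
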
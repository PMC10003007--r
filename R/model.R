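#' Sinusoidal fixed absolute position embedding
#'
#' PE(pos, 2i) = sin(pos / base^(2i/d)), PE(pos, 2i+1) = cos(pos /
#' base^(2i/d)), positions 0-based.
#'
#' @param nTokens number of positions.
#' @param d embedding width (even).
#' @param base frequency base.
#' @return matrix (nTokens x d) with entries in [-1, 1].
#' @export
positionEmbedding <- function(nTokens, d, base = 10000) {
  .assert(d %% 2 == 0, "embedding width must be even")
  .cpp_position_embedding(as.integer(nTokens), as.integer(d), base)
}

#' Combine motif and position embeddings into the uniform input
#'
#' X(0) = alpha * u + PE; with position mode "none" the PE term is dropped.
#'
#' @param u motif-embedding matrix (tokens x d).
#' @param pe position-embedding matrix of the same shape, or NULL.
#' @param alpha balance factor.
#' @return the input representation matrix.
#' @export
uniformInput <- function(u, pe = NULL, alpha = 1) {
  if (is.null(pe)) return(alpha * u)
  .assert(all(dim(u) == dim(pe)), "motif and position embedding shapes differ")
  alpha * u + pe
}

#' Long-range dependency measurement of attention queries
#'
#' Scores how far each query's attention distribution is from uniform. In
#' exact mode, M(q_i, K) = logsumexp_m(s_im) - mean_m(s_im) with s =
#' QK'/sqrt(d_h) (the KL-based form, constants dropped); in sampled mode the
#' max-minus-mean surrogate is computed on ceil(L_K ln L_Q / L_Q) keys drawn
#' per query without replacement.
#'
#' @param Q,K query and key matrices with a common inner width.
#' @param mode `"exact"` or `"sampled"`.
#' @param seed integer seed (sampled mode).
#' @return numeric vector, one measurement per query.
#' @export
sparsityMeasurement <- function(Q, K, mode = c("exact", "sampled"),
                                seed = 0) {
  mode <- match.arg(mode)
  .assert(ncol(Q) == ncol(K), "Q and K must share their inner width")
  .assert(nrow(K) > 0, "empty key matrix")
  as.numeric(.cpp_sparsity_measurement(Q, K, mode == "exact",
                                       as.integer(seed)))
}

#' Probability-sparse self-attention
#'
#' Only the u = ceil(c ln L_Q) queries with the largest long-range dependency
#' measurement attend to the keys through softmax(QK'/sqrt(d_h))V; the
#' remaining query rows receive the column mean of V (the softmax of
#' all-zero scores).
#'
#' @param Q,K,V query, key and value matrices (K and V with equal rows).
#' @param c sampling factor controlling u.
#' @param mode measurement mode, `"exact"` or `"sampled"`.
#' @param seed integer seed (sampled mode).
#' @return attention output matrix (rows of Q x columns of V).
#' @seealso [denseAttention()] for the dense reference.
#' @export
probDepAttention <- function(Q, K, V, c = 5, mode = c("exact", "sampled"),
                             seed = 0) {
  mode <- match.arg(mode)
  .assert(nrow(Q) > 0, "empty query matrix")
  .assert(nrow(K) == nrow(V), "K and V must have the same number of rows")
  .cpp_probdep_attention(Q, K, V, c, mode == "exact", as.integer(seed))
}

#' Dense softmax attention (reference implementation)
#'
#' Plain softmax(QK'/sqrt(d_h))V with no sparsity, written in R as an
#' independent reference for the probability-sparse implementation.
#'
#' @param Q,K,V query, key and value matrices.
#' @return attention output matrix.
#' @export
denseAttention <- function(Q, K, V) {
  s <- Q %*% t(K) / sqrt(ncol(Q))
  s <- s - apply(s, 1, max)
  p <- exp(s) / rowSums(exp(s))
  p %*% V
}

#' Binary cross-entropy loss
#'
#' Cell-averaged negated binary cross-entropy,
#' -(1/N) sum(y log p + (1 - y) log(1 - p)), with probabilities clipped at
#' 1e-7; always non-negative.
#'
#' @param prob predicted probabilities in (0, 1).
#' @param label binary labels of the same length.
#' @return scalar loss.
#' @export
bceLoss <- function(prob, label) {
  .assert(length(prob) == length(label),
          "prediction and label lengths differ")
  .assert(all(label %in% c(0, 1)), "labels must be binary")
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

#' Train the accessibility model
#'
#' Adam optimisation of the binary cross-entropy over peaks, with early
#' stopping once the validation loss has not improved for `config@patience`
#' epochs; the best-validation weights are restored.
#'
#' Accessibility labels have very low base rates, and whether the first
#' convolution discovers motif features before the optimiser settles into a
#' bias-only plateau depends on the initialisation draw. Training therefore
#' runs a short probe phase first: if the validation loss has not improved
#' by `probeGain` (relative) after `probeEpochs` epochs, the model is
#' reinitialised with a derived seed, up to `restarts` times (all
#' deterministic given `config@seed`). The best probe is then trained to
#' completion. Set `restarts = 0` for the plain single-run protocol.
#'
#' @param batch a [OneHotBatch] of peak sequences (length must match the
#'   config input length).
#' @param labels binary peaks x cells matrix aligned with `batch` (rows) —
#'   e.g. the assay of a binarized [PeakCellMatrix].
#' @param config a [ModelConfig]; `nCells` must equal `ncol(labels)`.
#' @param trainIdx,valIdx row indices of the training and validation peaks;
#'   by default a seeded 90/10 split.
#' @param restarts maximum number of probe-phase reinitialisations.
#' @param probeEpochs,probeGain length of the probe phase and the relative
#'   validation-loss improvement it must reach.
#' @param verbose print per-epoch losses.
#' @return a trained [AccessModel].
#' @export
trainAccessModel <- function(batch, labels, config, trainIdx = NULL,
                             valIdx = NULL, restarts = 3, probeEpochs = 12,
                             probeGain = 0.04, verbose = FALSE) {
  labels <- as.matrix(labels)
  enc <- batch@encoding
  .assert(dim(enc)[1] == config@inputLength,
          "sequence length ", dim(enc)[1],
          " does not match config input length ", config@inputLength)
  .assert(nrow(labels) == dim(enc)[3],
          "one label row per sequence required")
  .assert(ncol(labels) == config@nCells,
          "label columns must equal config nCells")
  .assert(all(labels %in% c(0, 1)), "labels must be binarized")
  n <- nrow(labels)
  if (is.null(trainIdx) || is.null(valIdx)) {
    perm <- with_seed(config@seed, sample.int(n))
    nVal <- max(1L, round(0.1 * n))
    valIdx <- sort(perm[seq_len(nVal)])
    trainIdx <- sort(perm[-seq_len(nVal)])
  }
  .assert(length(trainIdx) > 0, "empty training set")
  cfgl <- config_as_list(config)
  Xtr <- enc[, , trainIdx, drop = FALSE]
  Ytr <- labels[trainIdx, , drop = FALSE]
  Xval <- enc[, , valIdx, drop = FALSE]
  Yval <- labels[valIdx, , drop = FALSE]

  probe <- min(probeEpochs, config@maxEpochs)
  fit <- NULL
  probeHist <- NULL
  if (restarts > 0 && probe >= 3 && config@maxEpochs > probe) {
    best <- NULL
    for (attempt in 0:restarts) {
      seedA <- config@seed + attempt * 1000L
      pa <- initParameters(config, seed = seedA)
      fa <- .cpp_train(pa, cfgl, Xtr, Ytr, Xval, Yval,
                       config@learningRate, config@batchSize, probe,
                       probe, seedA, verbose)
      ref <- fa$val_loss[2] # bias-only plateau level
      if (is.null(best) || fa$best_val < best$fit$best_val)
        best <- list(fit = fa, seed = seedA)
      if (fa$best_val < (1 - probeGain) * ref) {
        best <- list(fit = fa, seed = seedA)
        break
      }
    }
    probeHist <- data.frame(train_loss = best$fit$train_loss,
                            val_loss = best$fit$val_loss)
    fit <- .cpp_train(best$fit$params, cfgl, Xtr, Ytr, Xval, Yval,
                      config@learningRate, config@batchSize,
                      config@patience,
                      config@maxEpochs - nrow(probeHist),
                      best$seed + 1L, verbose)
  } else {
    params <- initParameters(config)
    fit <- .cpp_train(params, cfgl, Xtr, Ytr, Xval, Yval,
                      config@learningRate, config@batchSize,
                      config@patience, config@maxEpochs, config@seed,
                      verbose)
  }
  cells <- colnames(labels)
  if (is.null(cells)) cells <- paste0("cell_", seq_len(config@nCells))
  hist <- data.frame(train_loss = c(probeHist$train_loss, fit$train_loss),
                     val_loss = c(probeHist$val_loss, fit$val_loss))
  hist <- data.frame(epoch = seq_len(nrow(hist)), hist)
  new("AccessModel", params = fit$params, config = config,
      cellNames = cells, history = hist, trained = TRUE)
}

#' @rdname predictAccessibility
#' @param seed integer seed for the sampled dependency measurement (ignored
#'   in exact mode).
setMethod("predictAccessibility", "AccessModel",
          function(object, batch, seed = 0L) {
  out <- .cpp_predict(object@params, config_as_list(object@config),
                      batch@encoding, as.integer(seed))
  y <- out$y
  dimnames(y) <- list(batch@ids, object@cellNames)
  y
})

#' Sequence embeddings Z for a batch of peaks
#'
#' @param object a trained [AccessModel].
#' @param batch a [OneHotBatch].
#' @param seed integer seed for the sampled dependency measurement.
#' @return matrix (peaks x embedding size).
#' @export
sequenceEmbeddings <- function(object, batch, seed = 0L) {
  out <- .cpp_predict(object@params, config_as_list(object@config),
                      batch@encoding, as.integer(seed))
  z <- out$z
  rownames(z) <- batch@ids
  z
}

#' @rdname cellEmbeddings
setMethod("cellEmbeddings", "AccessModel", function(object) {
  .assert(object@trained, "model has not been trained")
  e <- t(object@params$Wp)
  rownames(e) <- object@cellNames
  e
})

#' @rdname cellDepth
setMethod("cellDepth", "AccessModel", function(object) {
  .assert(object@trained, "model has not been trained")
  setNames(as.numeric(object@params$bp), object@cellNames)
})

#' @rdname trainingHistory
setMethod("trainingHistory", "AccessModel", function(object) object@history)

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation; NA when only one class is present.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels.
#' @return scalar auROC in [0, 1], or NA.
#' @export
aurocScore <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean per-cell auROC of an accessibility prediction
#'
#' auROC is computed cell by cell over peaks and averaged across cells that
#' have at least one positive and one negative label.
#'
#' @param prob peaks x cells prediction matrix.
#' @param labels peaks x cells binary matrix.
#' @return mean auROC.
#' @export
meanCellAuroc <- function(prob, labels) {
  .assert(all(dim(prob) == dim(labels)), "shape mismatch")
  per <- vapply(seq_len(ncol(prob)),
                function(j) aurocScore(prob[, j], labels[, j]), 0)
  mean(per, na.rm = TRUE)
}
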
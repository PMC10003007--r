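#' Create an accessibility-model configuration
#'
#' Defaults follow the published training protocol where one is stated
#' (mini-batch 16, learning rate 1e-3, early-stopping patience 5, sinusoidal
#' fixed absolute position embedding) and sensible desk-scale values where
#' the architecture width is unstated.
#'
#' @param nCells number of cells the model predicts (output units).
#' @param inputLength input sequence length L in bp.
#' @param embedDim token embedding width d (even, divisible by `heads`).
#' @param heads attention heads.
#' @param layers encoder layers; every layer but the last halves the token
#'   axis with self-attention pooling.
#' @param ffDim feed-forward width.
#' @param stemKernel,convKernel,headKernel odd convolution kernel widths.
#' @param headFilters sequence-embedder convolution filters.
#' @param embeddingSize sequence/cell embedding width.
#' @param stemThreshold token count above which the input stem alternates
#'   convolution and pooling (long-input variant).
#' @param poolWidth pooling width and stride.
#' @param alpha balance factor between motif and position embedding.
#' @param peBase sinusoidal position-embedding base.
#' @param samplingFactor factor c in u = ceil(c ln L): how many dominant
#'   queries receive full attention.
#' @param positionMode `"fixed_absolute"` or `"none"` (ablation switch).
#' @param measureMode `"exact"` or `"sampled"` long-range dependency
#'   measurement.
#' @param learningRate,batchSize,patience,maxEpochs,seed training protocol.
#' @return a [ModelConfig].
#' @export
modelConfig <- function(nCells, inputLength = 1344, embedDim = 128,
                        heads = 8, layers = 2, ffDim = 256,
                        stemKernel = 13, convKernel = 5, headKernel = 5,
                        headFilters = 8, embeddingSize = 32,
                        stemThreshold = 5000, poolWidth = 2, alpha = 1,
                        peBase = 10000, samplingFactor = 5,
                        positionMode = "fixed_absolute",
                        measureMode = "sampled", learningRate = 0.001,
                        batchSize = 16, patience = 5, maxEpochs = 100,
                        seed = 0) {
  new("ModelConfig", inputLength = as.integer(inputLength),
      embedDim = as.integer(embedDim), heads = as.integer(heads),
      layers = as.integer(layers), ffDim = as.integer(ffDim),
      stemKernel = as.integer(stemKernel),
      convKernel = as.integer(convKernel),
      headKernel = as.integer(headKernel),
      headFilters = as.integer(headFilters),
      embeddingSize = as.integer(embeddingSize),
      nCells = as.integer(nCells),
      stemThreshold = as.integer(stemThreshold),
      poolWidth = as.integer(poolWidth), alpha = alpha, peBase = peBase,
      samplingFactor = samplingFactor, positionMode = positionMode,
      measureMode = measureMode, learningRate = learningRate,
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      maxEpochs = as.integer(maxEpochs), seed = as.integer(seed))
}

#' Model configuration used for the bundled simulation study
#'
#' The desk-scale configuration trained on [simulateAccessibility()]
#' datasets throughout the package's tests and documentation: 2 encoder
#' layers of width 48 with 4 heads, feed-forward width 96, 32-dimensional
#' embeddings, 13-bp stem kernel, magnitude balance alpha = 3, sampled
#' dependency measurement with c = 5, and the published training protocol
#' (Adam, batch 16, learning rate 1e-3, patience 5).
#'
#' @param nCells number of cells (600 for the default simulated design).
#' @param inputLength peak length in bp.
#' @param seed training seed.
#' @return a [ModelConfig].
#' @export
simulationStudyConfig <- function(nCells = 600, inputLength = 300,
                                  seed = 1) {
  modelConfig(nCells = nCells, inputLength = inputLength, embedDim = 48,
              heads = 4, layers = 2, ffDim = 96, stemKernel = 13,
              convKernel = 5, headKernel = 5, headFilters = 8,
              embeddingSize = 32, samplingFactor = 5,
              measureMode = "sampled", alpha = 3, maxEpochs = 40,
              seed = seed)
}

config_as_list <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}

#' Token geometry implied by a configuration
#'
#' How the input stem and the encoder layers shorten the token axis: number
#' of stem conv+pool stages, tokens entering each encoder layer, and tokens
#' at the encoder output.
#'
#' @param config a [ModelConfig].
#' @return list with `stemStages`, `Ltok`, `tokensPerLayer`, `Llast`.
#' @export
tokenGeometry <- function(config) .cpp_geometry(config_as_list(config))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise model parameters for a configuration
#'
#' Glorot-uniform weights, zero biases; reproducible under the given seed.
#'
#' @param config a [ModelConfig].
#' @param seed integer seed (defaults to the config seed).
#' @return named list of parameter matrices/vectors.
#' @export
initParameters <- function(config, seed = config@seed) {
  g <- tokenGeometry(config)
  d <- config@embedDim
  with_seed(seed, {
    p <- list()
    nStem <- max(1L, g$stemStages)
    for (s in seq_len(nStem)) {
      cin <- if (s == 1) 4L else d
      p[[paste0("stem_W", s)]] <- glorot(config@stemKernel * cin, d)
      p[[paste0("stem_b", s)]] <- numeric(d)
    }
    for (l in seq_len(config@layers)) {
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(w, l)]] <- glorot(d, d)
      for (b in c("bq", "bk", "bv", "bo"))
        p[[paste0(b, l)]] <- numeric(d)
      p[[paste0("W1", l)]] <- glorot(d, config@ffDim)
      p[[paste0("b1", l)]] <- numeric(config@ffDim)
      p[[paste0("W2", l)]] <- glorot(config@ffDim, d)
      p[[paste0("b2", l)]] <- numeric(d)
      p[[paste0("g1", l)]] <- rep(1, d)   # layer-norm gains/offsets
      p[[paste0("h1", l)]] <- numeric(d)
      p[[paste0("g2", l)]] <- rep(1, d)
      p[[paste0("h2", l)]] <- numeric(d)
      p[[paste0("Wc", l)]] <- glorot(config@convKernel * d, d)
      p[[paste0("bc", l)]] <- numeric(d)
    }
    p$head_Wc <- glorot(config@headKernel * d, config@headFilters)
    p$head_bc <- numeric(config@headFilters)
    flat <- g$Llast * config@headFilters
    p$Wf <- glorot(flat, config@embeddingSize)
    p$bf <- numeric(config@embeddingSize)
    p$Wp <- glorot(config@embeddingSize, config@nCells)
    p$bp <- numeric(config@nCells)
    p
  })
}
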
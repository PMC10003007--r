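#' PeakCellMatrix: peak-by-cell accessibility container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' non-negative peaks x cells matrix in the `"counts"` assay, with peak
#' identifiers as rownames, cell identifiers as colnames and an optional
#' `cell_type` column in `colData`.
#'
#' @aliases PeakCellMatrix-class
#' @exportClass PeakCellMatrix
setClass("PeakCellMatrix", contains = "SummarizedExperiment")

setValidity("PeakCellMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "peak identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell identifiers must be present and unique")
  if (length(msg)) msg else TRUE
})

#' OneHotBatch: one-hot encoded peak sequences
#'
#' Fixed-length sequences encoded position x channel (A, C, G, T) x sequence.
#' Every position row sums to one; ambiguous bases (N) are encoded as 0.25
#' in each channel so the per-position mass stays 1.
#'
#' @slot encoding numeric array of dim (L, 4, n sequences).
#' @slot ids character vector of per-sequence (peak) identifiers.
#' @exportClass OneHotBatch
setClass("OneHotBatch",
         representation(encoding = "array", ids = "character"))

setValidity("OneHotBatch", function(object) {
  d <- dim(object@encoding)
  if (length(d) != 3 || d[2] != 4)
    return("encoding must be an (L, 4, n) array")
  if (length(object@ids) != d[3])
    return("one id per sequence required")
  rs <- apply(object@encoding, c(1, 3), sum)
  if (max(abs(rs - 1)) > 1e-6)
    return("each position must carry unit mass across the four channels")
  TRUE
})

#' ModelConfig: hyperparameters of the accessibility encoder
#'
#' @slot inputLength sequence length L in bp.
#' @slot embedDim token embedding width d (even; heads must divide it).
#' @slot heads number of attention heads.
#' @slot layers number of encoder layers.
#' @slot ffDim width of the position-wise feed-forward layer.
#' @slot stemKernel,convKernel,headKernel odd convolution kernel widths for
#'   the input stem, the per-layer convolution and the sequence embedder.
#' @slot headFilters filters of the sequence-embedder convolution.
#' @slot embeddingSize width of the sequence embedding Z (and of the cell
#'   embedding).
#' @slot nCells number of cells (output units).
#' @slot stemThreshold token count above which the stem alternates
#'   convolution and pooling to shorten the sequence.
#' @slot poolWidth pooling width/stride.
#' @slot alpha balance factor between motif embedding and position embedding.
#' @slot peBase base of the sinusoidal position embedding.
#' @slot samplingFactor factor c controlling how many dominant queries
#'   (u = ceil(c ln L)) receive full attention.
#' @slot positionMode `"fixed_absolute"` or `"none"`.
#' @slot measureMode `"exact"` (closed-form dependency measurement) or
#'   `"sampled"` (max-minus-mean surrogate on sampled query-key pairs).
#' @slot learningRate,batchSize,patience,maxEpochs,seed training protocol.
#' @exportClass ModelConfig
setClass("ModelConfig",
         representation(inputLength = "integer", embedDim = "integer",
                        heads = "integer", layers = "integer",
                        ffDim = "integer", stemKernel = "integer",
                        convKernel = "integer", headKernel = "integer",
                        headFilters = "integer", embeddingSize = "integer",
                        nCells = "integer", stemThreshold = "integer",
                        poolWidth = "integer", alpha = "numeric",
                        peBase = "numeric", samplingFactor = "numeric",
                        positionMode = "character", measureMode = "character",
                        learningRate = "numeric", batchSize = "integer",
                        patience = "integer", maxEpochs = "integer",
                        seed = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@embedDim %% 2L != 0L)
    msg <- c(msg, "embedDim must be even (sin/cos pairing)")
  if (object@embedDim %% object@heads != 0L)
    msg <- c(msg, "heads must divide embedDim")
  if (object@samplingFactor < 1)
    msg <- c(msg, "samplingFactor must be >= 1")
  for (k in c("stemKernel", "convKernel", "headKernel"))
    if (slot(object, k) %% 2L != 1L)
      msg <- c(msg, paste(k, "must be odd (same padding)"))
  if (!object@positionMode %in% c("fixed_absolute", "none"))
    msg <- c(msg, "positionMode must be 'fixed_absolute' or 'none'")
  if (!object@measureMode %in% c("exact", "sampled"))
    msg <- c(msg, "measureMode must be 'exact' or 'sampled'")
  if (object@inputLength < object@stemKernel)
    msg <- c(msg, "inputLength must be at least the stem kernel width")
  if (length(msg)) msg else TRUE
})

#' AccessModel: a (possibly trained) accessibility encoder
#'
#' @slot params named list of parameter matrices and vectors.
#' @slot config the [ModelConfig] the parameters were built for.
#' @slot cellNames cell identifiers, one per output unit.
#' @slot history per-epoch train/validation loss.
#' @slot trained whether [trainAccessModel()] has been run.
#' @exportClass AccessModel
setClass("AccessModel",
         representation(params = "list", config = "ModelConfig",
                        cellNames = "character", history = "data.frame",
                        trained = "logical"))

setValidity("AccessModel", function(object) {
  wp <- object@params[["Wp"]]
  if (!is.null(wp) && ncol(wp) != length(object@cellNames))
    return("Wp column count must equal the number of cells")
  bp <- object@params[["bp"]]
  if (!is.null(bp) && any(!is.finite(bp)))
    return("depth intercepts must be finite")
  TRUE
})

#' PWM: position probability matrix of a TF binding motif
#'
#' @slot name motif identifier.
#' @slot prob matrix (width x 4, columns A, C, G, T) of per-position base
#'   probabilities; rows sum to 1.
#' @slot consensus consensus sequence (argmax base per position).
#' @exportClass PWM
setClass("PWM",
         representation(name = "character", prob = "matrix",
                        consensus = "character"))

setValidity("PWM", function(object) {
  p <- object@prob
  if (ncol(p) != 4) return("prob must have 4 columns (A, C, G, T)")
  if (nrow(p) < 4) return("motif width must be >= 4")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (max(abs(rowSums(p) - 1)) > 1e-9) return("rows must sum to 1")
  TRUE
})

#' SyntheticDataset: simulated scATAC-seq data with known ground truth
#'
#' @slot sequences peak sequences (DNAStringSet).
#' @slot counts [PeakCellMatrix] of observed continuous counts (truncated
#'   Normal where a truly accessible site was detected, Gamma noise
#'   elsewhere).
#' @slot binary peaks x cells 0/1 detection matrix (exactly 0 wherever an
#'   accessible site dropped out); the training labels.
#' @slot truth peaks x cells clean binary accessibility ground truth.
#' @slot dropout peaks x cells logical: accessible sites lost to dropout.
#' @slot cellTypes factor of true cell-type labels.
#' @slot motifTable per-peak motif assignment (peak, motif, position).
#' @slot design the generator settings used.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(sequences = "DNAStringSet", counts = "PeakCellMatrix",
                        binary = "matrix", truth = "matrix",
                        dropout = "matrix", cellTypes = "factor",
                        motifTable = "data.frame", design = "list"))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (!all(object@truth %in% c(0, 1)))
    msg <- c(msg, "truth entries must be binary")
  if (any(object@binary[object@dropout > 0] != 0))
    msg <- c(msg, "binary matrix must be zero wherever dropout mask is 1")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: community labels from graph clustering
#'
#' @slot membership integer community id per cell, contiguous from 0.
#' @slot modularity modularity of the partition.
#' @slot resolution,seed clustering settings.
#' @slot cellNames cell identifiers.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
         representation(membership = "integer", modularity = "numeric",
                        resolution = "numeric", seed = "integer",
                        cellNames = "character"))

setValidity("ClusterAssignment", function(object) {
  ids <- sort(unique(object@membership))
  if (length(ids) && !identical(ids, 0:(length(ids) - 1L)))
    return("community ids must be contiguous from 0")
  if (length(object@cellNames) &&
      length(object@cellNames) != length(object@membership))
    return("one membership per cell required")
  TRUE
})

#' MixtureFit: per-peak, per-cluster Gamma-Normal dropout mixtures
#'
#' For every (peak, cluster) stratum with enough cells, the maximum-likelihood
#' two-component model: dropout weight lambda on a Gamma(shape, rate) noise
#' component and (1 - lambda) on a Normal(mean, sd) bona fide signal
#' component, fitted by EM.
#'
#' @slot fits data.frame with one row per (peak, cluster) stratum: `peak`,
#'   `cluster`, `lambda`, `shape`, `rate`, `mu`, `sigma`, `loglik`, `iter`,
#'   `converged`, `fitted`.
#' @slot clusterOf integer cluster id per cell (0-based).
#' @slot peakNames,cellNames identifiers.
#' @slot pseudoCount value substituted for zero counts before density
#'   evaluation (Gamma support is x > 0).
#' @slot loglikTrace per-cluster trace of the summed observed-data
#'   log-likelihood across EM iterations (non-decreasing).
#' @exportClass MixtureFit
setClass("MixtureFit",
         representation(fits = "data.frame", clusterOf = "integer",
                        peakNames = "character", cellNames = "character",
                        pseudoCount = "numeric", loglikTrace = "list"))

#' DenoisedMatrix: dropout-recovered peak-by-cell matrix
#'
#' @slot matrix recovered peaks x cells matrix; equal to the input wherever
#'   the recovery mask is 0.
#' @slot mask logical peaks x cells: entries replaced by the model-predicted
#'   candidate.
#' @slot threshold dropout-probability threshold T used.
#' @exportClass DenoisedMatrix
setClass("DenoisedMatrix",
         representation(matrix = "matrix", mask = "matrix",
                        threshold = "numeric"))

#' ActivityResult: per-cell TF activity from motif insertion
#'
#' @slot activity TFs x cells matrix of raw activity scores (mean influence
#'   across background sequences).
#' @slot normalized per-TF z-scored activity across cells (display scale).
#' @slot influence list (per TF) of background x cells influence scores.
#' @slot nBackground,seed motif-insertion settings.
#' @exportClass ActivityResult
setClass("ActivityResult",
         representation(activity = "matrix", normalized = "matrix",
                        influence = "list", nBackground = "integer",
                        seed = "integer"))

#' ISMResult: in-silico saturation mutagenesis scores
#'
#' @slot scores array (position, nucleotide A/C/G/T, cell) of normalized
#'   accessibility changes; the four scores at each (position, cell) sum to
#'   zero.
#' @slot reference the reference sequence that was mutated.
#' @exportClass ISMResult
setClass("ISMResult",
         representation(scores = "array", reference = "character"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "OneHotBatch", function(object) {
  d <- dim(object@encoding)
  cat("OneHotBatch:", d[3], "sequences of", d[1], "bp\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: L =", object@inputLength,
      "| d =", object@embedDim, "x", object@layers, "layers,",
      object@heads, "heads | embedding", object@embeddingSize,
      "| cells", object@nCells, "\n")
  cat("  attention: c =", object@samplingFactor,
      paste0("(", object@measureMode, " measurement),"),
      "position:", object@positionMode, "\n")
})

setMethod("show", "AccessModel", function(object) {
  cat("AccessModel (", if (object@trained) "trained" else "untrained",
      "): ", length(object@cellNames), " cells, embedding ",
      object@config@embeddingSize, "\n", sep = "")
  if (nrow(object@history))
    cat("  ", nrow(object@history), " epochs; best val loss ",
        signif(min(object@history$val_loss), 4), "\n", sep = "")
})

setMethod("show", "PWM", function(object) {
  cat("PWM", object@name, "width", nrow(object@prob),
      "consensus", object@consensus, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@sequences), "peaks x",
      length(object@cellTypes), "cells (",
      nlevels(object@cellTypes), "cell types )\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@membership), "cells in",
      length(unique(object@membership)), "communities; modularity",
      signif(object@modularity, 4), "\n")
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit:", nrow(object@fits), "strata,",
      sum(object@fits$fitted), "fitted\n")
})

setMethod("show", "DenoisedMatrix", function(object) {
  cat("DenoisedMatrix:", nrow(object@matrix), "x", ncol(object@matrix),
      "|", sum(object@mask), "entries recovered (T =", object@threshold,
      ")\n")
})

setMethod("show", "ActivityResult", function(object) {
  cat("ActivityResult:", nrow(object@activity), "motifs x",
      ncol(object@activity), "cells (", object@nBackground,
      "backgrounds )\n")
})

setMethod("show", "ISMResult", function(object) {
  d <- dim(object@scores)
  cat("ISMResult:", d[1], "positions x 4 nucleotides x", d[3], "cells\n")
})
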
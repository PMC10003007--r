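#' Binarize accessibility values
#'
#' Converts counts to a binary accessible indicator: entries strictly greater
#' than `threshold` become 1, all others 0. The input object is never
#' modified.
#'
#' @param x a numeric matrix or [PeakCellMatrix].
#' @param threshold detection threshold; the default 0 reproduces the usual
#'   "any signal counts as accessible" rule for integer count matrices.
#' @return an object of the same class as `x` with binary entries.
#' @export
setGeneric("binarize", function(x, threshold = 0) standardGeneric("binarize"))

#' Extract cell embeddings from a trained accessibility model
#'
#' The weight matrix of the final per-cell linear layer, transposed to
#' cells x embedding dimensions. Each row describes how strongly that cell's
#' accessibility loads on each learned sequence feature.
#'
#' @param object a trained [AccessModel].
#' @return numeric matrix (cells x embedding size) with cell names as
#'   rownames.
#' @export
setGeneric("cellEmbeddings", function(object) standardGeneric("cellEmbeddings"))

#' Per-cell depth intercepts of a trained accessibility model
#'
#' The intercept vector of the final linear layer, interpretable as the
#' sequencing depth of each cell.
#'
#' @param object a trained [AccessModel].
#' @return named numeric vector, one value per cell.
#' @export
setGeneric("cellDepth", function(object) standardGeneric("cellDepth"))

#' Predict per-cell accessibility probabilities for peak sequences
#'
#' @param object a trained [AccessModel].
#' @param batch a [OneHotBatch] of encoded peak sequences.
#' @param ... further arguments passed to methods.
#' @return numeric matrix (peaks x cells) of probabilities in (0, 1).
#' @export
setGeneric("predictAccessibility",
           function(object, batch, ...) standardGeneric("predictAccessibility"))

#' Per-epoch training history of a fitted model
#'
#' @param object a trained [AccessModel].
#' @return data.frame with columns `epoch`, `train_loss`, `val_loss`.
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))
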
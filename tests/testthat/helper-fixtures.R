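# shared fixtures; heavy objects are built lazily and cached across files
.fx <- new.env(parent = emptyenv())

fx_dataset <- function() {
  if (is.null(.fx$ds)) .fx$ds <- simulateAccessibility(seed = 11)
  .fx$ds
}

fx_split <- function() {
  if (is.null(.fx$sp)) {
    sp <- splitPeaks(seq_len(1000), c(0.7, 0.1, 0.2), seed = 11)
    .fx$sp <- attr(sp, "indices")
  }
  .fx$sp
}

fx_batch <- function() {
  if (is.null(.fx$batch)) .fx$batch <- oneHotEncode(fx_dataset()@sequences)
  .fx$batch
}

fx_model <- function(seed = 1) {
  key <- paste0("model", seed)
  if (is.null(.fx[[key]])) {
    idx <- fx_split()
    .fx[[key]] <- trainAccessModel(fx_batch(), fx_dataset()@binary,
                                   simulationStudyConfig(seed = seed),
                                   trainIdx = idx$train, valIdx = idx$val)
  }
  .fx[[key]]
}

fx_planted_pwms <- function() {
  lapply(c("TGATAAGGTC", "CACGTGACCT", "TTCCGGAAGT"), makePWM,
         matchProb = 0.9)
}

fx_decoy_pwms <- function() {
  lapply(1:5, function(i) makePWM(generateBackground(10, 1, seed = 900 + i),
                                  name = paste0("decoy", i)))
}

# a tiny untrained model with deterministic parameters, for shape/algebra
# tests that do not need learning
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(nCells = 5, inputLength = 16, embedDim = 8, heads = 2,
         layers = 2, ffDim = 10, stemKernel = 3, convKernel = 3,
         headKernel = 3, headFilters = 3, embeddingSize = 4,
         samplingFactor = 50, measureMode = "exact"),
    list(...))
  do.call(modelConfig, args)
}

tiny_model <- function(config = tiny_config(), seed = 4) {
  p <- initParameters(config, seed = seed)
  new("AccessModel", params = p, config = config,
      cellNames = paste0("c", seq_len(config@nCells)),
      history = data.frame(), trained = TRUE)
}

random_onehot <- function(L, n, seed = 1) {
  seqs <- generateBackground(L, n, seed = seed)
  oneHotEncode(seqs)
}
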
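#' Fit per-peak, per-cluster Gamma-Normal dropout mixtures by EM
#'
#' For every peak and every cell cluster, models the counts as
#' lambda * Gamma(shape, rate) + (1 - lambda) * Normal(mu, sigma): the Gamma
#' component absorbs dropout/noise counts near zero, the Normal component
#' the bona fide signal. Parameters are estimated by EM (exact weighted
#' M-steps; the Gamma shape by Newton iteration on the weighted
#' log-likelihood), so the observed-data log-likelihood is non-decreasing.
#'
#' Zero counts are replaced by `pseudoCount` before density evaluation
#' (Gamma support is x > 0). The EM is initialised from a split at
#' `dropoutCeiling`, anchoring the Gamma component to the near-zero counts
#' where dropouts live; pure-signal strata therefore converge to lambda ~ 0
#' instead of an arbitrary half-half split.
#'
#' Strata are flagged unfitted (and never recovered downstream) when they
#' have fewer than `minCells` cells, are constant, end with a collapsed
#' Normal component (effective weight < `minNormalN` cells or sigma at the
#' floor), end with a Normal component that is not separated from the
#' dropout regime (mu - `minSeparation` * sigma below `dropoutCeiling` — the
#' signature of the Normal latching onto the upper tail of pure noise in a
#' closed stratum), or when lambda ends at/above `lambdaMax`. A lambda near
#' 0 (pure signal) remains a valid fit.
#'
#' @param counts a [PeakCellMatrix] or peaks x cells matrix of non-negative
#'   counts.
#' @param clusters a [ClusterAssignment] or integer vector of per-cell
#'   cluster ids.
#' @param minCells minimum cells per stratum (default 20).
#' @param pseudoCount substitute for zero counts (default 0.1).
#' @param maxIter,tol EM iteration cap and absolute log-likelihood tolerance.
#' @param dropoutCeiling count level separating the dropout regime from the
#'   signal regime, used only for initialisation and configurable for other
#'   count scales.
#' @param shapeMax upper clamp on the Gamma shape (keeps the noise component
#'   from mimicking a narrow Normal).
#' @param sigmaMin lower floor on sigma.
#' @param lambdaMax dropout-weight ceiling above which a stratum is treated
#'   as closed.
#' @param minNormalN minimum effective cell count of the Normal component.
#' @param minSeparation required separation (in sigmas) between the Normal
#'   mean and the dropout regime.
#' @return a [MixtureFit].
#' @export
fitMixture <- function(counts, clusters, minCells = 20, pseudoCount = 0.1,
                       maxIter = 500, tol = 1e-6, dropoutCeiling = 2,
                       shapeMax = 100, sigmaMin = 1e-3, lambdaMax = 0.9,
                       minNormalN = 3, minSeparation = 2) {
  X <- if (is(counts, "PeakCellMatrix"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  .assert(all(X >= 0), "counts must be non-negative")
  cl <- if (is(clusters, "ClusterAssignment")) clusters@membership
        else as.integer(clusters)
  .assert(length(cl) == ncol(X), "one cluster id per cell required")
  P <- nrow(X)
  ids <- sort(unique(cl))
  res <- list()
  traces <- list()
  for (k in ids) {
    cells <- which(cl == k)
    n <- length(cells)
    df <- data.frame(peak = seq_len(P), cluster = k, lambda = NA_real_,
                     shape = NA_real_, rate = NA_real_, mu = NA_real_,
                     sigma = NA_real_, loglik = NA_real_, iter = 0L,
                     converged = FALSE, fitted = FALSE)
    if (n >= minCells) {
      x <- X[, cells, drop = FALSE]
      x[x == 0] <- pseudoCount
      fit <- em_gamma_normal(x, maxIter, tol, dropoutCeiling, shapeMax,
                             sigmaMin)
      ok <- fit$sds > 0 & is.finite(fit$lambda) & is.finite(fit$mu) &
        is.finite(fit$sigma) & is.finite(fit$shape) & is.finite(fit$rate) &
        fit$normalN >= minNormalN & fit$sigma > sigmaMin &
        fit$lambda < lambdaMax &
        fit$mu - minSeparation * fit$sigma >= dropoutCeiling
      df$lambda <- fit$lambda; df$shape <- fit$shape; df$rate <- fit$rate
      df$mu <- fit$mu; df$sigma <- fit$sigma; df$loglik <- fit$loglik
      df$iter <- fit$iter; df$converged <- fit$converged
      df$fitted <- ok
      traces[[as.character(k)]] <- fit$trace
    }
    res[[as.character(k)]] <- df
  }
  fits <- do.call(rbind, res)
  rownames(fits) <- NULL
  new("MixtureFit", fits = fits, clusterOf = cl,
      peakNames = if (is.null(rownames(X)))
        paste0("peak_", seq_len(P)) else rownames(X),
      cellNames = if (is.null(colnames(X)))
        paste0("cell_", seq_len(ncol(X))) else colnames(X),
      pseudoCount = pseudoCount, loglikTrace = traces)
}

# vectorised EM across the rows of a (peaks x cells-in-cluster) matrix
em_gamma_normal <- function(x, maxIter, tol, dropoutCeiling, shapeMax,
                            sigmaMin) {
  P <- nrow(x); n <- ncol(x)
  sds <- apply(x, 1, sd)
  logx <- log(x)

  low <- x <= dropoutCeiling
  nLow <- rowSums(low)
  lambda <- pmin(pmax(nLow / n, 0.02), 0.98)
  mLow <- rowSums(x * low) / pmax(nLow, 1)
  vLow <- rowSums((x - mLow)^2 * low) / pmax(nLow, 1)
  shape <- ifelse(nLow >= 2 & vLow > 1e-12,
                  pmin(pmax(mLow^2 / vLow, 0.05), shapeMax), 2)
  rate <- ifelse(nLow >= 2 & mLow > 1e-12, shape / pmax(mLow, 1e-12), 2)
  nHigh <- n - nLow
  mu <- ifelse(nHigh > 0, rowSums(x * !low) / pmax(nHigh, 1),
               rowMeans(x))
  sigma <- pmax(ifelse(nHigh > 1,
                       sqrt(rowSums((x - mu)^2 * !low) / pmax(nHigh, 1)),
                       sds), sigmaMin, na.rm = TRUE)

  ll <- rep(-Inf, P)
  converged <- rep(FALSE, P)
  normalN <- rep(n / 2, P)
  it <- 0L
  itAt <- rep(0L, P)
  trace <- numeric()
  act <- seq_len(P) # strata still iterating; converged rows are frozen
  while (it < maxIter && length(act)) {
    it <- it + 1L
    xa <- x[act, , drop = FALSE]
    m <- length(act)
    d1 <- matrix(dgamma(as.vector(xa), shape = rep(shape[act], n),
                        rate = rep(rate[act], n)), m, n)
    d2 <- matrix(dnorm(as.vector(xa), mean = rep(mu[act], n),
                       sd = rep(sigma[act], n)), m, n)
    w1 <- lambda[act] * d1
    tot <- pmax(w1 + (1 - lambda[act]) * d2, 1e-300)
    z <- w1 / tot
    llNew <- rowSums(log(tot))
    newConv <- abs(llNew - ll[act]) < tol
    itAt[act] <- it
    ll[act] <- llNew
    trace <- c(trace, sum(ll[is.finite(ll)]))
    converged[act] <- newConv

    W1 <- rowSums(z); W2 <- n - W1
    normalN[act] <- W2
    okN <- W2 > 1e-8
    muNew <- ifelse(okN, rowSums((1 - z) * xa) / pmax(W2, 1e-12), mu[act])
    sigNew <- ifelse(okN,
                     sqrt(rowSums((1 - z) * (xa - muNew)^2) /
                            pmax(W2, 1e-12)), sigma[act])
    mu[act] <- muNew
    sigma[act] <- pmax(sigNew, sigmaMin)
    okG <- W1 > 1e-8
    mw <- ifelse(okG, rowSums(z * xa) / pmax(W1, 1e-12), NA)
    mlog <- ifelse(okG, rowSums(z * logx[act, , drop = FALSE]) /
                     pmax(W1, 1e-12), NA)
    s <- pmax(log(mw) - mlog, 1e-12)
    a <- shape[act]
    upd <- okG & is.finite(s)
    if (any(upd)) {
      ai <- (3 - s[upd] + sqrt((s[upd] - 3)^2 + 24 * s[upd])) /
        (12 * s[upd])
      ai <- pmin(pmax(ai, 1e-2), shapeMax)
      for (nt in 1:25) {
        f <- log(ai) - digamma(ai) - s[upd]
        fp <- 1 / ai - trigamma(ai)
        ai <- pmin(pmax(ai - f / fp, 1e-2), shapeMax)
      }
      a[upd] <- ai
      rate[act][upd] <- a[upd] / pmax(mw[upd], 1e-12)
    }
    shape[act] <- a
    lambda[act] <- W1 / n
    act <- act[!newConv]
  }
  list(lambda = lambda, shape = shape, rate = rate, mu = mu, sigma = sigma,
       loglik = ll, iter = itAt, converged = converged, sds = sds,
       normalN = normalN, trace = trace)
}

# per-entry stratum parameter lookup: peaks x cells matrices of the fitted
# parameters (NA where unfitted)
stratum_param <- function(fit, what) {
  P <- length(fit@peakNames)
  cl <- fit@clusterOf
  out <- matrix(NA_real_, P, length(cl),
                dimnames = list(fit@peakNames, fit@cellNames))
  for (k in unique(cl)) {
    rows <- fit@fits$cluster == k & fit@fits$fitted
    vals <- rep(NA_real_, P)
    vals[fit@fits$peak[rows]] <- fit@fits[[what]][rows]
    out[, cl == k] <- vals
  }
  out
}

#' Posterior dropout probabilities from a mixture fit
#'
#' d = lambda g(x) / (lambda g(x) + (1 - lambda) f(x)) with g the Gamma and
#' f the Normal density of the entry's (peak, cluster) stratum, evaluated at
#' the pseudo-valued count. Entries in unfitted strata are NA and are never
#' recovered.
#'
#' @param fit a [MixtureFit].
#' @param counts the matrix (or [PeakCellMatrix]) the fit was built from.
#' @return peaks x cells matrix of dropout probabilities in [0, 1] (NA where
#'   undefined).
#' @export
dropoutProbability <- function(fit, counts) {
  X <- if (is(counts, "PeakCellMatrix"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  X[X == 0] <- fit@pseudoCount
  lam <- stratum_param(fit, "lambda")
  g <- dgamma(X, shape = stratum_param(fit, "shape"),
              rate = stratum_param(fit, "rate"))
  f <- dnorm(X, mean = stratum_param(fit, "mu"),
             sd = stratum_param(fit, "sigma"))
  num <- lam * g
  d <- num / pmax(num + (1 - lam) * f, 1e-300)
  dimnames(d) <- list(fit@peakNames, fit@cellNames)
  d
}

#' Recover likely dropout entries from predicted accessibility
#'
#' Entries whose dropout probability reaches the threshold T form the
#' recovery set and are replaced by the candidate value; all other entries
#' are returned untouched. The default candidate places the entry on the
#' stratum's bona fide count scale, modulated per cell by the model:
#' r = mu * yhat / mean(yhat over the stratum's cells). The model's raw
#' probabilities are calibrated to the observed (dropout-thinned) detection
#' rate, so they enter as a relative per-cell weight rather than an absolute
#' scale; `candidate = "probability"` keeps the raw probability instead.
#'
#' @param counts a [PeakCellMatrix] or peaks x cells matrix.
#' @param fit the [MixtureFit] for these counts.
#' @param predictions peaks x cells matrix of predicted accessibility
#'   probabilities from a trained model.
#' @param threshold dropout-probability threshold T (default 0.5).
#' @param candidate `"scaled"` or `"probability"`.
#' @param searchDropouts if FALSE, skip the mixture-based search and replace
#'   every entry at or below `zeroCeiling` indiscriminately (the ablation
#'   baseline).
#' @param zeroCeiling count level treated as "zero" by the no-search
#'   baseline.
#' @return a [DenoisedMatrix].
#' @export
denoiseMatrix <- function(counts, fit, predictions, threshold = 0.5,
                          candidate = c("scaled", "probability"),
                          searchDropouts = TRUE, zeroCeiling = 0) {
  candidate <- match.arg(candidate)
  X <- if (is(counts, "PeakCellMatrix"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  predictions <- as.matrix(predictions)
  .assert(all(dim(predictions) == dim(X)),
          "predictions must align with the count matrix")
  if (searchDropouts) {
    d <- dropoutProbability(fit, X)
    mask <- !is.na(d) & d >= threshold
  } else {
    mask <- X <= zeroCeiling
  }
  if (candidate == "scaled") {
    mu <- stratum_param(fit, "mu")
    mu[is.na(mu)] <- mean(fit@fits$mu[fit@fits$fitted], na.rm = TRUE)
    # per-cell modulation around the stratum scale: yhat relative to the
    # stratum's mean prediction
    ybar <- predictions
    for (k in unique(fit@clusterOf)) {
      cols <- fit@clusterOf == k
      ybar[, cols] <- rowMeans(predictions[, cols, drop = FALSE])
    }
    r <- mu * predictions / pmax(ybar, 1e-6)
  } else {
    r <- predictions
  }
  out <- X
  out[mask] <- r[mask]
  new("DenoisedMatrix", matrix = out, mask = mask * TRUE,
      threshold = threshold)
}

#' Neighbourhood label score of a peak-by-cell matrix
#'
#' Cells are projected onto principal components (50 by default) of the
#' cells x peaks matrix; the score is the mean, over cells, of the fraction
#' of each cell's k nearest neighbours (Euclidean, in PC space) sharing the
#' cell's label. Higher means biological neighbourhoods are better
#' preserved.
#'
#' @param counts a [PeakCellMatrix], [DenoisedMatrix] or peaks x cells
#'   matrix.
#' @param labels per-cell labels.
#' @param k neighbourhood size (the evaluation protocol uses 50, 75, 100).
#' @param nPCs number of principal components.
#' @return scalar label score in [0, 1].
#' @export
labelScore <- function(counts, labels, k = 50, nPCs = 50) {
  X <- if (is(counts, "PeakCellMatrix"))
    SummarizedExperiment::assay(counts, "counts")
  else if (is(counts, "DenoisedMatrix")) counts@matrix
  else as.matrix(counts)
  n <- ncol(X)
  .assert(length(labels) == n, "one label per cell required")
  .assert(k >= 1 && k < n, "k must satisfy 1 <= k < number of cells")
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE,
               rank. = min(nPCs, n - 1, nrow(X)))
  d <- as.matrix(dist(pc$x))
  labels <- as.character(labels)
  mean(vapply(seq_len(n), function(i) {
    nb <- setdiff(order(d[i, ]), i)[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, 0))
}
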
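#' Build a k-nearest-neighbour graph over cell embeddings
#'
#' Directed Euclidean kNN relations are symmetrised by union, so every cell
#' keeps degree >= k; distances are attached as the `weight` edge attribute.
#'
#' @param embedding cells x dimensions matrix.
#' @param k neighbours per cell (default 15).
#' @return an undirected [igraph::igraph] with one vertex per cell.
#' @export
buildKnnGraph <- function(embedding, k = 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  .assert(k >= 1 && k < n, "k must satisfy 1 <= k < number of cells")
  .assert(all(is.finite(embedding)), "embedding contains non-finite values")
  d <- as.matrix(dist(embedding))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    cbind(i, nb, d[i, nb])
  }))
  # union-symmetrise: keep one undirected edge per unordered pair
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  keep <- !duplicated(cbind(a, b))
  g <- igraph::graph_from_edgelist(cbind(a, b)[keep, , drop = FALSE],
                                   directed = FALSE)
  igraph::E(g)$weight <- edges[keep, 3]
  nms <- rownames(embedding)
  if (!is.null(nms)) igraph::V(g)$name <- nms
  g
}

#' Louvain community detection on a neighbour graph
#'
#' Greedy modularity optimisation; deterministic under a fixed seed. The
#' graph is treated as unweighted by default because kNN edge weights are
#' distances, not affinities.
#'
#' @param graph an undirected igraph, e.g. from [buildKnnGraph()].
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @param useWeights treat the `weight` edge attribute as connection
#'   strength.
#' @return a [ClusterAssignment] with community ids contiguous from 0.
#' @export
louvainCluster <- function(graph, resolution = 1, seed = 0,
                           useWeights = FALSE) {
  .assert(igraph::vcount(graph) > 0, "empty graph")
  w <- if (useWeights) igraph::E(graph)$weight else NA
  cl <- with_seed(seed,
                  igraph::cluster_louvain(graph, weights = w,
                                          resolution = resolution))
  mem <- as.integer(igraph::membership(cl)) - 1L
  nms <- igraph::V(graph)$name
  new("ClusterAssignment", membership = mem,
      modularity = igraph::modularity(cl),
      resolution = resolution, seed = as.integer(seed),
      cellNames = if (is.null(nms)) character() else nms)
}

entropy_counts <- function(n) {
  n <- n[n > 0]
  N <- sum(n)
  -sum(n / N * log(n / N))
}

#' Agreement between a clustering and reference labels
#'
#' Adjusted Rand index (permutation model), adjusted mutual information
#' (hypergeometric expected-MI correction, arithmetic mean normalisation)
#' and the v-score (harmonic mean of homogeneity and completeness). All
#' three are invariant to relabelling of cluster ids.
#'
#' @param pred a [ClusterAssignment] or a label vector.
#' @param truth reference labels of the same length.
#' @return list with `ari`, `ami`, `vscore`, `homogeneity`, `completeness`.
#' @export
clusteringAgreement <- function(pred, truth) {
  if (is(pred, "ClusterAssignment")) pred <- pred@membership
  .assert(length(pred) == length(truth),
          "prediction and truth lengths differ")
  n <- length(pred)
  tab <- table(pred, truth)
  a <- rowSums(tab); b <- colSums(tab)

  # ARI
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(a, 2)); sb <- sum(choose(b, 2))
  expected <- sa * sb / choose(n, 2)
  mx <- (sa + sb) / 2
  ari <- if (mx == expected) 1 else (sij - expected) / (mx - expected)

  # mutual information and entropies (natural log)
  ha <- entropy_counts(a); hb <- entropy_counts(b)
  nz <- which(tab > 0, arr.ind = TRUE)
  mi <- sum(vapply(seq_len(nrow(nz)), function(r) {
    nij <- tab[nz[r, 1], nz[r, 2]]
    nij / n * log(nij * n / (a[nz[r, 1]] * b[nz[r, 2]]))
  }, 0))

  # expected MI under the hypergeometric model
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (lo > hi) next
      for (nij in lo:hi) {
        term <- nij / n * log(n * nij / (a[i] * b[j]))
        lp <- lchoose(b[j], nij) + lchoose(n - b[j], a[i] - nij) -
          lchoose(n, a[i])
        emi <- emi + term * exp(lp)
      }
    }
  }
  denom <- (ha + hb) / 2 - emi
  ami <- if (abs(denom) < 1e-12) 1 else (mi - emi) / denom

  # homogeneity / completeness / v-score
  hom <- if (hb == 0) 1 else 1 - (hb - mi) / hb
  com <- if (ha == 0) 1 else 1 - (ha - mi) / ha
  v <- if (hom + com == 0) 0 else 2 * hom * com / (hom + com)

  list(ari = as.numeric(ari), ami = as.numeric(unname(ami)),
       vscore = as.numeric(unname(v)),
       homogeneity = as.numeric(unname(hom)),
       completeness = as.numeric(unname(com)))
}
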
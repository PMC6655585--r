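# Carbon-source syntrophy network and core-periphery (disassortative)
# structure detection.

#' Build the carbon-source syntrophy network
#'
#' Nodes are carbon sources; edge weights are the pair syntrophic
#' potentials (self-loops carry the within-source potential). The
#' `threshold` (default 0.55) is display-only: [thresholdedGraph()] applies
#' it, while all analysis runs on the full weighted network.
#'
#' @param sp symmetric matrix from [pairSyntrophicPotentials()].
#' @param threshold display threshold on edge weight.
#' @return object of class `carbonNetwork`: list with `weights`, `nodes`
#'   and `threshold`.
#' @export
buildCarbonNetwork <- function(sp, threshold = 0.55) {
  stopifnot(is.matrix(sp), nrow(sp) == ncol(sp))
  if (max(abs(sp - t(sp)), na.rm = TRUE) > 1e-12)
    stop("pair syntrophic potential matrix must be symmetric")
  w <- sp; w[is.na(w)] <- 0
  structure(list(weights = w, nodes = rownames(sp), threshold = threshold),
            class = "carbonNetwork")
}

#' Thresholded igraph view of a carbon network
#'
#' @param net a `carbonNetwork`.
#' @param threshold edge-weight threshold (default the network's).
#' @return an undirected weighted [igraph::graph] with edges of weight
#'   strictly above the threshold (self-loops dropped).
#' @export
thresholdedGraph <- function(net, threshold = net$threshold) {
  w <- net$weights
  w[w <= threshold] <- 0
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Correlation of the off-diagonal weights with the ideal core-periphery
# pattern (1 unless both endpoints are periphery).
.cpScore <- function(w, core) {
  n <- nrow(w)
  ut <- upper.tri(w)
  ideal <- outer(core, core, function(a, b) as.numeric(a | b))[ut]
  if (sd(ideal) == 0) return(-Inf)
  cor(w[ut], ideal)
}

#' Core-periphery partition of the carbon-source network
#'
#' Fits the two-role (disassortative) pattern - core-core and
#' core-periphery ties dense, periphery-periphery ties sparse - by
#' maximizing the correlation between the observed weights and the ideal
#' pattern, with greedy single-node refinement from `restarts` random
#' starts (deterministic given `seed`). Nodes whose tie pattern contradicts
#' both roles (mean weight to the periphery exceeding the mean weight to
#' the core by more than `outlierMargin`) are reported as outliers.
#'
#' @param net a `carbonNetwork` (at least 3 nodes).
#' @param restarts random restarts of the greedy search.
#' @param seed RNG seed for the restarts.
#' @param outlierMargin tolerance for the outlier rule.
#' @return list with `core`, `periphery`, `outliers` (node id vectors),
#'   `score` (fit correlation) and `degenerate` (TRUE with a warning when
#'   all weights are equal and no partition is meaningful).
#' @export
corePeriphery <- function(net, restarts = 50, seed = 1,
                          outlierMargin = 0.15) {
  w <- net$weights
  n <- nrow(w)
  if (n < 3) stop("core-periphery detection needs at least 3 nodes")
  if (sd(w[upper.tri(w)]) == 0) {
    warning("all edge weights equal: no meaningful core-periphery partition")
    return(list(core = character(), periphery = net$nodes,
                outliers = character(), score = NA_real_, degenerate = TRUE))
  }
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      core <- runif(n) < 0.5
      sc <- .cpScore(w, core)
      repeat {
        improved <- FALSE
        for (v in seq_len(n)) {
          cand <- core; cand[v] <- !cand[v]
          s2 <- .cpScore(w, cand)
          if (s2 > sc + 1e-12) { core <- cand; sc <- s2; improved <- TRUE }
        }
        if (!improved) break
      }
      if (is.null(best) || sc > best$score) best <- list(core = core, score = sc)
    }
  })
  core <- best$core
  # outlier rule on mean within/between weights (self excluded)
  wc <- wp <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    oc <- others[core[others]]; op <- others[!core[others]]
    wc[v] <- if (length(oc)) mean(w[v, oc]) else NA
    wp[v] <- if (length(op)) mean(w[v, op]) else NA
  }
  out <- !is.na(wc) & !is.na(wp) & (wp - wc > outlierMargin)
  list(core = net$nodes[core & !out],
       periphery = net$nodes[!core & !out],
       outliers = net$nodes[out],
       score = best$score, degenerate = FALSE)
}

#' Weighted degree assortativity of a carbon network
#'
#' Weighted Pearson correlation, over all edges (both orientations,
#' weighted by edge weight, self-loops excluded), between the weighted
#' degrees (strengths) of the endpoints. Negative values indicate the
#' disassortative organization expected of a core-periphery network.
#'
#' @param net a `carbonNetwork`.
#' @return the assortativity coefficient (`NA` with a warning when all
#'   strengths are equal).
#' @export
assortativityWeighted <- function(net) {
  w <- net$weights
  diag(w) <- 0
  s <- rowSums(w)
  idx <- which(w > 0, arr.ind = TRUE)
  if (!nrow(idx)) { warning("edgeless network"); return(NA_real_) }
  x <- s[idx[, 1]]; y <- s[idx[, 2]]; ew <- w[idx]
  mx <- sum(ew * x) / sum(ew); my <- sum(ew * y) / sum(ew)
  vx <- sum(ew * (x - mx)^2); vy <- sum(ew * (y - my)^2)
  if (vx == 0 || vy == 0) {
    warning("uniform strengths: assortativity undefined")
    return(NA_real_)
  }
  sum(ew * (x - mx) * (y - my)) / sqrt(vx * vy)
}
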
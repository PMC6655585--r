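# Planted two-role (core/periphery) weighted networks for tests.

plantedNetwork <- function(nCore = 4, nPeriph = 8, wCC = 0.8, wCP = 0.6,
                           wPP = 0.1, noise = 0, outlier = FALSE,
                           seed = NULL) {
  n <- nCore + nPeriph + outlier
  roles <- c(rep("core", nCore), rep("periph", nPeriph),
             if (outlier) "outlier")
  w <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    w[i, j] <- if (roles[i] == "outlier" || roles[j] == "outlier") {
      # the outlier ties strongly to the periphery only
      if (roles[c(i, j)][roles[c(i, j)] != "outlier"][1] == "periph" ||
          (roles[i] == "outlier" && roles[j] == "outlier")) wCP else wPP
    } else if (roles[i] == "core" && roles[j] == "core") wCC
    else if (roles[i] == "periph" && roles[j] == "periph") wPP
    else wCP
  }
  if (noise > 0) {
    e <- matrix(runif(n * n, -noise, noise), n)
    w <- pmin(pmax(w + (e + t(e)) / 2, 0), 1)
  }
  diag(w) <- 0
  dimnames(w) <- list(paste0("C", 1:n), paste0("C", 1:n))
  list(net = buildCarbonNetwork(w), roles = setNames(roles, rownames(w)))
}
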
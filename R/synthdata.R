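# Synthetic reaction universes with the structural features the syntrophy
# analysis assumes: several carbon sources, each connected by a dedicated
# transport reaction and a redundant upstream pathway to a shared trunk of
# intermediates feeding a single biomass reaction, plus off-pathway decoy
# reactions that give the MCMC sampler and the size-reduction step room to
# act. All stoichiometric coefficients are 1 so pathway yields can be
# checked by hand (biomass flux equals the carbon uptake bound).

# Run expr with a private RNG stream, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic reaction universe
#'
#' @param nCarbonSources number of carbon sources (each gets an
#'   extracellular metabolite, transport and an upstream pathway).
#' @param pathwayLength reactions between the internal carbon metabolite and
#'   the shared trunk.
#' @param nBranchRedundancy parallel copies of every pathway reaction.
#' @param nSharedIntermediates length of the shared trunk between the
#'   pathway hub and the biomass precursors.
#' @param nDecoyReactions mass-balanced reactions among decoy metabolites
#'   that never touch the biomass route.
#' @param transportPerSource parallel transport reactions per carbon source.
#' @param seed integer seed making generation deterministic.
#' @return A validated list of class `universeSpec`.
#' @export
universeSpec <- function(nCarbonSources = 5, pathwayLength = 3,
                         nBranchRedundancy = 2, nSharedIntermediates = 2,
                         nDecoyReactions = 40, transportPerSource = 1,
                         seed = 1) {
  spec <- list(nCarbonSources = as.integer(nCarbonSources),
               pathwayLength = as.integer(pathwayLength),
               nBranchRedundancy = as.integer(nBranchRedundancy),
               nSharedIntermediates = as.integer(nSharedIntermediates),
               nDecoyReactions = as.integer(nDecoyReactions),
               transportPerSource = as.integer(transportPerSource),
               seed = as.integer(seed))
  with(spec, {
    if (nCarbonSources < 1 || pathwayLength < 1 || nBranchRedundancy < 1 ||
        nSharedIntermediates < 1 || transportPerSource < 1 ||
        nDecoyReactions < 0)
      stop("all universeSpec counts must be >= 1 (decoys >= 0)")
  })
  structure(spec, class = "universeSpec")
}

.carbonSourceIds <- function(spec) paste0("C", seq_len(spec$nCarbonSources), "_ext")

# Reaction ids of one parallel copy of the complete route for source k:
# transport, upstream segments, trunk, distribution.
.routeIds <- function(spec, k, copy = 1) {
  c(sprintf("T%d_%d", k, min(copy, spec$transportPerSource)),
    sprintf("R%d_%d_%d", k, seq_len(spec$pathwayLength), copy),
    if (spec$nSharedIntermediates > 1)
      sprintf("RZ%d_%d", seq_len(spec$nSharedIntermediates - 1), copy),
    sprintf("RD_%d", copy))
}

.allRouteIds <- function(spec, k) {
  unique(unlist(lapply(seq_len(spec$nBranchRedundancy), function(cp)
    c(.routeIds(spec, k, cp),
      sprintf("T%d_%d", k, seq_len(spec$transportPerSource))))))
}

#' Generate a synthetic reaction universe and per-source seed metabolisms
#'
#' Builds the universe described by a [universeSpec()]: for carbon source
#' `k`, the route is `Ck_ext -> Ck -> Uk_1 -> ... -> Z1 -> ... -> Zq ->
#' P1+P2+P3 -> biomass`, with `nBranchRedundancy` parallel copies of every
#' non-transport pathway reaction. Decoy reactions interconvert a separate
#' pool of decoy metabolites. Each seed metabolism contains the complete
#' (all-copy) route of its primary source plus a random fill of other
#' reactions, and is verified viable on its primary source.
#'
#' @param spec a [universeSpec()].
#' @param seedFill fraction of the universe's reactions a seed metabolism
#'   contains (default 0.45).
#' @param selfCheck verify every seed's viability by LP (default `TRUE`).
#' @return list with elements `universe` ([ReactionUniverse-class]),
#'   `seeds` (named list of [Metabolism-class], one per carbon source),
#'   `sources` (carbon-source ids) and `spec`.
#' @export
generateUniverse <- function(spec, seedFill = 0.45, selfCheck = TRUE) {
  stopifnot(inherits(spec, "universeSpec"))
  .withSeed(spec$seed, {
    K <- spec$nCarbonSources; L <- spec$pathwayLength
    B <- spec$nBranchRedundancy; Q <- spec$nSharedIntermediates
    srcExt <- .carbonSourceIds(spec)
    srcInt <- paste0("C", seq_len(K))
    upstream <- if (L > 1)
      as.vector(outer(seq_len(K), seq_len(L - 1),
                      function(k, s) sprintf("U%d_%d", k, s))) else character()
    trunk <- paste0("Z", seq_len(Q))
    prec <- paste0("P", 1:3)
    nDm <- max(2L, ceiling(spec$nDecoyReactions / 2))
    decoyM <- if (spec$nDecoyReactions > 0) paste0("D", seq_len(nDm)) else character()
    mids <- c(srcExt, srcInt, upstream, trunk, prec, decoyM)
    ext <- setNames(mids %in% srcExt, mids)

    rx <- list()  # id -> list(stoich = named numeric, rev, transport, biomass)
    addRx <- function(id, from, to, rev = FALSE, transport = FALSE,
                      biomass = FALSE) {
      s <- c(setNames(rep(-1, length(from)), from),
             setNames(rep(1, length(to)), to))
      rx[[id]] <<- list(stoich = s, rev = rev, transport = transport,
                        biomass = biomass)
    }
    for (k in seq_len(K)) {
      for (tcp in seq_len(spec$transportPerSource))
        addRx(sprintf("T%d_%d", k, tcp), srcExt[k], srcInt[k], transport = TRUE)
      chain <- c(srcInt[k],
                 if (L > 1) sprintf("U%d_%d", k, seq_len(L - 1)), trunk[1])
      for (s in seq_len(L)) for (cp in seq_len(B))
        addRx(sprintf("R%d_%d_%d", k, s, cp), chain[s], chain[s + 1])
    }
    if (Q > 1) for (t in seq_len(Q - 1)) for (cp in seq_len(B))
      addRx(sprintf("RZ%d_%d", t, cp), trunk[t], trunk[t + 1])
    for (cp in seq_len(B))
      addRx(sprintf("RD_%d", cp), trunk[Q], prec)
    addRx("R_biomass", prec, character(), biomass = TRUE)
    if (spec$nDecoyReactions > 0) {
      for (j in seq_len(spec$nDecoyReactions)) {
        ab <- sample(decoyM, 2)
        addRx(sprintf("X%d", j), ab[1], ab[2], rev = runif(1) < 0.3)
      }
    }

    ids <- names(rx)
    T <- do.call(rbind, lapply(seq_along(ids), function(j) {
      s <- rx[[j]]$stoich
      cbind(match(names(s), mids), j, s)
    }))
    S <- Matrix::sparseMatrix(i = T[, 1], j = T[, 2], x = T[, 3],
                              dims = c(length(mids), length(ids)),
                              dimnames = list(mids, ids))
    uni <- ReactionUniverse(S,
                            reversible = vapply(rx, `[[`, logical(1), "rev"),
                            transport = vapply(rx, `[[`, logical(1), "transport"),
                            biomassId = "R_biomass",
                            extracellular = ext, medium = character())

    seedSize <- max(ceiling(seedFill * length(ids)),
                    max(vapply(seq_len(K), function(k)
                      length(.allRouteIds(spec, k)) + 1L, integer(1))))
    seeds <- setNames(vector("list", K), srcExt)
    for (k in seq_len(K)) {
      core <- c(.allRouteIds(spec, k), "R_biomass")
      fill <- sample(setdiff(ids, core), seedSize - length(core))
      seeds[[k]] <- Metabolism(c(core, fill), srcExt[k],
                               label = paste0(srcExt[k], ".seed"),
                               universe = uni)
    }
    if (selfCheck) {
      ok <- vapply(seeds, function(m)
        isViable(m, uni, primaryCarbonSource(m)), logical(1))
      if (!all(ok))
        stop("generator self-check failed: seed not viable for ",
             paste(srcExt[!ok], collapse = ", "))
    }
    list(universe = uni, seeds = seeds, sources = srcExt, spec = spec)
  })
}

#' Plant a complementary (syntrophic) pair for a carbon source
#'
#' Splits the single-copy route of carbon source `source` at upstream
#' position `cutAt`: template A receives the transport and the upstream
#' segments up to the cut, template B the segments after the cut plus the
#' shared trunk. Neither template is viable on `source` alone, the pooled
#' pair is, and the only metabolite whose transfer can bridge the cut is the
#' upstream intermediate at the cut (the designed minimum exchange of 1).
#' Optionally each template additionally receives the full single-copy route
#' of its own primary carbon source, making it viable on that primary.
#'
#' @param gen a bundle from [generateUniverse()].
#' @param source carbon source id to plant the syntrophy on.
#' @param cutAt upstream segment after which the route is cut
#'   (1..pathwayLength-1; default middle). Requires `pathwayLength >= 2`.
#' @param primaryA,primaryB optional distinct carbon sources whose complete
#'   route is added to template A / B.
#' @return list with `a`, `b` ([Metabolism-class] templates), `source`,
#'   `cutMetabolite` (the designed cross-fed intermediate) and
#'   `producerReaction` (the sole reaction producing it in the pair).
#' @export
plantComplementarity <- function(gen, source, cutAt = NULL,
                                 primaryA = NULL, primaryB = NULL) {
  spec <- gen$spec
  k <- match(source, gen$sources)
  if (is.na(k)) stop("unknown carbon source: ", source)
  if (spec$pathwayLength < 2)
    stop("plantComplementarity needs pathwayLength >= 2")
  if (is.null(cutAt)) cutAt <- ceiling((spec$pathwayLength - 1) / 2)
  stopifnot(cutAt >= 1, cutAt <= spec$pathwayLength - 1)

  segs <- sprintf("R%d_%d_%d", k, seq_len(spec$pathwayLength), 1L)
  trunkIds <- c(if (spec$nSharedIntermediates > 1)
    sprintf("RZ%d_%d", seq_len(spec$nSharedIntermediates - 1), 1L), "RD_1")
  aIds <- c(sprintf("T%d_1", k), segs[seq_len(cutAt)], "R_biomass")
  bIds <- c(segs[(cutAt + 1):spec$pathwayLength], trunkIds, "R_biomass")
  if (!is.null(primaryA)) {
    ka <- match(primaryA, gen$sources)
    aIds <- union(aIds, .routeIds(spec, ka, 1))
  }
  if (!is.null(primaryB)) {
    kb <- match(primaryB, gen$sources)
    bIds <- union(bIds, .routeIds(spec, kb, 1))
  }
  cutMet <- sprintf("U%d_%d", k, cutAt)
  list(a = Metabolism(aIds, if (is.null(primaryA)) source else primaryA,
                      label = "plantedA", universe = gen$universe),
       b = Metabolism(bIds, if (is.null(primaryB)) source else primaryB,
                      label = "plantedB", universe = gen$universe),
       source = source, cutMetabolite = cutMet,
       producerReaction = segs[cutAt])
}

#' Generate a population with known per-metabolism off-primary viability
#'
#' Fixture for the no-exchange null model: metabolism `i` receives the
#' complete single-copy routes of its primary source and of every other
#' source independently with probability `p[i]`. Because routes are included
#' all-or-nothing, pooling two such metabolisms can never complete a route
#' neither has, so pairs are non-interacting by construction and the
#' per-source viability probability of metabolism `i` is exactly `p[i]`.
#'
#' @param gen a bundle from [generateUniverse()].
#' @param n number of metabolisms.
#' @param p per-source inclusion probability, scalar or length-`n` vector.
#' @param seed RNG seed.
#' @return list with `population` (list of [Metabolism-class]), `p`
#'   (per-metabolism probabilities) and `primaries`.
#' @export
generateNullPopulation <- function(gen, n, p = 0.2, seed = 1) {
  spec <- gen$spec
  p <- rep_len(p, n)
  .withSeed(seed, {
    prim <- sample(seq_len(spec$nCarbonSources), n, replace = TRUE)
    pop <- lapply(seq_len(n), function(i) {
      extras <- setdiff(which(rbinom(spec$nCarbonSources, 1, p[i]) == 1),
                        prim[i])
      ids <- unique(c(unlist(lapply(c(prim[i], extras), function(k)
        .routeIds(spec, k, 1))), "R_biomass"))
      Metabolism(ids, gen$sources[prim[i]], label = sprintf("null.%d", i),
                 universe = gen$universe)
    })
    list(population = pop, p = p, primaries = gen$sources[prim])
  })
}
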
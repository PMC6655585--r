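# Viability-constrained MCMC reaction-swap sampling of random viable
# metabolisms, size reduction, and the random-augmentation control.

#' One MCMC reaction-swap step
#'
#' Removes one non-biomass reaction uniformly at random, inserts one
#' universe reaction not currently present uniformly at random, and accepts
#' the swap iff the result is still viable on the metabolism's primary
#' carbon source; otherwise the metabolism is returned unchanged. Consumes
#' R's global RNG stream (use `set.seed()` for reproducibility).
#'
#' @inheritParams growth
#' @param system optional precomputed full-universe system (internal use by
#'   [randomWalk()]; amortizes the LP assembly over a whole walk).
#' @return list with `metabolism` (new or unchanged), `accepted` (logical),
#'   and the proposed `removed`/`added` reaction ids.
#' @export
swapStep <- function(metabolism, universe, threshold = 1e-3,
                     system = NULL) {
  ids <- reactionIds(metabolism)
  absent <- setdiff(reactionIds(universe), ids)
  if (!length(absent))
    stop("swap saturation: the metabolism already contains the whole universe")
  drop <- sample(setdiff(ids, biomassId(universe)), 1L)
  add <- absent[sample.int(length(absent), 1L)]
  newIds <- c(setdiff(ids, drop), add)
  ok <- if (is.null(system)) {
    cand <- new("Metabolism", reactionIds = newIds,
                primarySource = metabolism@primarySource,
                label = metabolism@label)
    isViable(cand, universe, primaryCarbonSource(metabolism), threshold)
  } else .growthMasked(system, newIds, threshold) > 0
  out <- if (ok)
    new("Metabolism", reactionIds = newIds,
        primarySource = metabolism@primarySource,
        label = metabolism@label)
  else metabolism
  list(metabolism = out, accepted = ok, removed = drop, added = add)
}

#' MCMC random walk through the space of viable metabolisms
#'
#' Iterates [swapStep()] `nSteps` times. Every intermediate metabolism is
#' viable on the primary carbon source and the reaction count is invariant.
#'
#' @inheritParams swapStep
#' @param nSteps number of proposed swaps (default 50000, the number used
#'   to effectively randomize a genome-scale reaction complement).
#' @param recordTrace record the fraction of reactions shared with the
#'   start every `traceEvery` steps.
#' @param traceEvery trace sampling interval.
#' @return A [WalkResult-class] object.
#' @export
randomWalk <- function(metabolism, universe, nSteps = 50000,
                       threshold = 1e-3, recordTrace = FALSE,
                       traceEvery = 50L) {
  if (!isViable(metabolism, universe, primaryCarbonSource(metabolism),
                threshold))
    stop("walk must start from a metabolism viable on its primary source")
  start <- reactionIds(metabolism)
  cur <- metabolism
  accepted <- 0L
  usys <- .universeSystem(universe, primaryCarbonSource(metabolism))
  tr <- if (recordTrace) list(list(step = 0L, sharedFraction = 1)) else NULL
  for (s in seq_len(nSteps)) {
    st <- swapStep(cur, universe, threshold, system = usys)
    cur <- st$metabolism
    accepted <- accepted + st$accepted
    if (recordTrace && (s %% traceEvery == 0L || s == nSteps))
      tr[[length(tr) + 1L]] <- list(
        step = s,
        sharedFraction = length(intersect(reactionIds(cur), start)) /
          length(start))
  }
  new("WalkResult", metabolism = cur, steps = as.integer(nSteps),
      accepted = as.integer(accepted),
      acceptanceRate = if (nSteps > 0) accepted / nSteps else NaN,
      trace = if (recordTrace)
        do.call(rbind, lapply(tr, as.data.frame)) else NULL)
}

#' Reduce a metabolism to a target size
#'
#' Repeatedly removes a reaction drawn uniformly from the currently
#' removable set - reactions carrying zero flux in a current optimal flux
#' solution (hence not essential) - recomputing that set after every
#' deletion, until `targetSize` reactions remain. The result is verified
#' viable after every removal.
#'
#' @inheritParams growth
#' @param targetSize number of reactions to keep (default 520, a quarter of
#'   a genome-scale reaction complement).
#' @param carbonSource carbon source to preserve viability on (default the
#'   metabolism's primary).
#' @return A reduced [Metabolism-class] of exactly `targetSize` reactions.
#' @export
reduceMetabolism <- function(metabolism, universe, targetSize = 520,
                             carbonSource = primaryCarbonSource(metabolism),
                             threshold = 1e-3) {
  cur <- metabolism
  if (length(reactionIds(cur)) < targetSize)
    stop("metabolism smaller than targetSize")
  sol <- solveSystem(buildSystem(cur, universe, carbonSource))
  if (sol$status != "optimal" || sol$objective <= threshold)
    stop("metabolism is not viable on ", .sourceName(carbonSource))
  while (length(reactionIds(cur)) > targetSize) {
    removable <- setdiff(names(sol$fluxes)[sol$fluxes == 0],
                         biomassId(universe))
    repeat {
      if (!length(removable))
        stop("reduction floor reached at ", length(reactionIds(cur)),
             " reactions; targetSize ", targetSize, " not achievable")
      r <- removable[sample.int(length(removable), 1L)]
      cand <- new("Metabolism",
                  reactionIds = setdiff(reactionIds(cur), r),
                  primarySource = cur@primarySource, label = cur@label)
      solc <- solveSystem(buildSystem(cand, universe, carbonSource))
      if (solc$status == "optimal" && solc$objective > threshold) {
        cur <- cand; sol <- solc
        break
      }
      removable <- setdiff(removable, r)
    }
  }
  cur
}

#' Augment a metabolism with random universe reactions
#'
#' Adds `k` distinct absent reactions drawn uniformly from the universe,
#' with no viability constraint (the random-augmentation control for the
#' reaction-count explanation of syntrophy).
#'
#' @inheritParams swapStep
#' @param k number of reactions to add.
#' @return The augmented [Metabolism-class].
#' @export
augmentWithRandomReactions <- function(metabolism, universe, k) {
  absent <- setdiff(reactionIds(universe), reactionIds(metabolism))
  if (k > length(absent))
    stop("k exceeds the ", length(absent), " absent universe reactions")
  add <- absent[sample.int(length(absent), k)]
  new("Metabolism", reactionIds = c(reactionIds(metabolism), add),
      primarySource = metabolism@primarySource, label = metabolism@label)
}

#' Sample a population of random viable metabolisms
#'
#' Runs `perSource` independent MCMC walks from each per-source seed
#' metabolism, assigning labels `"<source>.<x>"`. Per-walk seeds are derived
#' as `seed + walk index`, so the whole population reproduces from one
#' integer. With `reduceTo` set, each walked metabolism is afterwards
#' size-reduced (`mode = "walk-then-reduce"`, the default); the alternative
#' `"reduce-then-walk"` first reduces the seed and then walks, which
#' constrains the walk much more strongly (acceptance drops markedly) and is
#' provided for comparison only.
#'
#' @param universe a [ReactionUniverse-class].
#' @param seeds named list of seed [Metabolism-class] objects, one per
#'   primary carbon source (e.g. from [generateUniverse()]).
#' @param perSource walks per carbon source (default 20).
#' @param nSteps swap proposals per walk.
#' @param seed base RNG seed.
#' @param reduceTo optional target size for [reduceMetabolism()].
#' @param mode see Description.
#' @param threshold viability threshold.
#' @return list with `population` (list of [Metabolism-class]) and
#'   `acceptance` (data.frame of per-walk acceptance rates).
#' @export
samplePopulation <- function(universe, seeds, perSource = 20,
                             nSteps = 50000, seed = 1, reduceTo = NULL,
                             mode = c("walk-then-reduce", "reduce-then-walk"),
                             threshold = 1e-3) {
  mode <- match.arg(mode)
  sources <- names(seeds)
  if (is.null(sources)) stop("seeds must be a named list keyed by carbon source")
  pop <- list(); acc <- list()
  w <- 0L
  for (src in sources) {
    for (x in seq_len(perSource)) {
      w <- w + 1L
      walked <- .withSeed(seed + w, {
        m0 <- seeds[[src]]
        if (!is.null(reduceTo) && mode == "reduce-then-walk")
          m0 <- reduceMetabolism(m0, universe, reduceTo, threshold = threshold)
        wr <- randomWalk(m0, universe, nSteps, threshold)
        mw <- wr@metabolism
        if (!is.null(reduceTo) && mode == "walk-then-reduce")
          mw <- reduceMetabolism(mw, universe, reduceTo, threshold = threshold)
        list(m = mw, rate = wr@acceptanceRate)
      })
      acc[[w]] <- data.frame(label = paste0(src, ".", x),
                             acceptanceRate = walked$rate)
      m <- walked$m
      m@label <- paste0(src, ".", x)
      pop[[m@label]] <- m
    }
  }
  list(population = pop, acceptance = do.call(rbind, acc))
}
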
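# Pairwise syntrophy detection, explicit exchange modelling, minimal
# exchanged metabolites, transport restoration, and syntrophy-essential
# reactions.

#' Pool two metabolisms into a joint metabolism
#'
#' The pooled metabolism is the union of the two reaction sets. Pooling is
#' symmetric and idempotent, and solving FBA on the pooled metabolism is
#' mathematically equivalent to the explicit two-compartment exchange model
#' with unrestricted transfer of every metabolite.
#'
#' @param mA,mB [Metabolism-class] objects from the same universe.
#' @return The pooled [Metabolism-class] (label `"<a>+<b>"`, primary source
#'   inherited from `mA`).
#' @export
poolMetabolisms <- function(mA, mB) {
  new("Metabolism",
      reactionIds = union(reactionIds(mA), reactionIds(mB)),
      primarySource = mA@primarySource,
      label = paste0(metabolismLabel(mA), "+", metabolismLabel(mB)))
}

#' Growth of a metabolism pair on a carbon source
#'
#' `G(A, B, Ck)`: the biomass flux of the pooled metabolism of `mA` and
#' `mB`. `jointGrowth(m, m, Ck)` equals the single-metabolism [growth()].
#'
#' @inheritParams poolMetabolisms
#' @inheritParams growth
#' @export
jointGrowth <- function(mA, mB, universe, env, threshold = 1e-3) {
  growth(poolMetabolisms(mA, mB), universe, env, threshold)
}

#' Detect syntrophic carbon sources for a metabolism pair
#'
#' A carbon source `Ck` is syntrophic for the pair (`S = 1`) iff both
#' individual growths are 0 (at most the 0.001 threshold) and the pooled
#' joint growth exceeds it. A metabolism can never be syntrophic with
#' itself. The count of syntrophic sources equals the number of carbon
#' sources the pair can use beyond the individual viability profiles.
#'
#' @inheritParams poolMetabolisms
#' @inheritParams viabilityProfile
#' @return list with `labels`, `syntrophicSources` (character vector of
#'   sources with `S = 1`) and `nJointAdditional` (its length).
#' @export
detectSyntrophy <- function(mA, mB, universe, carbonSources,
                            threshold = 1e-3) {
  if (setequal(reactionIds(mA), reactionIds(mB))) {
    return(list(labels = c(metabolismLabel(mA), metabolismLabel(mB)),
                syntrophicSources = character(), nJointAdditional = 0L))
  }
  syn <- character()
  for (ck in carbonSources) {
    gA <- growth(mA, universe, ck, threshold)
    if (gA > 0) next
    gB <- growth(mB, universe, ck, threshold)
    if (gB > 0) next
    if (jointGrowth(mA, mB, universe, ck, threshold) > 0) syn <- c(syn, ck)
  }
  list(labels = c(metabolismLabel(mA), metabolismLabel(mB)),
       syntrophicSources = syn, nJointAdditional = length(syn))
}

#' Growth under an explicit compartmentalized exchange model
#'
#' Keeps the two metabolisms distinct (internal metabolites duplicated per
#' partner, extracellular space shared) and couples them only through
#' reversible transfer reactions for the metabolites in `allowedExchange`.
#' The objective is the summed biomass flux of the two partners. With all
#' metabolites exchangeable this equals [jointGrowth()] (within solver
#' tolerance); with none it equals the better individual growth.
#'
#' @inheritParams jointGrowth
#' @param allowedExchange metabolite ids whose transfer between the
#'   partners is permitted (default: all).
#' @export
explicitExchangeGrowth <- function(mA, mB, universe, env,
                                   allowedExchange = metaboliteIds(universe),
                                   threshold = 1e-3) {
  sys <- .buildPairSystem(mA, mB, universe, env, allowedExchange)
  res <- solveSystem(sys)
  if (res$status != "optimal") return(0)
  if (res$objective <= threshold) 0 else res$objective
}

# Internal metabolites whose transfer can matter: touched by reactions of
# both partners.
.exchangeCandidates <- function(mA, mB, universe) {
  S <- stoichiometry(universe)
  ext <- isExtracellular(universe)
  touched <- function(ids)
    rownames(S)[Matrix::rowSums(abs(S[, ids, drop = FALSE])) > 0]
  setdiff(intersect(touched(reactionIds(mA)), touched(reactionIds(mB))),
          rownames(S)[ext])
}

#' Minimum number of exchanged metabolites for a syntrophy
#'
#' Finds a smallest set of metabolites whose transfer between the two
#' partners yields joint growth above the viability threshold on the given
#' carbon source. `method = "bnb"` (default) solves the mixed-integer
#' program - one binary per candidate metabolite gating its transfer
#' fluxes (big-M = 1000 x the carbon uptake bound), objective the number of
#' open transfers - by LP-relaxation branch and bound.
#' `method = "exhaustive"` enumerates subsets by increasing size and is
#' intended for small universes and as an oracle. Candidate metabolites are
#' the internal metabolites touched by both partners' reactions
#' (transferring any other metabolite cannot affect either partner).
#'
#' @inheritParams jointGrowth
#' @param method `"bnb"` or `"exhaustive"`.
#' @return list with `carbonSource`, `exchangedMetabolites` and `count`.
#' @export
minExchangedMetabolites <- function(mA, mB, universe, env,
                                    method = c("bnb", "exhaustive"),
                                    threshold = 1e-3) {
  method <- match.arg(method)
  env <- .asMedium(universe, env)
  gA <- growth(mA, universe, env, threshold)
  gB <- growth(mB, universe, env, threshold)
  gJ <- jointGrowth(mA, mB, universe, env, threshold)
  if (gA > 0 || gB > 0 || gJ == 0)
    stop("no syntrophy on ", env@carbonSource,
         ": minimal exchange is undefined")
  cand <- .exchangeCandidates(mA, mB, universe)
  feasible <- function(open)
    explicitExchangeGrowth(mA, mB, universe, env, open, threshold) > 0
  if (!feasible(cand))
    stop("internal inconsistency: candidate transfers do not reproduce the ",
         "pooled growth")

  if (method == "exhaustive") {
    for (k in 0:length(cand)) {
      for (set in if (k == 0) list(character()) else
        asplit(combn(cand, k), 2)) {
        if (feasible(as.character(set)))
          return(list(carbonSource = env@carbonSource,
                      exchangedMetabolites = as.character(set), count = k))
      }
    }
  }
  .minExchangeBnB(mA, mB, universe, env, cand, threshold, feasible)
}

# Branch and bound over open/closed transfer gates. Node relaxation: gates
# in `open` free, in `free` relaxed to z in [0,1] with transfer fluxes
# bounded by bigM * z; joint growth constrained above the threshold;
# objective = sum of free z. Integer incumbents are verified exactly.
.minExchangeBnB <- function(mA, mB, universe, env, cand, threshold,
                            feasible) {
  bigM <- env@uptakeBound * 1e3
  best <- list(count = length(cand), set = cand)

  relax <- function(open, free) {
    sys <- .buildPairSystem(mA, mB, universe, env, c(open, free))
    nc <- nrow(sys$cols)
    nF <- length(free)
    # growth row: objective - slack = threshold * (1 + 1e-6)
    A <- rbind(sys$A, Matrix::Matrix(sys$objective, 1, sparse = TRUE))
    rhs <- c(sys$rhs, threshold * (1 + 1e-6))
    upper <- sys$upper
    obj <- rep(0, nc)
    slackCols <- Matrix::sparseMatrix(i = nrow(A), j = 1L, x = -1,
                                      dims = c(nrow(A), 1L))
    if (nF) {
      # gating rows: t_ab + t_ba - bigM * z <= 0  (one per free metabolite)
      gi <- gj <- gx <- numeric(0)
      for (f in seq_len(nF)) {
        tcols <- which(sys$cols$kind %in% c("transfer_ab", "transfer_ba") &
                         sys$cols$target == free[f])
        gi <- c(gi, rep(nrow(A) + f, length(tcols)))
        gj <- c(gj, tcols)
        gx <- c(gx, rep(1, length(tcols)))
      }
      G <- Matrix::sparseMatrix(i = gi - nrow(A), j = gj, x = gx,
                                dims = c(nF, nc))
      A <- rbind(A, G)
      rhs <- c(rhs, rep(0, nF))
      # z columns (coefficient -bigM in its gating row) and slack columns
      Z <- Matrix::sparseMatrix(i = nrow(A) - nF + seq_len(nF),
                                j = seq_len(nF), x = rep(-bigM, nF),
                                dims = c(nrow(A), nF))
      Sl <- Matrix::sparseMatrix(i = nrow(A) - nF + seq_len(nF),
                                 j = seq_len(nF), x = rep(1, nF),
                                 dims = c(nrow(A), nF))
      slackCols <- rbind(slackCols,
                         Matrix::Matrix(0, nF, 1, sparse = TRUE))
      A <- cbind(A, Z, Sl, slackCols)
      obj <- c(obj, rep(1, nF), rep(0, nF), 0)
      upper <- c(upper, rep(1, nF), rep(Inf, nF), Inf)
    } else {
      A <- cbind(A, slackCols)
      obj <- c(obj, 0)
      upper <- c(upper, Inf)
    }
    res <- solveLP(obj, A, rhs, upper, maximize = FALSE)
    if (res$status != "optimal") return(NULL)
    list(objective = res$objective,
         z = if (nF) res$x[nc + seq_len(nF)] else numeric())
  }

  recurse <- function(open, free) {
    r <- relax(open, free)
    if (is.null(r)) return()
    lb <- length(open) + max(0, ceiling(r$objective - 1e-6))
    if (lb >= best$count) return()
    if (!length(free)) {
      if (feasible(open) && length(open) < best$count)
        best <<- list(count = length(open), set = open)
      return()
    }
    pick <- which.max(r$z)
    m <- free[pick]
    recurse(c(open, m), free[-pick])   # open branch first (greedy descent)
    recurse(open, free[-pick])
  }
  recurse(character(), cand)
  list(carbonSource = env@carbonSource, exchangedMetabolites = best$set,
       count = best$count)
}

#' Restore transport reactions for a set of carbon sources
#'
#' Adds every universe transport reaction touching each listed carbon
#' source to the metabolism (a superset, so the viability profile can only
#' grow).
#'
#' @inheritParams swapStep
#' @param carbonSources carbon-source metabolite ids.
#' @return The augmented [Metabolism-class].
#' @export
restoreTransport <- function(metabolism, universe, carbonSources) {
  S <- stoichiometry(universe)
  tr <- reactionIds(universe)[isTransport(universe)]
  add <- character()
  for (ck in carbonSources) {
    hit <- tr[S[ck, tr] != 0]
    if (!length(hit))
      stop("universe has no transport reaction for ", ck)
    add <- c(add, hit)
  }
  new("Metabolism",
      reactionIds = union(reactionIds(metabolism), add),
      primarySource = metabolism@primarySource, label = metabolism@label)
}

#' Reactions essential for a syntrophic interaction
#'
#' Partitions the pooled reactions of a syntrophic pair into those whose
#' single deletion abolishes joint growth on the syntrophic carbon source
#' and the rest, cross-tagged with membership in each parent and with
#' essentiality for each parent's growth on its own primary carbon source
#' (`NA` where a parent is not viable on its primary).
#'
#' @inheritParams jointGrowth
#' @param carbonSource the syntrophic carbon source.
#' @return data.frame with columns `reaction`, `essentialForSyntrophy`,
#'   `inA`, `inB`, `essentialA`, `essentialB`.
#' @export
syntrophyEssentialReactions <- function(mA, mB, universe, carbonSource,
                                        threshold = 1e-3) {
  if (growth(mA, universe, carbonSource, threshold) > 0 ||
      growth(mB, universe, carbonSource, threshold) > 0 ||
      jointGrowth(mA, mB, universe, carbonSource, threshold) == 0)
    stop("the pair is not syntrophic on ", .sourceName(carbonSource))
  pooled <- poolMetabolisms(mA, mB)
  ess <- essentialReactions(pooled, universe, carbonSource, threshold)
  ids <- reactionIds(pooled)
  parentEss <- function(m) {
    if (!isViable(m, universe, primaryCarbonSource(m), threshold))
      return(NULL)
    essentialReactions(m, universe, primaryCarbonSource(m), threshold)
  }
  eA <- parentEss(mA); eB <- parentEss(mB)
  data.frame(reaction = ids,
             essentialForSyntrophy = ids %in% ess,
             inA = ids %in% reactionIds(mA),
             inB = ids %in% reactionIds(mB),
             essentialA = if (is.null(eA)) NA else ids %in% eA,
             essentialB = if (is.null(eB)) NA else ids %in% eB,
             stringsAsFactors = FALSE)
}

#' Syntrophy records for every pair in a population
#'
#' Computes individual viability profiles once per metabolism, then for
#' every unordered pair evaluates the pooled growth on each carbon source
#' neither partner can use, recording the syntrophic sources.
#'
#' @param population list of [Metabolism-class] objects.
#' @inheritParams viabilityProfile
#' @return data.frame with one row per unordered pair: `labelA`, `labelB`,
#'   `primaryA`, `primaryB`, `syntrophicSources` (semicolon-joined),
#'   `nJointAdditional`.
#' @export
pairSyntrophy <- function(population, universe, carbonSources,
                          threshold = 1e-3) {
  n <- length(population)
  profiles <- lapply(population, function(m)
    viabilityProfile(m, universe, carbonSources, threshold))
  rows <- vector("list", n * (n - 1L) / 2L)
  idx <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    mA <- population[[i]]; mB <- population[[j]]
    open <- setdiff(carbonSources, union(profiles[[i]], profiles[[j]]))
    syn <- open[vapply(open, function(ck)
      jointGrowth(mA, mB, universe, ck, threshold) > 0, logical(1))]
    idx <- idx + 1L
    rows[[idx]] <- data.frame(
      labelA = metabolismLabel(mA), labelB = metabolismLabel(mB),
      primaryA = primaryCarbonSource(mA),
      primaryB = primaryCarbonSource(mB),
      syntrophicSources = paste(syn, collapse = ";"),
      nJointAdditional = length(syn), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
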
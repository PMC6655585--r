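# Assembly of stoichiometric LP systems for flux balance analysis.
#
# Conventions (see the methods vignette):
#  * every metabolite row is constrained to steady state (S v = 0);
#  * reversible reactions are split into forward/backward columns;
#  * medium metabolites get unbounded uptake and secretion;
#  * the carbon source gets uptake bounded by the medium's uptakeBound;
#  * every other extracellular metabolite may be secreted but never taken
#    up, so losing a transport reaction genuinely blocks a carbon source.

.asMedium <- function(universe, env, uptakeBound = 10) {
  if (methods::is(env, "GrowthMedium")) return(env)
  GrowthMedium(env, uptakeBound, universeMedium(universe))
}

.checkMembership <- function(metabolism, universe) {
  ids <- reactionIds(metabolism)
  bad <- setdiff(ids, reactionIds(universe))
  if (length(bad))
    stop("cannot resolve reaction ids in universe: ",
         paste(head(bad, 5L), collapse = ", "))
  if (!(biomassId(universe) %in% ids))
    stop("metabolism lacks the biomass reaction '", biomassId(universe), "'")
  ids
}

.checkMediumMetabolites <- function(universe, env) {
  mids <- metaboliteIds(universe)
  ext <- isExtracellular(universe)
  if (!(env@carbonSource %in% mids))
    stop("unknown carbon source: ", env@carbonSource)
  if (!ext[env@carbonSource])
    stop("carbon source '", env@carbonSource, "' is not extracellular")
  bad <- setdiff(env@medium, mids[ext])
  if (length(bad))
    stop("medium metabolites not extracellular/registered: ",
         paste(bad, collapse = ", "))
}

# Exchange columns over the extracellular rows of a system.
# Returns list(A, upper, cols) where A has one row per `rows` entry.
.exchangeBlock <- function(rows, extIds, env) {
  ups <- intersect(c(env@medium, env@carbonSource), extIds)
  i <- j <- x <- integer(0)
  upper <- numeric(0)
  kind <- character(0); target <- character(0)
  col <- 0L
  for (m in extIds) {
    ri <- match(m, rows)
    # secretion: removes m from the system
    col <- col + 1L
    i <- c(i, ri); j <- c(j, col); x <- c(x, -1)
    upper <- c(upper, Inf); kind <- c(kind, "secretion"); target <- c(target, m)
    if (m %in% ups) {
      col <- col + 1L
      i <- c(i, ri); j <- c(j, col); x <- c(x, 1)
      upper <- c(upper, if (m == env@carbonSource) env@uptakeBound else Inf)
      kind <- c(kind, "uptake"); target <- c(target, m)
    }
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(rows), col))
  list(A = A, upper = upper,
       cols = data.frame(kind = kind, target = target, side = "",
                         stringsAsFactors = FALSE))
}

# Flux columns of one metabolism over a given row space. rowOf maps a
# metabolite id to its row index (internal rows may be compartment copies).
.fluxBlock <- function(ids, universe, rowOf, nRows, side = "") {
  S <- stoichiometry(universe)[, ids, drop = FALSE]
  rev <- isReversible(universe)[ids]
  T <- methods::as(S, "TsparseMatrix")
  ri <- rowOf[rownames(S)][T@i + 1L]
  Afwd <- Matrix::sparseMatrix(i = ri, j = T@j + 1L, x = T@x,
                               dims = c(nRows, length(ids)))
  cols <- data.frame(kind = "flux_fwd", target = ids, side = side,
                     stringsAsFactors = FALSE)
  upper <- rep(Inf, length(ids))
  if (any(rev)) {
    Arev <- -Afwd[, rev, drop = FALSE]
    A <- cbind(Afwd, Arev)
    cols <- rbind(cols, data.frame(kind = "flux_rev", target = ids[rev],
                                   side = side, stringsAsFactors = FALSE))
    upper <- c(upper, rep(Inf, sum(rev)))
  } else A <- Afwd
  list(A = A, upper = upper, cols = cols)
}

#' Build the stoichiometric LP system of a metabolism in an environment
#'
#' Assembles the steady-state flux balance system: one row per metabolite,
#' forward/backward flux columns per (reversible) reaction, and exchange
#' columns implementing the environment (unbounded medium exchange, bounded
#' carbon-source uptake, secretion-only for all other extracellular
#' metabolites). The objective is the net biomass flux.
#'
#' @param metabolism a [Metabolism-class].
#' @param universe the [ReactionUniverse-class] the metabolism draws from.
#' @param env a [GrowthMedium-class], or a carbon-source id (the universe's
#'   declared medium and an uptake bound of 10 are then used).
#' @return An object of class `fbaSystem`: a list with the sparse constraint
#'   matrix `A`, right-hand side `rhs`, `upper` bounds, `objective` vector,
#'   column metadata `cols` (kind, target, side) and row ids `rows`.
#' @seealso [solveSystem()], [growth()]
#' @export
buildSystem <- function(metabolism, universe, env) {
  env <- .asMedium(universe, env)
  ids <- .checkMembership(metabolism, universe)
  .checkMediumMetabolites(universe, env)
  mids <- metaboliteIds(universe)
  ext <- isExtracellular(universe)
  rowOf <- setNames(seq_along(mids), mids)

  flux <- .fluxBlock(ids, universe, rowOf, length(mids))
  exch <- .exchangeBlock(mids, mids[ext], env)
  A <- cbind(flux$A, exch$A)
  cols <- rbind(flux$cols, exch$cols)
  objective <- numeric(nrow(cols))
  objective[cols$kind == "flux_fwd" & cols$target == biomassId(universe)] <- 1
  objective[cols$kind == "flux_rev" & cols$target == biomassId(universe)] <- -1

  structure(list(A = A, rhs = rep(0, length(mids)),
                 upper = c(flux$upper, exch$upper),
                 objective = objective, cols = cols, rows = mids,
                 env = env),
            class = "fbaSystem")
}

#' Solve an assembled flux balance system
#'
#' @param sys an `fbaSystem` from [buildSystem()] (or the internal pair
#'   builder).
#' @param maximize maximize the objective (default).
#' @return list with `status`, `objective`, raw column solution `x`, and
#'   `fluxes`: named net per-reaction fluxes (forward minus backward),
#'   clamped to zero below 1e-9.
#' @export
solveSystem <- function(sys, maximize = TRUE) {
  res <- solveLP(sys$objective, sys$A, sys$rhs, sys$upper,
                 maximize = maximize)
  if (res$status == "maxiter")
    stop("LP solver iteration limit reached (solver diagnostic, not infeasibility)")
  if (res$status == "unbounded")
    stop("LP unbounded: the system admits unlimited biomass flux; ",
         "check exchange bounds")
  fluxes <- NULL
  if (res$status == "optimal") {
    x <- .clampZero(res$x)
    isFlux <- sys$cols$kind %in% c("flux_fwd", "flux_rev")
    key <- ifelse(sys$cols$side == "", sys$cols$target,
                  paste0(sys$cols$side, "::", sys$cols$target))[isFlux]
    sgn <- ifelse(sys$cols$kind[isFlux] == "flux_fwd", 1, -1)
    fluxes <- tapply(x[isFlux] * sgn, key, sum)
    fluxes <- setNames(as.numeric(fluxes), names(fluxes))
    res$x <- x
    res$objective <- .clampZero(res$objective)
  }
  res$fluxes <- fluxes
  res
}

# Joint system for an explicit two-compartment exchange model: internal
# metabolites are duplicated per partner, the extracellular space is shared,
# and reversible transfer columns couple the copies of each metabolite in
# `allowedExchange`. Objective = sum of both biomass fluxes.
.buildPairSystem <- function(mA, mB, universe, env,
                             allowedExchange = character()) {
  env <- .asMedium(universe, env)
  idsA <- .checkMembership(mA, universe)
  idsB <- .checkMembership(mB, universe)
  .checkMediumMetabolites(universe, env)
  mids <- metaboliteIds(universe)
  ext <- isExtracellular(universe)
  intIds <- mids[!ext]; extIds <- mids[ext]

  rows <- c(paste0("A::", intIds), paste0("B::", intIds), extIds)
  rowA <- setNames(c(match(paste0("A::", intIds), rows),
                     match(extIds, rows)), c(intIds, extIds))[mids]
  rowB <- setNames(c(match(paste0("B::", intIds), rows),
                     match(extIds, rows)), c(intIds, extIds))[mids]
  names(rowA) <- names(rowB) <- mids
  nr <- length(rows)

  fA <- .fluxBlock(idsA, universe, rowA, nr, side = "A")
  fB <- .fluxBlock(idsB, universe, rowB, nr, side = "B")
  AA <- fA$A; AB <- fB$A
  exch <- .exchangeBlock(rows, extIds, env)

  allowed <- intersect(unique(allowedExchange), intIds)
  if (length(allowed)) {
    i <- c(rowA[allowed], rowB[allowed], rowA[allowed], rowB[allowed])
    j <- c(rep(seq_along(allowed), 2),
           rep(seq_along(allowed) + length(allowed), 2))
    x <- c(rep(-1, length(allowed)), rep(1, length(allowed)),
           rep(1, length(allowed)), rep(-1, length(allowed)))
    At <- Matrix::sparseMatrix(i = i, j = j, x = x,
                               dims = c(nr, 2L * length(allowed)))
    tcols <- data.frame(kind = rep(c("transfer_ab", "transfer_ba"),
                                   each = length(allowed)),
                        target = rep(allowed, 2), side = "",
                        stringsAsFactors = FALSE)
    A <- cbind(AA, AB, exch$A, At)
    cols <- rbind(fA$cols, fB$cols, exch$cols, tcols)
    upper <- c(fA$upper, fB$upper, exch$upper, rep(Inf, ncol(At)))
  } else {
    A <- cbind(AA, AB, exch$A)
    cols <- rbind(fA$cols, fB$cols, exch$cols)
    upper <- c(fA$upper, fB$upper, exch$upper)
  }
  objective <- numeric(nrow(cols))
  bio <- cols$target == biomassId(universe)
  objective[bio & cols$kind == "flux_fwd"] <- 1
  objective[bio & cols$kind == "flux_rev"] <- -1
  structure(list(A = A, rhs = rep(0, nr), upper = upper,
                 objective = objective, cols = cols, rows = rows, env = env),
            class = "fbaSystem")
}
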
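# Viability prediction and essentiality analysis via flux balance analysis.

# Full-universe system with every reaction present; membership of a
# particular metabolism is imposed by zeroing the flux bounds of absent
# reactions (identical feasible set to buildSystem on the subset, but the
# assembly cost is paid once per walk instead of once per LP).
.universeSystem <- function(universe, env) {
  all <- new("Metabolism", reactionIds = reactionIds(universe),
             primarySource = .sourceName(env), label = "universe")
  sys <- buildSystem(all, universe, env)
  sys$Adense <- as.matrix(sys$A)
  sys$isFlux <- sys$cols$kind %in% c("flux_fwd", "flux_rev")
  sys$fluxTarget <- sys$cols$target
  sys
}

# Thresholded growth of the metabolism given by `ids` on a cached
# .universeSystem.
.growthMasked <- function(sys, ids, threshold = 1e-3) {
  up <- sys$upper
  up[sys$isFlux & !(sys$fluxTarget %in% ids)] <- 0
  res <- .simplex_solve(sys$Adense, sys$rhs, -sys$objective, up, 0L)
  if (res$status != 0) {
    if (res$status == 1) return(0)
    stop("LP solver failure (status ", res$status, ") in masked growth")
  }
  g <- -res$objective
  if (g <= threshold) 0 else g
}

#' Growth of a metabolism in a single-carbon-source environment
#'
#' Maximal biomass flux of the metabolism under the steady-state constraints
#' of [buildSystem()]. Growth rates at or below the viability `threshold`
#' are reported as 0, following the convention that biomass yields must
#' strictly exceed 0.001 to count as growth.
#'
#' @inheritParams buildSystem
#' @param threshold viability threshold on the biomass flux (default 0.001).
#' @return A single number: the biomass flux, or 0 if the optimum does not
#'   exceed `threshold` (or the system is infeasible).
#' @examples
#' g <- generateUniverse(universeSpec(nCarbonSources = 2, seed = 1))
#' growth(g$seeds[[1]], g$universe, primaryCarbonSource(g$seeds[[1]]))
#' @export
growth <- function(metabolism, universe, env, threshold = 1e-3) {
  res <- solveSystem(buildSystem(metabolism, universe, env))
  if (res$status != "optimal") return(0)
  if (res$objective <= threshold) 0 else res$objective
}

#' Full flux balance solution of a metabolism
#'
#' Like [growth()] but returns the whole [FluxSolution-class]: solver
#' status, the (unthresholded) optimal biomass flux and net per-reaction
#' fluxes.
#'
#' @inheritParams growth
#' @return A [FluxSolution-class] object.
#' @export
fba <- function(metabolism, universe, env) {
  res <- solveSystem(buildSystem(metabolism, universe, env))
  if (res$status != "optimal")
    return(new("FluxSolution", status = "infeasible", objective = 0,
               fluxes = numeric()))
  new("FluxSolution", status = "optimal", objective = res$objective,
      fluxes = res$fluxes)
}

#' Is a metabolism viable on a carbon source?
#'
#' Viability means the maximal biomass flux strictly exceeds the threshold
#' (default 0.001) when the carbon source is supplied at the medium's uptake
#' bound.
#'
#' @inheritParams growth
#' @param carbonSource carbon-source metabolite id or a [GrowthMedium-class].
#' @return `TRUE` or `FALSE`.
#' @export
isViable <- function(metabolism, universe, carbonSource, threshold = 1e-3) {
  growth(metabolism, universe, carbonSource, threshold) > 0
}

#' Viability profile over a set of carbon sources
#'
#' @inheritParams growth
#' @param carbonSources character vector of carbon-source metabolite ids.
#' @return Character vector of the sources the metabolism is viable on, with
#'   attributes `label` and `primary`.
#' @export
viabilityProfile <- function(metabolism, universe, carbonSources,
                             threshold = 1e-3) {
  ok <- vapply(carbonSources, function(ck)
    isViable(metabolism, universe, ck, threshold), logical(1))
  structure(carbonSources[ok], label = metabolismLabel(metabolism),
            primary = primaryCarbonSource(metabolism))
}

#' Viability profiles of a population, as a table
#'
#' @param population list of [Metabolism-class] objects.
#' @inheritParams viabilityProfile
#' @return data.frame with columns `label`, `primary` and `viableSources`
#'   (semicolon-joined), suitable for CSV export.
#' @export
viabilityProfileTable <- function(population, universe, carbonSources,
                                  threshold = 1e-3) {
  rows <- lapply(population, function(m) {
    p <- viabilityProfile(m, universe, carbonSources, threshold)
    data.frame(label = metabolismLabel(m),
               primary = primaryCarbonSource(m),
               viableSources = paste(p, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reactions essential for viability on a carbon source
#'
#' A reaction is essential if its single deletion makes [isViable()] false.
#' The biomass reaction is essential by construction and is never deleted.
#'
#' @inheritParams isViable
#' @return Character vector of essential reaction ids (always containing the
#'   biomass reaction).
#' @export
essentialReactions <- function(metabolism, universe, carbonSource,
                               threshold = 1e-3) {
  if (!isViable(metabolism, universe, carbonSource, threshold))
    stop("metabolism is not viable on ", .sourceName(carbonSource),
         "; essentiality is undefined")
  ids <- reactionIds(metabolism)
  others <- setdiff(ids, biomassId(universe))
  ess <- vapply(others, function(r) {
    m2 <- new("Metabolism", reactionIds = setdiff(ids, r),
              primarySource = metabolism@primarySource,
              label = metabolism@label)
    !isViable(m2, universe, carbonSource, threshold)
  }, logical(1))
  c(biomassId(universe), others[ess])
}

.sourceName <- function(env) {
  if (methods::is(env, "GrowthMedium")) env@carbonSource else as.character(env)
}

#' Reactions with provably zero flux at the growth optimum
#'
#' Flux-variability criterion: a reaction is reported if the maximum of
#' \eqn{|v|} over the optimal face (biomass flux within a relative 1e-9 of
#' its optimum) is zero. Deleting any single returned reaction therefore
#' preserves viability.
#'
#' @inheritParams isViable
#' @return Character vector of zero-flux reaction ids (never the biomass
#'   reaction).
#' @export
zeroFluxReactions <- function(metabolism, universe, carbonSource,
                              threshold = 1e-3) {
  sys <- buildSystem(metabolism, universe, carbonSource)
  res <- solveSystem(sys)
  if (res$status != "optimal" || res$objective <= threshold)
    stop("metabolism is not viable on ", .sourceName(carbonSource))
  cand <- setdiff(names(res$fluxes)[res$fluxes == 0], biomassId(universe))
  if (!length(cand)) return(character())

  fixed <- .fixObjectiveFace(sys, res$objective)
  keep <- vapply(cand, function(r) {
    rng <- .netFluxRange(fixed, r)
    max(abs(rng)) < 1e-7
  }, logical(1))
  cand[keep]
}

# Append a row constraining the objective to its optimal face:
# objective >= opt*(1 - 1e-9), encoded as obj - slack = bound.
.fixObjectiveFace <- function(sys, opt) {
  bound <- opt * (1 - 1e-9)
  A <- rbind(sys$A, Matrix::Matrix(sys$objective, 1, sparse = TRUE))
  A <- cbind(A, Matrix::sparseMatrix(i = nrow(A), j = 1L, x = -1,
                                     dims = c(nrow(A), 1L)))
  sys$A <- A
  sys$rhs <- c(sys$rhs, bound)
  sys$upper <- c(sys$upper, Inf)
  sys$objective <- c(sys$objective, 0)
  sys$cols <- rbind(sys$cols, data.frame(kind = "slack", target = "objective",
                                         side = "", stringsAsFactors = FALSE))
  sys
}

# (min, max) of the net flux of reaction r over the current feasible set.
# Unbounded directions (internal flux cycles) are reported as +/-Inf.
.netFluxRange <- function(sys, r) {
  v <- numeric(nrow(sys$cols))
  v[sys$cols$kind == "flux_fwd" & sys$cols$target == r] <- 1
  v[sys$cols$kind == "flux_rev" & sys$cols$target == r] <- -1
  one <- function(maximize) {
    res <- solveLP(v, sys$A, sys$rhs, sys$upper, maximize = maximize)
    if (res$status == "optimal") res$objective
    else if (maximize) Inf else -Inf
  }
  c(one(FALSE), one(TRUE))
}
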
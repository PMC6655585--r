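#' @import methods
NULL

#' ReactionUniverse: the global pool of candidate reactions
#'
#' A `ReactionUniverse` holds the stoichiometry of every candidate reaction a
#' metabolism may draw from, as a sparse metabolite-by-reaction matrix
#' (negative coefficients = consumed), together with per-reaction
#' reversibility and transport flags, the identity of the single biomass
#' reaction, a per-metabolite extracellular flag, and the universe's declared
#' minimal-medium metabolites (freely exchangeable non-carbon nutrients;
#' may be empty).
#'
#' @slot stoich a `dgCMatrix`, metabolites x reactions, with dimnames.
#' @slot reversible named logical, one entry per reaction.
#' @slot transport named logical, one entry per reaction.
#' @slot biomassId id of the biomass reaction.
#' @slot extracellular named logical, one entry per metabolite.
#' @slot medium character vector of medium metabolite ids.
#'
#' @aliases ReactionUniverse-class
#' @export
setClass("ReactionUniverse",
  representation(
    stoich = "dgCMatrix",
    reversible = "logical",
    transport = "logical",
    biomassId = "character",
    extracellular = "logical",
    medium = "character"
  )
)

setValidity("ReactionUniverse", function(object) {
  S <- object@stoich
  rids <- colnames(S); mids <- rownames(S)
  msg <- character()
  if (is.null(rids) || is.null(mids))
    return("stoichiometry must carry metabolite and reaction ids as dimnames")
  if (anyDuplicated(rids)) msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(mids)) msg <- c(msg, "duplicated metabolite ids")
  if (!identical(names(object@reversible), rids) ||
      !identical(names(object@transport), rids))
    msg <- c(msg, "reversible/transport flags must be named by reaction id, in matrix order")
  if (!identical(names(object@extracellular), mids))
    msg <- c(msg, "extracellular flags must be named by metabolite id, in matrix order")
  if (length(object@biomassId) != 1L || !(object@biomassId %in% rids))
    msg <- c(msg, "biomass reaction missing from universe")
  if (any(Matrix::colSums(S != 0) == 0))
    msg <- c(msg, "every reaction needs a non-empty stoichiometry")
  if (!all(object@medium %in% mids))
    msg <- c(msg, "medium metabolites must be registered")
  # a transport reaction moves something across the boundary
  tr <- names(object@transport)[object@transport]
  if (length(tr)) {
    touchesExt <- vapply(tr, function(r) {
      m <- mids[S[, r] != 0]
      any(object@extracellular[m])
    }, logical(1))
    if (!all(touchesExt))
      msg <- c(msg, "transport reactions must touch an extracellular metabolite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReactionUniverse
#'
#' @param stoich metabolite-by-reaction matrix (dense or sparse) with
#'   dimnames; negative = consumed, positive = produced.
#' @param reversible logical vector (recycled or named by reaction id).
#' @param transport logical vector, as `reversible`.
#' @param biomassId id of the biomass reaction.
#' @param extracellular logical per metabolite (named or in row order).
#' @param medium character vector of freely exchangeable medium metabolites.
#' @return A [ReactionUniverse-class] object.
#' @export
ReactionUniverse <- function(stoich, reversible, transport, biomassId,
                             extracellular, medium = character()) {
  S <- methods::as(methods::as(Matrix::Matrix(stoich, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  rids <- colnames(S); mids <- rownames(S)
  fix <- function(v, ids) {
    if (!is.null(names(v))) v <- v[ids]
    v <- rep_len(as.logical(v), length(ids))
    names(v) <- ids
    v
  }
  new("ReactionUniverse", stoich = S,
      reversible = fix(reversible, rids), transport = fix(transport, rids),
      biomassId = biomassId, extracellular = fix(extracellular, mids),
      medium = as.character(medium))
}

#' Metabolism: a reaction subset with a primary carbon source
#'
#' A `Metabolism` is a subset of a universe's reactions (always including the
#' biomass reaction), tagged with the primary carbon source its viability is
#' constrained on and a free-form label.
#'
#' @slot reactionIds character vector of member reaction ids.
#' @slot primarySource metabolite id of the primary carbon source.
#' @slot label identifier, conventionally `"<source>.<index>"`.
#' @aliases Metabolism-class
#' @export
setClass("Metabolism",
  representation(reactionIds = "character", primarySource = "character",
                 label = "character")
)

setValidity("Metabolism", function(object) {
  msg <- character()
  if (anyDuplicated(object@reactionIds)) msg <- c(msg, "duplicated reaction ids")
  if (length(object@primarySource) != 1L) msg <- c(msg, "one primary carbon source required")
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Metabolism
#'
#' @param reactionIds member reaction ids.
#' @param primarySource primary carbon source metabolite id.
#' @param label metabolism label (default `""`).
#' @param universe optional [ReactionUniverse-class]; if supplied, membership
#'   is checked and the biomass reaction added if absent.
#' @return A [Metabolism-class] object.
#' @export
Metabolism <- function(reactionIds, primarySource, label = "",
                       universe = NULL) {
  reactionIds <- unique(as.character(reactionIds))
  if (!is.null(universe)) {
    bad <- setdiff(reactionIds, reactionIds(universe))
    if (length(bad))
      stop("reaction ids not in universe: ", paste(head(bad, 5), collapse = ", "))
    reactionIds <- union(reactionIds, biomassId(universe))
    if (!(primarySource %in% metaboliteIds(universe)))
      stop("unknown carbon source: ", primarySource)
  }
  new("Metabolism", reactionIds = reactionIds,
      primarySource = as.character(primarySource), label = as.character(label))
}

#' GrowthMedium: a minimal medium with a single bounded carbon source
#'
#' @slot carbonSource metabolite id of the carbon source.
#' @slot uptakeBound maximal uptake flux of the carbon source (flux units).
#' @slot medium ids of the medium metabolites with unbounded exchange.
#' @aliases GrowthMedium-class
#' @export
setClass("GrowthMedium",
  representation(carbonSource = "character", uptakeBound = "numeric",
                 medium = "character")
)

setValidity("GrowthMedium", function(object) {
  msg <- character()
  if (length(object@carbonSource) != 1L) msg <- c(msg, "one carbon source required")
  if (length(object@uptakeBound) != 1L || object@uptakeBound <= 0)
    msg <- c(msg, "uptakeBound must be a single positive number")
  if (object@carbonSource %in% object@medium)
    msg <- c(msg, "carbon source cannot be part of the unrestricted medium")
  if (length(msg)) msg else TRUE
})

#' Construct a GrowthMedium
#'
#' @param carbonSource carbon source metabolite id.
#' @param uptakeBound carbon uptake flux bound (default 10).
#' @param medium unrestricted medium metabolite ids.
#' @return A [GrowthMedium-class] object.
#' @export
GrowthMedium <- function(carbonSource, uptakeBound = 10,
                         medium = character()) {
  new("GrowthMedium", carbonSource = as.character(carbonSource),
      uptakeBound = as.numeric(uptakeBound), medium = as.character(medium))
}

#' FluxSolution: result of a flux balance analysis
#'
#' @slot status `"optimal"` or `"infeasible"`.
#' @slot objective optimal biomass flux (0 if infeasible).
#' @slot fluxes named numeric of net per-reaction fluxes.
#' @aliases FluxSolution-class
#' @export
setClass("FluxSolution",
  representation(status = "character", objective = "numeric",
                 fluxes = "numeric")
)

#' WalkResult: outcome of an MCMC reaction-swap random walk
#'
#' @slot metabolism the final [Metabolism-class].
#' @slot steps number of proposed swaps.
#' @slot accepted number of accepted swaps.
#' @slot acceptanceRate accepted/steps (`NaN` for zero-step walks).
#' @slot trace optional data.frame with columns `step` and
#'   `sharedFraction` (fraction of reactions shared with the start).
#' @aliases WalkResult-class
#' @export
setClass("WalkResult",
  representation(metabolism = "Metabolism", steps = "integer",
                 accepted = "integer", acceptanceRate = "numeric",
                 trace = "ANY")
)

setValidity("WalkResult", function(object) {
  if (object@accepted > object@steps) "accepted cannot exceed steps" else TRUE
})

setMethod("show", "ReactionUniverse", function(object) {
  cat("ReactionUniverse:", ncol(object@stoich), "reactions,",
      nrow(object@stoich), "metabolites\n")
  cat("  biomass:", object@biomassId,
      "| transport:", sum(object@transport),
      "| reversible:", sum(object@reversible), "\n")
  cat("  extracellular metabolites:", sum(object@extracellular),
      "| medium:", if (length(object@medium))
        paste(object@medium, collapse = ", ") else "(none)", "\n")
})

setMethod("show", "Metabolism", function(object) {
  cat("Metabolism", if (nzchar(object@label)) object@label else "(unlabelled)",
      "-", length(object@reactionIds), "reactions, primary carbon source",
      object@primarySource, "\n")
})

setMethod("show", "GrowthMedium", function(object) {
  cat("GrowthMedium: carbon source", object@carbonSource,
      "(uptake <=", object@uptakeBound, ") +",
      length(object@medium), "medium metabolites\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status, "| biomass flux",
      format(object@objective, digits = 6), "\n")
})

setMethod("show", "WalkResult", function(object) {
  cat("WalkResult:", object@steps, "steps,", object@accepted,
      "accepted (rate", format(object@acceptanceRate, digits = 4), ")\n")
  show(object@metabolism)
})
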
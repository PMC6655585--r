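#' Accessors for universe and metabolism objects
#'
#' `reactionIds` returns the reaction ids of a universe or metabolism;
#' `metaboliteIds` the metabolite registry; `biomassId` the biomass reaction
#' id; `stoichiometry` the sparse metabolite-by-reaction matrix;
#' `isTransport` / `isReversible` the per-reaction flags;
#' `isExtracellular` the per-metabolite compartment flag;
#' `universeMedium` the declared minimal-medium metabolites;
#' `primaryCarbonSource` and `metabolismLabel` the metabolism tags.
#'
#' @param x a [ReactionUniverse-class] or [Metabolism-class] object.
#' @return Character vectors, logical vectors or a `dgCMatrix`, as described.
#' @name accessors
#' @examples
#' u <- generateUniverse(universeSpec(nCarbonSources = 2, seed = 1))$universe
#' length(reactionIds(u)); biomassId(u)
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))
#' @rdname accessors
#' @export
setGeneric("biomassId", function(x) standardGeneric("biomassId"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("isTransport", function(x) standardGeneric("isTransport"))
#' @rdname accessors
#' @export
setGeneric("isReversible", function(x) standardGeneric("isReversible"))
#' @rdname accessors
#' @export
setGeneric("isExtracellular", function(x) standardGeneric("isExtracellular"))
#' @rdname accessors
#' @export
setGeneric("universeMedium", function(x) standardGeneric("universeMedium"))
#' @rdname accessors
#' @export
setGeneric("primaryCarbonSource", function(x) standardGeneric("primaryCarbonSource"))
#' @rdname accessors
#' @export
setGeneric("metabolismLabel", function(x) standardGeneric("metabolismLabel"))

#' @rdname accessors
setMethod("reactionIds", "ReactionUniverse", function(x) colnames(x@stoich))
#' @rdname accessors
setMethod("reactionIds", "Metabolism", function(x) x@reactionIds)
#' @rdname accessors
setMethod("metaboliteIds", "ReactionUniverse", function(x) rownames(x@stoich))
#' @rdname accessors
setMethod("biomassId", "ReactionUniverse", function(x) x@biomassId)
#' @rdname accessors
setMethod("stoichiometry", "ReactionUniverse", function(x) x@stoich)
#' @rdname accessors
setMethod("isTransport", "ReactionUniverse", function(x) x@transport)
#' @rdname accessors
setMethod("isReversible", "ReactionUniverse", function(x) x@reversible)
#' @rdname accessors
setMethod("isExtracellular", "ReactionUniverse", function(x) x@extracellular)
#' @rdname accessors
setMethod("universeMedium", "ReactionUniverse", function(x) x@medium)
#' @rdname accessors
setMethod("primaryCarbonSource", "Metabolism", function(x) x@primarySource)
#' @rdname accessors
setMethod("metabolismLabel", "Metabolism", function(x) x@label)
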
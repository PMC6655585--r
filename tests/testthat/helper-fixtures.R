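# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# default synthetic universe (5 sources, redundancy 2, decoys)
defaultGen <- function() fixture("default", generateUniverse(universeSpec(seed = 7)))

# tiny universe: 2 sources, single-copy pathways, no decoys (12 metabolites)
tinySpec <- function(seed = 1)
  universeSpec(nCarbonSources = 2, pathwayLength = 3, nBranchRedundancy = 1,
               nSharedIntermediates = 1, nDecoyReactions = 0,
               transportPerSource = 1, seed = seed)
tinyGen <- function() fixture("tiny", generateUniverse(tinySpec()))

# hand-built 3-reaction toy: uptake -> convert -> biomass.
# Carbon yield is 1 biomass per carbon unit, so growth = uptake bound.
toyUniverse <- function() fixture("toy", {
  S <- matrix(0, 3, 3,
              dimnames = list(c("glc_ext", "glc", "bm_pre"),
                              c("T_glc", "R_conv", "R_bio")))
  S["glc_ext", "T_glc"] <- -1; S["glc", "T_glc"] <- 1
  S["glc", "R_conv"] <- -1; S["bm_pre", "R_conv"] <- 1
  S["bm_pre", "R_bio"] <- -1
  ReactionUniverse(S, reversible = FALSE,
                   transport = c(TRUE, FALSE, FALSE),
                   biomassId = "R_bio",
                   extracellular = c(TRUE, FALSE, FALSE))
})

toyMetabolism <- function()
  Metabolism(c("T_glc", "R_conv", "R_bio"), "glc_ext", label = "toy",
             universe = toyUniverse())

# random member metabolism of a universe: biomass + a random reaction subset
randomMetabolism <- function(universe, size, primary, label = "rnd") {
  ids <- setdiff(reactionIds(universe), biomassId(universe))
  Metabolism(c(sample(ids, size), biomassId(universe)), primary,
             label = label, universe = universe)
}
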
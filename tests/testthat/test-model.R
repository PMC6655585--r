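# Domain types, system assembly, and the reaction-table / SBML readers.

test_that("toy system assembles with the expected columns and optimum", {
  u <- toyUniverse()
  m <- toyMetabolism()
  sys <- buildSystem(m, u, "glc_ext")
  # 3 irreversible flux columns + uptake/secretion for the one
  # extracellular metabolite
  expect_equal(sum(sys$cols$kind == "flux_fwd"), 3)
  expect_equal(sum(sys$cols$kind == "flux_rev"), 0)
  expect_setequal(sys$cols$kind[sys$cols$target == "glc_ext"],
                  c("uptake", "secretion"))
  # the only uptake column is the bounded carbon exchange
  expect_equal(sys$upper[sys$cols$kind == "uptake"], 10)
  expect_equal(sum(sys$objective != 0), 1)
  # yield is 1 biomass per carbon, uptake bound 10 => growth 10
  expect_equal(growth(m, u, "glc_ext"), 10)
})

test_that("a metabolism without carbon transport cannot import the source", {
  u <- toyUniverse()
  m <- Metabolism(c("R_conv", "R_bio"), "glc_ext", universe = u)
  sys <- buildSystem(m, u, "glc_ext")
  # no flux column consumes the extracellular carbon row
  row <- match("glc_ext", sys$rows)
  fluxCols <- which(sys$cols$kind %in% c("flux_fwd", "flux_rev"))
  expect_true(all(as.matrix(sys$A)[row, fluxCols] == 0))
  expect_equal(growth(m, u, "glc_ext"), 0)
})

test_that("validity catches broken universes and metabolisms", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a_ext", "b"), "T1"))
  expect_error(ReactionUniverse(S, FALSE, TRUE, biomassId = "nope",
                                extracellular = c(TRUE, FALSE)),
               "biomass")
  # transport flag without extracellular contact
  S2 <- cbind(S, R_bio = c(0, -1))
  expect_error(ReactionUniverse(S2, FALSE, c(FALSE, TRUE),
                                biomassId = "R_bio",
                                extracellular = c(TRUE, FALSE)),
               "transport")
  expect_error(Metabolism("nope", "glc_ext", universe = toyUniverse()),
               "not in universe")
  expect_error(GrowthMedium("a", medium = "a"), "carbon source")
  expect_error(GrowthMedium("a", uptakeBound = -1), "positive|uptakeBound")
})

test_that("mass balance holds at the optimum of sampled systems", {
  g <- defaultGen()
  sys <- buildSystem(g$seeds[[2]], g$universe,
                     primaryCarbonSource(g$seeds[[2]]))
  sol <- solveSystem(sys)
  expect_equal(sol$status, "optimal")
  expect_lt(max(abs(as.numeric(sys$A %*% sol$x))), 1e-6)
})

test_that("removing a reaction never increases the optimal biomass flux", {
  g <- tinyGen(); u <- g$universe
  m <- g$seeds[[1]]
  base <- growth(m, u, "C1_ext")
  set.seed(5)
  ids <- setdiff(reactionIds(m), biomassId(u))
  for (r in sample(ids, min(100, length(ids)), replace = TRUE)) {
    m2 <- Metabolism(setdiff(reactionIds(m), r), "C1_ext", universe = u)
    expect_lte(growth(m2, u, "C1_ext"), base + 1e-9)
  }
})

test_that("reaction-table writing and reading round-trips exactly", {
  g <- defaultGen()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeUniverse(g$universe, path)
  u2 <- readUniverse(path)
  expect_setequal(reactionIds(u2), reactionIds(g$universe))
  expect_equal(biomassId(u2), biomassId(g$universe))
  expect_equal(isTransport(u2)[reactionIds(g$universe)],
               isTransport(g$universe))
  expect_equal(isReversible(u2)[reactionIds(g$universe)],
               isReversible(g$universe))
  S1 <- stoichiometry(g$universe)
  S2 <- stoichiometry(u2)[rownames(S1), colnames(S1)]
  expect_equal(as.matrix(S2), as.matrix(S1))
  expect_equal(sort(names(which(isExtracellular(u2)))),
               sort(names(which(isExtracellular(g$universe)))))
})

test_that("duplicate reaction ids in a table are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# SynFBA-universe v1", "# biomass: B",
               "# extracellular: a_ext",
               "reaction_id\tequation\tflags",
               "R1\ta_ext => b\ttransport",
               "R1\tb => c\t-",
               "B\tc => \tbiomass"), path)
  expect_error(readUniverse(path), "duplicated")
})

test_that("the SBML importer reads species, stoichiometry and flags", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy"><listOfCompartments>',
    '<compartment id="c" constant="true"/><compartment id="e" constant="true"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="glc_e" compartment="e"/>',
    '<species id="glc_c" compartment="c"/>',
    '<species id="pyr_c" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="T_glc" reversible="false">',
    '<listOfReactants><speciesReference species="glc_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="glc_c" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_glyc" reversible="true">',
    '<listOfReactants><speciesReference species="glc_c" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="pyr_c" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_biomass" reversible="false">',
    '<listOfReactants><speciesReference species="pyr_c" stoichiometry="2"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), path)
  u <- readUniverse(path, format = "sbml")
  # independent count of reaction records in the document
  nRef <- length(grep("<reaction ", readLines(path)))
  expect_equal(length(reactionIds(u)), nRef)
  expect_equal(biomassId(u), "R_biomass")
  expect_true(isTransport(u)["T_glc"])
  expect_false(isTransport(u)["R_glyc"])
  expect_true(isReversible(u)["R_glyc"])
  expect_equal(stoichiometry(u)["pyr_c", "R_glyc"], 2)
  expect_true(isExtracellular(u)["glc_e"])
  # glucose yields 2 pyruvate, biomass needs 2: growth = uptake bound
  m <- Metabolism(reactionIds(u), "glc_e", universe = u)
  expect_equal(growth(m, u, "glc_e"), 10)
})

test_that("metabolism populations round-trip through JSON-lines", {
  g <- tinyGen()
  path <- withr::local_tempfile(fileext = ".jsonl")
  writePopulation(g$seeds, path)
  back <- readPopulation(path, g$universe)
  expect_equal(length(back), length(g$seeds))
  for (nm in names(back)) {
    orig <- g$seeds[[which(vapply(g$seeds, metabolismLabel, "") ==
                             metabolismLabel(back[[nm]]))]]
    expect_setequal(reactionIds(back[[nm]]), reactionIds(orig))
    expect_equal(primaryCarbonSource(back[[nm]]), primaryCarbonSource(orig))
  }
})
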
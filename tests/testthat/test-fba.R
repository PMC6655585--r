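# Growth, viability, essentiality and zero-flux identification.

test_that("growth matches hand-computed pathway yields", {
  # toy: unit-yield chain, uptake bound 10 -> growth 10
  expect_equal(growth(toyMetabolism(), toyUniverse(), "glc_ext"), 10)
  # halved uptake bound halves the yield (linearity)
  expect_equal(growth(toyMetabolism(), toyUniverse(),
                      GrowthMedium("glc_ext", uptakeBound = 2.5)), 2.5)
  # synthetic seed: every pathway coefficient is 1, so growth = uptake
  g <- defaultGen()
  for (k in c(1, 3))
    expect_equal(growth(g$seeds[[k]], g$universe, g$sources[k]), 10)
})

test_that("growth at exactly the threshold counts as zero (strict exceedance)", {
  env <- GrowthMedium("glc_ext", uptakeBound = 1e-3)
  # LP optimum is exactly 0.001; the rule demands strict exceedance
  expect_equal(growth(toyMetabolism(), toyUniverse(), env), 0)
  expect_false(isViable(toyMetabolism(), toyUniverse(), env))
  env2 <- GrowthMedium("glc_ext", uptakeBound = 2e-3)
  expect_equal(growth(toyMetabolism(), toyUniverse(), env2), 2e-3)
  expect_true(isViable(toyMetabolism(), toyUniverse(), env2))
})

test_that("a biomass-only metabolism is not viable anywhere", {
  g <- tinyGen()
  m <- Metabolism(biomassId(g$universe), "C1_ext", universe = g$universe)
  expect_false(isViable(m, g$universe, "C1_ext"))
  expect_length(viabilityProfile(m, g$universe, g$sources), 0)
})

test_that("viability profiles contain the primary and engineered extras", {
  g <- defaultGen()
  s <- g$seeds[[2]]
  expect_true(g$sources[2] %in% viabilityProfile(s, g$universe, g$sources))
  # engineer a metabolism viable on exactly 2 of the 5 sources
  spec <- g$spec
  ids <- unique(c(SynFBA:::.routeIds(spec, 1), SynFBA:::.routeIds(spec, 4),
                  "R_biomass"))
  m <- Metabolism(ids, g$sources[1], universe = g$universe)
  expect_setequal(viabilityProfile(m, g$universe, g$sources),
                  g$sources[c(1, 4)])
})

test_that("viability is monotone under reaction addition", {
  g <- defaultGen()
  set.seed(21)
  m <- g$seeds[[1]]
  p0 <- viabilityProfile(m, g$universe, g$sources)
  m2 <- augmentWithRandomReactions(m, g$universe, 10)
  p2 <- viabilityProfile(m2, g$universe, g$sources)
  expect_true(all(p0 %in% p2))
})

test_that("essential reactions: single path means every reaction is essential", {
  g <- tinyGen()  # redundancy 1
  spec <- g$spec
  route <- c(SynFBA:::.routeIds(spec, 1), "R_biomass")
  m <- Metabolism(route, "C1_ext", universe = g$universe)
  expect_setequal(essentialReactions(m, g$universe, "C1_ext"), route)
})

test_that("parallel routes remove essentiality of their private reactions", {
  g <- defaultGen()  # redundancy 2
  spec <- g$spec
  ids <- unique(c(SynFBA:::.allRouteIds(spec, 1), "R_biomass"))
  m <- Metabolism(ids, "C1_ext", universe = g$universe)
  ess <- essentialReactions(m, g$universe, "C1_ext")
  # the sole transport is essential; duplicated pathway copies are not
  expect_true("T1_1" %in% ess)
  expect_false(any(c("R1_1_1", "R1_1_2", "RD_1", "RD_2") %in% ess))
  expect_true("R_biomass" %in% ess)
  # delete-and-resolve oracle agrees reaction by reaction
  for (r in c("R1_2_1", "T1_1", "RZ1_2")) {
    m2 <- Metabolism(setdiff(ids, r), "C1_ext", universe = g$universe)
    expect_equal(r %in% ess, !isViable(m2, g$universe, "C1_ext"))
  }
})

test_that("essentiality requires a viable metabolism", {
  g <- tinyGen()
  m <- Metabolism(biomassId(g$universe), "C1_ext", universe = g$universe)
  expect_error(essentialReactions(m, g$universe, "C1_ext"), "not viable")
})

test_that("zero-flux reactions: linear toy has none, side branches are caught", {
  expect_length(zeroFluxReactions(toyMetabolism(), toyUniverse(), "glc_ext"),
                0)
  # toy plus a dangling conversion off the pathway
  S <- matrix(0, 4, 4,
              dimnames = list(c("glc_ext", "glc", "bm_pre", "waste"),
                              c("T_glc", "R_conv", "R_bio", "R_dangle")))
  S["glc_ext", "T_glc"] <- -1; S["glc", "T_glc"] <- 1
  S["glc", "R_conv"] <- -1; S["bm_pre", "R_conv"] <- 1
  S["bm_pre", "R_bio"] <- -1
  S["glc", "R_dangle"] <- -1; S["waste", "R_dangle"] <- 1
  u <- ReactionUniverse(S, FALSE, c(TRUE, FALSE, FALSE, FALSE), "R_bio",
                        c(TRUE, FALSE, FALSE, FALSE))
  m <- Metabolism(colnames(S), "glc_ext", universe = u)
  expect_equal(zeroFluxReactions(m, u, "glc_ext"), "R_dangle")
  # postcondition: deleting a zero-flux reaction preserves viability
  m2 <- Metabolism(setdiff(colnames(S), "R_dangle"), "glc_ext", universe = u)
  expect_true(isViable(m2, u, "glc_ext"))
})

test_that("zero-flux and essential sets never overlap, and zero-flux is a
           superset check against brute-force deletions", {
  g <- defaultGen()
  set.seed(31)
  m <- g$seeds[[3]]
  ess <- essentialReactions(m, g$universe, g$sources[3])
  zf <- zeroFluxReactions(m, g$universe, g$sources[3])
  expect_length(intersect(ess, zf), 0)
  # every FVA-zero reaction is deletable one at a time (brute force)
  for (r in zf) {
    m2 <- Metabolism(setdiff(reactionIds(m), r), primaryCarbonSource(m),
                     universe = g$universe)
    expect_true(isViable(m2, g$universe, g$sources[3]))
  }
})

test_that("LP viability agrees with path enumeration on a tiny universe", {
  # tiny universe is small enough to enumerate: a metabolism is viable on
  # source k iff it contains the transport, every upstream segment, the
  # trunk and the biomass reaction (single-copy pathways, no redundancy)
  g <- tinyGen()
  spec <- g$spec
  enumViable <- function(ids, k)
    all(c(SynFBA:::.routeIds(spec, k), "R_biomass") %in% ids)
  set.seed(41)
  all <- reactionIds(g$universe)
  for (i in 1:40) {
    ids <- c(sample(setdiff(all, "R_biomass"), sample(3:9, 1)), "R_biomass")
    m <- Metabolism(ids, "C1_ext", universe = g$universe)
    for (k in 1:2)
      expect_equal(isViable(m, g$universe, g$sources[k]),
                   enumViable(ids, k))
  }
})
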
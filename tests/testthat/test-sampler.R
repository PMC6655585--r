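# MCMC reaction-swap sampler, size reduction, augmentation control.

test_that("swap steps preserve size, never touch biomass, and reject
           viability-breaking proposals", {
  g <- defaultGen(); u <- g$universe
  set.seed(1)
  m <- g$seeds[[1]]
  n0 <- length(reactionIds(m))
  for (i in 1:200) {
    st <- swapStep(m, u)
    expect_length(reactionIds(st$metabolism), n0)
    expect_true(biomassId(u) != st$removed)
    expect_true(biomassId(u) %in% reactionIds(st$metabolism))
    if (!st$accepted) expect_identical(reactionIds(st$metabolism),
                                       reactionIds(m))
    m <- st$metabolism
  }
  expect_true(isViable(m, u, primaryCarbonSource(m)))
})

test_that("rejected swaps are exactly the viability-breaking ones", {
  g <- tinyGen(); u <- g$universe
  # single-copy pathways: deleting any primary-route reaction breaks
  # viability, so an accepted step can never have removed one
  set.seed(2)
  route <- c(SynFBA:::.routeIds(g$spec, 1), "R_biomass")
  m <- g$seeds[[1]]
  for (i in 1:100) {
    st <- swapStep(m, u)
    if (st$accepted) {
      expect_false(st$removed %in% route)
      m <- st$metabolism
    } else {
      # the reverted metabolism must indeed be nonviable with the swap
      broken <- Metabolism(c(setdiff(reactionIds(m), st$removed), st$added),
                           "C1_ext", universe = u)
      expect_false(isViable(broken, u, "C1_ext"))
    }
  }
})

test_that("swap step errors at universe saturation", {
  g <- tinyGen(); u <- g$universe
  m <- Metabolism(reactionIds(u), "C1_ext", universe = u)
  expect_error(swapStep(m, u), "saturation")
})

test_that("zero-step walks return the start; seeds decide the endpoint", {
  g <- defaultGen(); u <- g$universe
  w0 <- randomWalk(g$seeds[[1]], u, 0)
  expect_identical(reactionIds(w0@metabolism), reactionIds(g$seeds[[1]]))
  set.seed(101); w1 <- randomWalk(g$seeds[[1]], u, 300)
  set.seed(101); w1b <- randomWalk(g$seeds[[1]], u, 300)
  set.seed(202); w2 <- randomWalk(g$seeds[[1]], u, 300)
  expect_identical(sort(reactionIds(w1@metabolism)),
                   sort(reactionIds(w1b@metabolism)))
  expect_false(setequal(reactionIds(w1@metabolism),
                        reactionIds(w2@metabolism)))
})

test_that("walks stay viable, keep their size, and diverge from the start", {
  g <- defaultGen(); u <- g$universe
  set.seed(5)
  shared <- replicate(10, {
    w <- randomWalk(g$seeds[[2]], u, 250, recordTrace = TRUE,
                    traceEvery = 25)
    expect_true(isViable(w@metabolism, u, g$sources[2]))
    expect_length(reactionIds(w@metabolism),
                  length(reactionIds(g$seeds[[2]])))
    expect_true(w@accepted <= w@steps)
    w@trace$sharedFraction
  })
  # shared fraction with the start declines in expectation until the walk
  # equilibrates: early intervals fall monotonically, the end sits well
  # below the start
  meanTrace <- rowMeans(shared)
  expect_true(all(diff(meanTrace[1:4]) < 0))
  expect_lt(tail(meanTrace, 1), 0.8 * meanTrace[1])
})

test_that("independently walked metabolisms are more diverged from each
           other than from the shared seed", {
  g <- defaultGen(); u <- g$universe
  set.seed(6)
  ends <- replicate(6, reactionIds(randomWalk(g$seeds[[1]], u,
                                              300)@metabolism),
                    simplify = FALSE)
  seedIds <- reactionIds(g$seeds[[1]])
  toSeed <- mean(vapply(ends, function(e) length(intersect(e, seedIds)),
                        numeric(1)))
  pairsShared <- combn(length(ends), 2, function(ij)
    length(intersect(ends[[ij[1]]], ends[[ij[2]]])))
  expect_lt(mean(pairsShared), toSeed)
})

test_that("reduction reaches the target, keeps viability, recomputes
           removability, and reports unreachable floors", {
  g <- defaultGen(); u <- g$universe
  m <- g$seeds[[1]]
  expect_identical(reduceMetabolism(m, u, length(reactionIds(m))), m)
  set.seed(8)
  r <- reduceMetabolism(m, u, 20)
  expect_length(reactionIds(r), 20)
  expect_true(isViable(r, u, primaryCarbonSource(r)))
  # a single linear pathway cannot be reduced below its own length
  tg <- tinyGen()
  route <- c(SynFBA:::.routeIds(tg$spec, 1), "R_biomass")
  lin <- Metabolism(route, "C1_ext", universe = tg$universe)
  expect_error(reduceMetabolism(lin, tg$universe, 2), "floor")
})

test_that("random augmentation adds exactly k reactions without constraint", {
  g <- defaultGen(); u <- g$universe
  m <- g$seeds[[1]]
  set.seed(9)
  expect_identical(reactionIds(augmentWithRandomReactions(m, u, 0)),
                   reactionIds(m))
  nAbsent <- length(setdiff(reactionIds(u), reactionIds(m)))
  full <- augmentWithRandomReactions(m, u, nAbsent)
  expect_setequal(reactionIds(full), reactionIds(u))
  expect_error(augmentWithRandomReactions(m, u, nAbsent + 1), "exceeds")
  a <- augmentWithRandomReactions(m, u, 5)
  expect_length(setdiff(reactionIds(a), reactionIds(m)), 5)
})

test_that("population sampling labels, sizes and reproducibility", {
  g <- tinyGen(); u <- g$universe
  pop <- samplePopulation(u, g$seeds, perSource = 3, nSteps = 30, seed = 4)
  expect_length(pop$population, 6)
  expect_setequal(names(pop$population),
                  as.vector(outer(g$sources, 1:3, paste, sep = ".")))
  for (m in pop$population)
    expect_true(isViable(m, u, primaryCarbonSource(m)))
  expect_equal(nrow(pop$acceptance), 6)
  pop2 <- samplePopulation(u, g$seeds, perSource = 3, nSteps = 30, seed = 4)
  expect_identical(lapply(pop$population, reactionIds),
                   lapply(pop2$population, reactionIds))
})
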
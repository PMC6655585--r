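# Pooling, joint growth, syntrophy detection, explicit exchange, minimal
# exchange, transport restoration and syntrophy essentiality.

test_that("pooling is idempotent, symmetric, and unions the reaction sets", {
  g <- defaultGen()
  a <- g$seeds[[1]]; b <- g$seeds[[2]]
  expect_setequal(reactionIds(poolMetabolisms(a, a)), reactionIds(a))
  expect_setequal(reactionIds(poolMetabolisms(a, b)),
                  reactionIds(poolMetabolisms(b, a)))
  expect_setequal(reactionIds(poolMetabolisms(a, b)),
                  union(reactionIds(a), reactionIds(b)))
  expect_lte(length(reactionIds(poolMetabolisms(a, b))),
             length(reactionIds(a)) + length(reactionIds(b)))
})

test_that("joint growth is symmetric and reduces to single growth on a
           self-pair", {
  g <- defaultGen(); u <- g$universe
  a <- g$seeds[[1]]; b <- g$seeds[[3]]
  for (ck in g$sources[1:3]) {
    expect_equal(jointGrowth(a, b, u, ck), jointGrowth(b, a, u, ck))
  }
  expect_equal(jointGrowth(a, a, u, g$sources[1]),
               growth(a, u, g$sources[1]))
  expect_gt(jointGrowth(a, a, u, primaryCarbonSource(a)), 1e-3)
})

test_that("complementary halves are syntrophic exactly on the designed source", {
  g <- defaultGen(); u <- g$universe
  pl <- plantComplementarity(g, "C4_ext")
  expect_equal(growth(pl$a, u, "C4_ext"), 0)
  expect_equal(growth(pl$b, u, "C4_ext"), 0)
  expect_gt(jointGrowth(pl$a, pl$b, u, "C4_ext"), 1e-3)
  rec <- detectSyntrophy(pl$a, pl$b, u, g$sources)
  expect_equal(rec$syntrophicSources, "C4_ext")
  # symmetric in the pair
  rec2 <- detectSyntrophy(pl$b, pl$a, u, g$sources)
  expect_setequal(rec$syntrophicSources, rec2$syntrophicSources)
})

test_that("self-pairs and one-sided viability are never syntrophic", {
  g <- defaultGen(); u <- g$universe
  a <- g$seeds[[1]]
  expect_equal(detectSyntrophy(a, a, u, g$sources)$nJointAdditional, 0L)
  # a is viable on C1, so C1 is excluded for any pair involving a
  pl <- plantComplementarity(g, "C2_ext")
  rec <- detectSyntrophy(a, pl$b, u, g$sources)
  expect_false("C1_ext" %in% rec$syntrophicSources)
})

test_that("explicit exchange: empty set decouples, full set equals pooling,
           growth is monotone in the allowed set", {
  g <- defaultGen(); u <- g$universe
  pl <- plantComplementarity(g, "C3_ext", primaryA = "C1_ext",
                             primaryB = "C2_ext")
  a <- pl$a; b <- pl$b
  # decoupled: the better individual growth (here on b's primary)
  expect_equal(explicitExchangeGrowth(a, b, u, "C2_ext", character()),
               max(growth(a, u, "C2_ext"), growth(b, u, "C2_ext")))
  # full exchange reproduces the pooled optimum
  for (ck in c("C1_ext", "C3_ext")) {
    expect_lt(abs(explicitExchangeGrowth(a, b, u, ck) -
                    jointGrowth(a, b, u, ck)), 1e-6)
  }
  # single designed intermediate suffices, and adding metabolites never hurts
  g1 <- explicitExchangeGrowth(a, b, u, "C3_ext", pl$cutMetabolite)
  expect_gt(g1, 1e-3)
  g2 <- explicitExchangeGrowth(a, b, u, "C3_ext",
                               c(pl$cutMetabolite, "Z1", "P1"))
  expect_gte(g2, g1 - 1e-9)
})

test_that("minimal exchange on the planted cut is one metabolite, by both
           methods", {
  g <- defaultGen(); u <- g$universe
  pl <- plantComplementarity(g, "C5_ext")
  for (method in c("bnb", "exhaustive")) {
    me <- minExchangedMetabolites(pl$a, pl$b, u, "C5_ext", method = method)
    expect_equal(me$count, 1L)
    expect_equal(me$exchangedMetabolites, pl$cutMetabolite)
  }
  # precondition: no syntrophy, no minimal exchange
  expect_error(minExchangedMetabolites(g$seeds[[1]], g$seeds[[2]], u,
                                       "C1_ext"), "no syntrophy")
})

test_that("branch-and-bound equals subset enumeration on random chain splits", {
  # random bipartitions of a single-copy pathway force minima > 1:
  # each ownership switch along the chain costs one transferred metabolite
  g <- tinyGen(); u <- g$universe
  spec <- g$spec
  set.seed(12)
  for (trial in 1:10) {
    k <- sample(1:2, 1)
    segs <- sprintf("R%d_%d_1", k, seq_len(spec$pathwayLength))
    trunk <- c("RD_1", "R_biomass")
    ownA <- c(TRUE, sample(c(TRUE, FALSE), spec$pathwayLength - 1,
                           replace = TRUE))
    if (all(ownA)) ownA[spec$pathwayLength] <- FALSE
    aIds <- c(sprintf("T%d_1", k), segs[ownA], trunk)
    bIds <- c(segs[!ownA], trunk)
    src <- g$sources[k]
    a <- Metabolism(aIds, src, universe = u)
    b <- Metabolism(bIds, src, universe = u)
    if (growth(a, u, src) > 0 || growth(b, u, src) > 0) next
    m1 <- minExchangedMetabolites(a, b, u, src, method = "bnb")
    m2 <- minExchangedMetabolites(a, b, u, src, method = "exhaustive")
    expect_equal(m1$count, m2$count)
    expect_gte(m1$count, 1L)
  }
})

test_that("transport restoration is idempotent and recovers lost sources", {
  g <- defaultGen(); u <- g$universe
  s <- g$seeds[[1]]
  expect_setequal(reactionIds(restoreTransport(s, u, "C1_ext")),
                  reactionIds(s))
  # strip every transport of C2 from a metabolism that has the rest of the
  # C2 route: restoring transport recovers viability
  ids <- unique(c(reactionIds(s), SynFBA:::.allRouteIds(g$spec, 2)))
  tr2 <- reactionIds(u)[isTransport(u) &
                          stoichiometry(u)["C2_ext", ] != 0]
  crippled <- Metabolism(setdiff(ids, tr2), "C1_ext", universe = u)
  expect_false(isViable(crippled, u, "C2_ext"))
  fixed <- restoreTransport(crippled, u, g$sources)
  expect_true(isViable(fixed, u, "C2_ext"))
  p0 <- viabilityProfile(crippled, u, g$sources)
  p1 <- viabilityProfile(fixed, u, g$sources)
  expect_true(all(p0 %in% p1))
  expect_error(restoreTransport(s, u, "P1"), "no transport")
})

test_that("syntrophy-essential reactions include biomass and the cross-fed
           producer, with consistent bookkeeping", {
  g <- defaultGen(); u <- g$universe
  pl <- plantComplementarity(g, "C3_ext", primaryA = "C1_ext",
                             primaryB = "C2_ext")
  se <- syntrophyEssentialReactions(pl$a, pl$b, u, "C3_ext")
  expect_true(se$essentialForSyntrophy[se$reaction == "R_biomass"])
  expect_true(se$essentialForSyntrophy[se$reaction == pl$producerReaction])
  # removing the producer indeed destroys the syntrophy
  a2 <- Metabolism(setdiff(reactionIds(pl$a), pl$producerReaction),
                   primaryCarbonSource(pl$a), universe = u)
  expect_equal(jointGrowth(a2, pl$b, u, "C3_ext"), 0)
  # partition bookkeeping covers the pooled set exactly
  expect_setequal(se$reaction,
                  union(reactionIds(pl$a), reactionIds(pl$b)))
  expect_equal(se$inA | se$inB, rep(TRUE, nrow(se)))
})

test_that("pair records match direct detection", {
  g <- tinyGen(); u <- g$universe
  pl <- plantComplementarity(g, "C1_ext", primaryA = "C2_ext",
                             primaryB = "C2_ext")
  pop <- list(pl$a, pl$b, g$seeds[[1]])
  names(pop) <- vapply(pop, metabolismLabel, character(1))
  pairs <- pairSyntrophy(pop, u, g$sources)
  expect_equal(nrow(pairs), 3)
  for (r in seq_len(nrow(pairs))) {
    rec <- detectSyntrophy(pop[[pairs$labelA[r]]], pop[[pairs$labelB[r]]],
                           u, g$sources)
    got <- strsplit(pairs$syntrophicSources[r], ";")[[1]]
    expect_setequal(got[nzchar(got)], rec$syntrophicSources)
  }
})
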
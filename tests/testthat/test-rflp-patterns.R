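draI <- restrictionEnzyme("DraI", "TTTAAA", 3)

test_that("toVisibleBands drops invisible fragments and merges comigrants", {
  g <- gelModel()
  expect_identical(bands(toVisibleBands(c(200, 150, 88), g)),
                   c(200L, 150L, 88L))
  expect_identical(bands(toVisibleBands(c(100, 100, 38), g)), 100L)
  expect_identical(bands(toVisibleBands(c(160, 158, 60), g)), c(159L, 60L))
  expect_identical(
    bands(toVisibleBands(c(160, 158, 60), gelModel(coMigrationTol = 1))),
    c(160L, 158L, 60L))
  expect_error(toVisibleBands(c(30, 12), g), class = "EmptyPattern")
})

test_that("single-linkage chains merge transitively", {
  # 100, 104, 108: adjacent gaps 4 <= 5 chain into one band even though the
  # extremes differ by 8
  expect_identical(bands(toVisibleBands(c(100, 104, 108), gelModel())), 104L)
})

test_that("patternsEqual compares positionally within tolerance", {
  g <- gelModel()
  expect_true(patternsEqual(rflpPattern(438), rflpPattern(438), g))
  expect_true(patternsEqual(rflpPattern(c(200, 150, 88)),
                            rflpPattern(c(203, 149, 86)), g))
  expect_false(patternsEqual(rflpPattern(c(200, 150, 88)),
                             rflpPattern(c(203, 149, 86)),
                             gelModel(coMigrationTol = 1)))
  expect_false(patternsEqual(rflpPattern(c(200, 150)),
                             rflpPattern(c(200, 150, 88)), g))
  expect_error(
    patternsEqual(rflpPattern(438, enzyme = "DraI"),
                  rflpPattern(438, enzyme = "AluI"), g),
    class = "IncomparablePatterns")
  # reflexive and symmetric on random patterns
  set.seed(31)
  for (i in 1:50) {
    a <- rflpPattern(sample(40:400, sample(1:4, 1)))
    b <- rflpPattern(sample(40:400, sample(1:4, 1)))
    expect_true(patternsEqual(a, a, g))
    expect_identical(patternsEqual(a, b, g), patternsEqual(b, a, g))
  }
})

test_that("groupPatterns recovers planted per-species pattern counts", {
  planted <- list(
    "species A" = list(c(200L, 150L, 88L)),
    "species B" = list(c(300L, 138L), c(438L)),
    "species C" = list(c(100L, 100L, 238L))
  )
  cfg <- syntheticConfig(planted, seqsPerSpecies = 10, seed = 99)
  sim <- simulateAmplicons(cfg)
  cat_ <- groupPatterns(sim$sequences, draI)
  expect_identical(patternCounts(cat_),
                   c("species A" = 1L, "species B" = 2L, "species C" = 1L))
  # representatives are the first members in input order
  reps <- as.data.frame(cat_)
  expect_identical(reps$representative_id[1], "species_A_01")
  expect_identical(sum(reps$n_members), 30L)
})

test_that("a single sequence yields a one-pattern catalog", {
  cfg <- syntheticConfig(list(X = list(438L)), seqsPerSpecies = 1, seed = 5)
  sim <- simulateAmplicons(cfg)
  cat_ <- groupPatterns(sim$sequences, draI)
  expect_length(patterns(cat_), 1)
  expect_identical(patternCounts(cat_), c(X = 1L))
})

test_that("pattern counts never increase with co-migration tolerance", {
  set.seed(77)
  for (rep in 1:5) {
    cfg <- syntheticConfig(randomPlanted(3), seqsPerSpecies = 6,
                           substitutionRate = 0.01, seed = 1000 + rep)
    sim <- simulateAmplicons(cfg)
    prev <- Inf
    for (tol in seq(0, 10, by = 2)) {
      n <- length(patterns(groupPatterns(
        sim$sequences, draI, gelModel(coMigrationTol = tol))))
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("at tol 0 and minVisible 1 grouping partitions by fragment multiset", {
  set.seed(88)
  cfg <- syntheticConfig(randomPlanted(2), seqsPerSpecies = 8,
                         substitutionRate = 0.02, seed = 41)
  sim <- simulateAmplicons(cfg)
  g0 <- gelModel(minVisible = 1, coMigrationTol = 0)
  cat_ <- groupPatterns(sim$sequences, draI, g0)
  sp <- S4Vectors::mcols(sim$sequences)$species
  expected <- 0L
  for (s in unique(sp)) {
    keys <- vapply(which(sp == s), function(i)
      paste(fragments(digestLinear(sim$sequences[i], draI)), collapse = ","),
      character(1))
    expected <- expected + length(unique(keys))
  }
  expect_identical(length(patterns(cat_)), expected)
})

test_that("virtual gels are deterministic and canonicalize band order", {
  g1 <- renderGel(list(c(300L, 100L)), quiet = TRUE)
  g2 <- renderGel(list(c(100L, 300L)), quiet = TRUE)
  expect_identical(g1$svg, g2$svg)
  expect_identical(g1$text, g2$text)
  # identical lanes render identically
  g3 <- renderGel(list(c(200L, 88L), c(200L, 88L)), quiet = TRUE)
  lanes <- regmatches(g3$svg, gregexpr('<rect x="[0-9]+" y="[0-9.]+"',
                                       g3$svg))[[1]]
  ys <- sub('.*y="([0-9.]+)".*', "\\1", lanes)
  xs <- sub('.*x="([0-9]+)".*', "\\1", lanes)
  laneYs <- split(ys, xs)
  expect_identical(laneYs[["70"]], laneYs[["130"]])
})

test_that("migration position decreases strictly with fragment size", {
  sizes <- c(500L, 400L, 300L, 200L, 100L, 50L)
  g <- renderGel(list(sizes), ladder = c(600L, 40L), quiet = TRUE)
  rects <- regmatches(g$svg, gregexpr('<rect x="70" y="[0-9.]+"', g$svg))[[1]]
  ys <- as.numeric(sub('.*y="([0-9.]+)".*', "\\1", rects))
  expect_identical(order(ys), seq_along(sizes))  # larger bands sit higher
  expect_true(all(diff(ys) > 0))
})
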
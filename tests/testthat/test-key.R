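test_that("a two-pattern catalog builds a single decisive couplet", {
  cat_ <- patternCatalog(list(A = 438L, B = c(300L, 138L)),
                         enzyme = "DraI", region = "16S")
  k <- buildKey(cat_)
  expect_length(couplets(k), 1)
  expect_identical(applyKey(k, 438L)$species, "A")
  expect_identical(applyKey(k, c(300L, 138L))$species, "B")
})

test_that("species sharing one pattern are refused with the pair named", {
  cat_ <- patternCatalog(list("H. longicornis" = 438L,
                              "H. asiatica" = 438L))
  err <- tryCatch(buildKey(cat_), error = function(e) e)
  expect_s3_class(err, "IndistinguishableSpecies")
  expect_setequal(err$pair, c("H. longicornis", "H. asiatica"))
})

test_that("the built-in North American 16S key matches the printed key", {
  k <- naKey16S()
  expect_length(couplets(k), 5)
  expect_identical(k@enzyme, "DraI")
  expect_identical(k@region, "16S")

  r1 <- applyKey(k, c(430, 120))
  expect_identical(r1$species, "H. leporispalustris")
  expect_identical(r1$trace, c(1L, 3L))

  r2 <- applyKey(k, c(160, 150, 128))
  expect_identical(r2$species, "H. longicornis")
  expect_identical(r2$trace, c(1L, 2L, 5L))

  # three bands, largest > 200, middle near 175 -> H. juxtakochi via 1-2-4
  r3 <- applyKey(k, c(220, 175, 43))
  expect_identical(r3$species, "H. juxtakochi")
  expect_identical(r3$trace, c(1L, 2L, 4L))

  # two bands, largest < 300 -> H. chordeilis
  expect_identical(applyKey(k, c(250, 120))$species, "H. chordeilis")
})

test_that("uncovered leads stop the walk as undetermined", {
  k <- naKey16S()
  # a 28 bp band is below the visibility limit: a single visible band
  # satisfies neither lead of couplet 1
  r <- applyKey(k, c(410, 28))
  expect_identical(r$species, "undetermined")
  expect_identical(r$stalledAt, 1L)
  # the printed key's couplet 3 covers >400 and <300 only
  r2 <- applyKey(k, c(350, 88))
  expect_identical(r2$species, "undetermined")
  expect_identical(r2$stalledAt, 3L)
})

test_that("bands near a strict threshold raise an ambiguity warning", {
  k <- naKey16S()
  r <- applyKey(k, c(199, 120))   # couplet 3 compares 199 with 300/400... no
  # couplet 1 -> 3 (two bands); 199 < 300 -> H. chordeilis, no threshold graze
  expect_identical(r$species, "H. chordeilis")
  # 402 grazes the >400 threshold at couplet 3
  r2 <- applyKey(k, c(402, 36 + 5))
  expect_identical(r2$species, "H. leporispalustris")
  expect_true(length(r2$warnings) > 0)
})

test_that("key construction classifies every training pattern back (small)", {
  set.seed(404)
  for (i in 1:30) {
    cat_ <- randomGridCatalog(sample(2:6, 1))
    k <- buildKey(cat_)
    for (p in patterns(cat_)) {
      expect_identical(applyKey(k, p)$species, p@species)
    }
    # every couplet reachable: validity already enforces termination; check
    # that each species appears exactly once as a leaf per distinct pattern
    leaves <- unlist(lapply(couplets(k), function(co)
      c(if (!co@toCoupletA) co@consequentA, if (!co@toCoupletB) co@consequentB)))
    expect_identical(sort(leaves),
                     sort(vapply(patterns(cat_), speciesLabel, character(1))))
  }
})

test_that("classification is robust to sub-tolerance band jitter", {
  set.seed(505)
  for (i in 1:10) {
    cat_ <- randomGridCatalog(sample(2:5, 1))
    k <- buildKey(cat_)
    jit <- k@gel@coMigrationTol - 1L
    for (p in patterns(cat_)) {
      for (rep in 1:3) {
        wob <- bands(p) + sample(c(-jit, 0L, jit), length(bands(p)),
                                 replace = TRUE)
        expect_identical(applyKey(k, wob)$species, p@species)
      }
    }
  }
})

test_that("key serialization round-trips exactly", {
  set.seed(606)
  for (i in 1:20) {
    k <- buildKey(randomGridCatalog(sample(2:6, 1)))
    txt <- formatKey(k)
    k2 <- parseKey(txt, text = TRUE)
    expect_identical(formatKey(k2), txt)
    # and the reparsed key behaves identically
    for (p in patterns(randomGridCatalog(3))) {
      expect_identical(applyKey(k2, bands(p))$species,
                       applyKey(k, bands(p))$species)
    }
  }
  # the bundled key file is in canonical form: parse-then-format is identity
  f <- system.file("extdata", "na16s_key.txt", package = "rflpkit")
  onDisk <- readLines(f)
  expect_identical(formatKey(parseKey(f)), onDisk[nzchar(onDisk)])
})

test_that("malformed key text is rejected with a line number", {
  expect_error(parseKey("", text = TRUE), class = "KeyParseError")
  err <- tryCatch(
    parseKey(c("# key enzyme=DraI region=16S tol=5 min_visible=40",
               "1(-) count>2 -> 2 | count==2 -> 3",
               "2(1) giberish"), text = TRUE),
    error = function(e) e)
  expect_s3_class(err, "KeyParseError")
  expect_identical(err$line, 3L)
  # dangling couplet reference fails structural validation
  expect_error(
    parseKey("1(-) count>2 -> 9 | count<=2 -> A", text = TRUE))
})

test_that("pretty printing uses couplet numbering with dot leaders", {
  txt <- formatKey(naKey16S(), style = "pretty")
  expect_length(txt, 10)
  expect_match(txt[1], "^1 More than 2 bands present\\.+")
  expect_match(txt[3], "^2\\(1\\)")
  expect_match(txt[5], "H\\. leporispalustris")
  expect_match(txt[6], "H\\. chordeilis")
})
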
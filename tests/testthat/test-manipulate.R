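# Random (forest, selection, flags) cases reused across filter tests.
randomFilterCase <- function(seed) {
  fx <- randomTaxmap(nTaxa = sample(3:30, 1), nObs = sample(5:40, 1),
                     nRoots = sample(1:2, 1), seed = seed)
  nSel <- sample.int(nTaxa(fx$taxmap), 1)
  sel <- sort(sample(taxonIds(fx$taxmap), nSel))
  list(fx = fx, sel = sel)
}

expectMatchesOracle <- function(tm, oracle) {
  tx <- taxonTable(tm)
  got <- stats::setNames(tx$supertaxon_id, tx$taxon_id)
  expect_identical(got, oracle$parent)
  ob <- obsTable(tm)
  expect_identical(stats::setNames(ob$taxon_id, ob$obs_id), oracle$obsTaxon)
}

test_that("filterTaxa identity and basic reassignment semantics", {
  tm <- chainTaxmap(3, obsOn = 3)  # A->B->C, obs on C
  expect_identical(taxonTable(filterTaxa(tm, TRUE)), taxonTable(tm))

  kept <- filterTaxa(tm, taxon_id %in% c("a", "b"))
  expect_equal(taxonIds(kept), c("a", "b"))
  expect_equal(obsTable(kept)$taxon_id, "b")  # o1 reassigned to B

  dropped <- filterTaxa(tm, taxon_id %in% c("a", "b"), reassignObs = FALSE)
  expect_equal(nrow(obsTable(dropped)), 0L)

  expect_error(filterTaxa(tm, not_a_column > 1), "unknown column")
})

test_that("filterTaxa agrees with the set-based oracle over all 16 flag combos", {
  flags <- expand.grid(keepSubtaxa = c(FALSE, TRUE),
                       keepSupertaxa = c(FALSE, TRUE),
                       reassignObs = c(FALSE, TRUE),
                       reassignTaxa = c(FALSE, TRUE))
  for (s in 1:25) {
    case <- randomFilterCase(1000 + s)
    tm <- case$fx$taxmap
    for (f in seq_len(nrow(flags))) {
      out <- filterTaxa(tm, taxon_id %in% case$sel,
                        keepSubtaxa = flags$keepSubtaxa[f],
                        keepSupertaxa = flags$keepSupertaxa[f],
                        reassignObs = flags$reassignObs[f],
                        reassignTaxa = flags$reassignTaxa[f])
      expectValidTaxmap(out)
      oracle <- oracleFilterTaxa(case$fx$parent, case$fx$obsTaxon, case$sel,
                                 keepSubtaxa = flags$keepSubtaxa[f],
                                 keepSupertaxa = flags$keepSupertaxa[f],
                                 reassignObs = flags$reassignObs[f],
                                 reassignTaxa = flags$reassignTaxa[f])
      expectMatchesOracle(out, oracle)
    }
  }
})

test_that("invert complements the expanded selection", {
  for (s in 1:10) {
    case <- randomFilterCase(2000 + s)
    tm <- case$fx$taxmap
    out <- filterTaxa(tm, taxon_id %in% case$sel, keepSubtaxa = TRUE,
                      invert = TRUE)
    expectValidTaxmap(out)
    oracle <- oracleFilterTaxa(case$fx$parent, case$fx$obsTaxon, case$sel,
                               keepSubtaxa = TRUE, invert = TRUE)
    expectMatchesOracle(out, oracle)
    # double inversion restores the expanded selected id set
    expanded <- union(case$sel, unlist(subtaxa(tm, case$sel), use.names = FALSE))
    inverted <- setdiff(taxonIds(tm), expanded)
    expect_setequal(taxonIds(filterTaxa(tm, taxon_id %in% inverted, invert = TRUE)),
                    expanded)
  }
})

test_that("filterObs removes rows and optionally empty taxa", {
  tm <- chainTaxmap(3, obsOn = c(3, 3))
  one <- filterObs(tm, obs_id == "o1")
  expect_equal(nrow(obsTable(one)), 1L)
  expect_equal(nTaxa(one), 3L)  # taxon table untouched

  none <- filterObs(tm, FALSE, dropEmptyTaxa = TRUE)
  expect_equal(nTaxa(none), 0L)
  expect_equal(nrow(obsTable(none)), 0L)
  expectValidTaxmap(none)
})

test_that("mutate adds columns, transmute keeps only keys plus new columns", {
  fx <- randomTaxmap(nTaxa = 10, nObs = 20, seed = 31)
  tm <- fx$taxmap
  m <- mutateTaxa(tm, ones = 1, double_obs = n_obs * 2)
  expect_equal(m@taxa$ones, rep(1, 10))
  expect_equal(m@taxa$double_obs, nObs(tm) * 2)
  expect_identical(m@taxa$supertaxon_id, tm@taxa$supertaxon_id)

  tm2 <- mutateObs(tm, tag = paste0("x", seq_len(20)))
  t2 <- transmuteObs(tm2, keep = tag)
  expect_equal(names(obsTable(t2)), c("obs_id", "taxon_id", "keep"))

  expect_error(mutateTaxa(tm, taxon_id = "boom"), "protected")
  expect_error(mutateObs(tm, obs_id = "boom"), "protected")
})

test_that("select keeps protected columns; arrange never changes traversals", {
  fx <- randomTaxmap(nTaxa = 15, nObs = 25, seed = 32)
  tm <- mutateObs(fx$taxmap, val = stats::runif(25))
  s <- selectObs(tm, character())
  expect_equal(names(obsTable(s)), c("obs_id", "taxon_id"))
  expect_error(selectObs(tm, "nope"), "unknown column")
  expect_error(arrangeTaxa(tm, nope), "unknown column")

  arranged <- arrangeTaxa(arrangeObs(tm, val), name)
  expectValidTaxmap(arranged)
  expect_setequal(roots(arranged), roots(tm))
  for (id in taxonIds(tm)) {
    expect_setequal(subtaxa(arranged, id)[[1]], subtaxa(tm, id)[[1]])
    expect_setequal(observations(arranged, id)[[1]], observations(tm, id)[[1]])
  }
  # arranging twice by the same key is idempotent
  again <- arrangeObs(arrangeObs(tm, val), val)
  expect_identical(obsTable(again), obsTable(arrangeObs(tm, val)))
})

test_that("weighted sampling honors weights, n and the seed", {
  fx <- randomTaxmap(nTaxa = 8, nObs = 30, seed = 33)
  tm <- fx$taxmap
  all <- sampleNTaxa(tm, nTaxa(tm), seed = 1)
  expect_setequal(taxonIds(all), taxonIds(tm))

  w <- c(rep(0, 7), 1)
  one <- sampleNObs(tm, 1, weights = rep(c(0, 1), c(29, 1)), seed = 99)
  expect_equal(obsTable(one)$obs_id, obsIds(tm)[30])

  expect_error(sampleNObs(tm, 31), "cannot sample")
  expect_error(sampleNTaxa(tm, 2, weights = rep(0, 8)), "positively weighted")

  a <- sampleNObs(tm, 10, seed = 5)
  b <- sampleNObs(tm, 10, seed = 5)
  c <- sampleNObs(tm, 10, seed = 6)
  expect_identical(obsTable(a), obsTable(b))
  expect_false(identical(obsIds(a), obsIds(c)))
})

test_that("sequential-draw frequencies match the binomial oracle (2 items, w = 2:1)", {
  # inclusion probability of item 1 in a single draw is 2/3
  reps <- 3000
  hits <- 0L
  tm <- taxmap(data.frame(taxon_id = c("a", "b"), supertaxon_id = c(NA, NA)))
  for (s in seq_len(reps)) {
    out <- sampleNTaxa(tm, 1, weights = c(2, 1), seed = s)
    if (taxonIds(out) == "a") hits <- hits + 1L
  }
  se <- sqrt(2 / 9 / reps)
  expect_lt(abs(hits / reps - 2 / 3), 3 * se)
})

test_that("taxonomicSample enforces min/max counts per rank taxon", {
  fx <- randomTaxmap(nTaxa = 40, nObs = 200, maxDepth = 3,
                     ranks = c("root", "phylum", "genus", "species"), seed = 35)
  tm <- fx$taxmap
  expect_error(taxonomicSample(tm, "kingdom", 1, 10), "available ranks")

  expect_identical(taxonTable(taxonomicSample(tm, "genus", 0, 10000)),
                   taxonTable(tm))

  out <- taxonomicSample(tm, "genus", minCounts = 3, maxCounts = 8, seed = 2)
  expectValidTaxmap(out)
  gen <- taxonIds(out)[taxonTable(out)$rank == "genus"]
  if (length(gen)) {
    cnt <- lengths(observations(out, gen, recursive = TRUE))
    expect_true(all(cnt >= 3 & cnt <= 8))
  }
  # all-or-nothing removal: genus taxa below min disappear entirely
  genBefore <- taxonIds(tm)[taxonTable(tm)$rank == "genus"]
  small <- genBefore[lengths(observations(tm, genBefore)) < 3]
  expect_true(all(!small %in% taxonIds(out)))
  removedSub <- unlist(subtaxa(tm, small, includeInput = TRUE), use.names = FALSE)
  expect_true(all(!removedSub %in% taxonIds(out)))
  # reproducible under the seed
  expect_identical(obsTable(taxonomicSample(tm, "genus", 3, 8, seed = 2)),
                   obsTable(out))
})

test_that("one rank taxon with 5 obs subsamples to exactly maxCounts", {
  tm <- taxmap(data.frame(taxon_id = c("r", "g"), supertaxon_id = c(NA, "r"),
                          rank = c("root", "genus")),
               data.frame(obs_id = paste0("o", 1:5), taxon_id = "g"))
  out <- taxonomicSample(tm, "genus", 0, 2, seed = 7)
  expect_equal(nrow(obsTable(out)), 2L)
})
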
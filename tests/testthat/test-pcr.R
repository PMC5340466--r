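IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
           "B", "D", "H", "V", "N")

test_that("iupacMatch equals set intersection over all 15x15 code pairs", {
  expect_true(iupacMatch("A", "A"))
  expect_true(iupacMatch("N", "G"))
  expect_true(iupacMatch("A", "R"))
  expect_false(iupacMatch("A", "Y"))
  for (a in IUPAC) for (b in IUPAC) {
    expect_identical(iupacMatch(a, b), oracleIupacMatch(a, b))
  }
  expect_error(iupacMatch("A", "Z"), "non-IUPAC")
})

test_that("revComp handles degenerate codes and is an involution", {
  expect_equal(revComp("ACGT"), "ACGT")
  expect_equal(revComp("RN"), "NY")
  expect_error(revComp("AXC"), "non-IUPAC")
  set.seed(1)
  for (i in 1:50) {
    s <- paste(sample(IUPAC, sample(1:30, 1), replace = TRUE), collapse = "")
    expect_equal(revComp(revComp(s)), s)
    expect_equal(revComp(s), oracleRevComp(s))
  }
})

test_that("findPrimerSites finds exact occurrences and honors the budget", {
  # exact substring occurrences at 0%
  hits <- findPrimerSites("ACGT", "TTACGTACGTA", 0)
  expect_equal(hits$start, c(2L, 6L))
  expect_equal(hits$mismatches, c(0L, 0L))
  # NNNN matches every offset
  expect_equal(findPrimerSites("NNNN", "ACGTACG", 0)$start, 0:3)
  # primer longer than template
  expect_equal(nrow(findPrimerSites("ACGTACGT", "ACG", 50)), 0L)
  # budget formula: floor(p/100 * L)
  expect_equal(nrow(findPrimerSites("AAAA", "AAAT", 24)), 0L)  # floor(.96)=0
  expect_equal(findPrimerSites("AAAA", "AAAT", 25)$mismatches, 1L)
})

test_that("findPrimerSites equals the sliding-window oracle on random pairs", {
  set.seed(7)
  for (i in 1:40) {
    primer <- paste(sample(IUPAC, sample(4:10, 1), replace = TRUE,
                           prob = c(rep(4, 4), rep(1, 11))), collapse = "")
    template <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1),
                             replace = TRUE, prob = c(4, 4, 4, 4, 1)),
                      collapse = "")
    pct <- sample(c(0, 10, 25, 50), 1)
    expect_equal(findPrimerSites(primer, template, pct),
                 oracleSites(primer, template, pct))
  }
})

test_that("digitalPcr amplifies constructed templates and rejects wrong geometry", {
  fwd <- "ACGTACGT"
  rev <- "TTGGCCAA"
  pp <- primerPair(fwd, rev, 0)
  spacer <- "AAAACCCC"
  template <- paste0(fwd, spacer, revComp(rev))
  tm <- taxmap(data.frame(taxon_id = "a", supertaxon_id = NA),
               data.frame(obs_id = "o1", taxon_id = "a",
                          sequence = template))
  out <- digitalPcr(tm, pp)
  ob <- obsTable(out)
  expect_true(ob$amplified)
  expect_equal(ob$product_length, nchar(template))
  expect_equal(ob$product_start, 0L)
  expect_equal(ob$product_end, nchar(template))

  # reverse site upstream of the forward site only: no product
  bad <- paste0(revComp(rev), spacer, fwd)
  tm2 <- taxmap(data.frame(taxon_id = "a", supertaxon_id = NA),
                data.frame(obs_id = "o1", taxon_id = "a", sequence = bad))
  expect_false(obsTable(digitalPcr(tm2, pp))$amplified)

  expect_error(digitalPcr(tm, pp, sequenceColumn = "nope"), "missing sequence")
})

test_that("digitalPcr matches the exhaustive site-pairing oracle on planted fixtures", {
  pp <- primerPair("GTGCCAGCMGCCGCGGTAA", "GGACTACHVGGGTWTCTAAT", 15)
  for (s in 1:12) {
    fx <- randomSequences(12, seqLength = 120, primers = pp,
                          plantedFraction = 0.7,
                          mismatches = sample(0:2, 1), seed = 400 + s)
    fxtm <- randomTaxmap(nTaxa = 6, nObs = 12, seed = 500 + s)
    tm <- mutateObs(fxtm$taxmap, sequence = fx$sequences)
    out <- obsTable(digitalPcr(tm, pp))
    for (i in seq_len(12)) {
      oracle <- oracleAmplify(fx$sequences[i], pp@forward, pp@reverse, 15)
      expect_equal(out$amplified[i], oracle$amplified)
      expect_equal(out$product_start[i], oracle$start)
      expect_equal(out$product_end[i], oracle$end)
      expect_equal(out$product_length[i], oracle$length)
      expect_equal(out$fwd_mismatches[i], oracle$fwd_mm)
      expect_equal(out$rev_mismatches[i], oracle$rev_mm)
    }
  }
})

test_that("amplification is monotone in the mismatch budget", {
  base <- primerPair("ACGTACGTAC", "GGATCCGGAT", 0)
  fx <- randomSequences(30, seqLength = 80, primers = base,
                        plantedFraction = 0.6, mismatches = 1, seed = 11)
  tmBase <- taxmap(data.frame(taxon_id = "a", supertaxon_id = NA),
                   data.frame(obs_id = sprintf("o%d", 1:30), taxon_id = "a",
                              sequence = fx$sequences))
  prev <- rep(FALSE, 30)
  for (pct in c(0, 10, 20, 40)) {
    amp <- obsTable(digitalPcr(tmBase, primerPair("ACGTACGTAC", "GGATCCGGAT",
                                                  pct)))$amplified
    expect_true(all(amp | !prev))  # raising the budget never un-amplifies
    prev <- amp
  }
})

test_that("planted sites amplify iff injected mismatches fit the budget", {
  pp0 <- primerPair("ACGTTGCAAC", "TGCAACGTTG", 0)
  ppLoose <- primerPair("ACGTTGCAAC", "TGCAACGTTG", 20)  # floor(2) = 2
  fx <- randomSequences(40, seqLength = 100, primers = pp0,
                        plantedFraction = 1, mismatches = 2, seed = 21)
  tm <- taxmap(data.frame(taxon_id = "a", supertaxon_id = NA),
               data.frame(obs_id = sprintf("o%d", 1:40), taxon_id = "a",
                          sequence = fx$sequences))
  strict <- obsTable(digitalPcr(tm, pp0))$amplified
  loose <- obsTable(digitalPcr(tm, ppLoose))$amplified
  # with 2 injected mismatches per site, a 20% budget must recover them all
  expect_true(all(loose))
  # 0% budget: only sequences where random background happens to contain
  # exact sites could amplify; planted (corrupted) sites alone cannot
  oracle0 <- vapply(fx$sequences, function(s)
    oracleAmplify(s, pp0@forward, pp0@reverse, 0)$amplified, logical(1))
  expect_equal(strict, unname(oracle0))
})

test_that("per-taxon amplification proportions respect the hierarchy", {
  pp <- primerPair("ACGTACGTAC", "GGATCCGGAT", 10)
  fxtm <- randomTaxmap(nTaxa = 12, nObs = 40, seed = 61)
  fx <- randomSequences(40, seqLength = 90, primers = pp,
                        plantedFraction = 0.5, seed = 62)
  tm <- digitalPcr(mutateObs(fxtm$taxmap, sequence = fx$sequences), pp)
  df <- pcrSummary(tm)
  withObs <- df$n_obs > 0
  expect_true(all(df$prop_amplified[withObs] >= 0 &
                  df$prop_amplified[withObs] <= 1))
  expect_true(all(is.na(df$prop_amplified[!withObs])))
  expect_equal(df$n_not_amplified, df$n_obs - df$n_amplified)
  counts <- stats::setNames(df$n_amplified, df$taxon_id)
  for (id in taxonIds(tm)) {
    for (anc in supertaxa(tm, id)[[1]]) {
      expect_gte(counts[[anc]], counts[[id]])
    }
  }
  # computed columns stay fresh after filtering
  half <- filterObs(tm, amplified)
  expect_equal(pcrSummary(half)$n_amplified, pcrSummary(half)$n_obs)
})

test_that("strand symmetry: reverse-complemented templates amplify with swapped primers", {
  pp <- primerPair("ACGTACGTAC", "GGATCCGGAT", 10)
  ppSwap <- primerPair("GGATCCGGAT", "ACGTACGTAC", 10)
  fx <- randomSequences(25, seqLength = 80, primers = pp,
                        plantedFraction = 0.6, seed = 71)
  tmF <- taxmap(data.frame(taxon_id = "a", supertaxon_id = NA),
                data.frame(obs_id = sprintf("o%d", 1:25), taxon_id = "a",
                           sequence = fx$sequences))
  tmR <- mutateObs(tmF, sequence = revComp(sequence))
  ampF <- obsTable(digitalPcr(tmF, pp))$amplified
  ampR <- obsTable(digitalPcr(tmR, ppSwap))$amplified
  expect_equal(ampF, ampR)
  # bothStrands finds the flipped orientation with the original pair
  ampBoth <- obsTable(digitalPcr(tmR, pp, bothStrands = TRUE))$amplified
  expect_true(all(ampBoth | !ampF))
})
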
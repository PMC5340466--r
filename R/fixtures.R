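# Synthetic data generators. Every module is testable offline: random
# taxonomies with known structure, sequences with plantable primer binding
# sites, and two-group abundance matrices with plantable fold-changes. All
# generators are deterministic given their seed and return the generating
# ground truth alongside the data for use as test oracles.

#' Generate a random taxonomy with observations
#'
#' Builds a forest by sequential parent attachment: taxa are created one at
#' a time and attached to a randomly chosen existing taxon whose depth is
#' below `maxDepth`. Parents with fewer than `branching` children are
#' strongly preferred, so `branching` sets the mean number of children per
#' internal taxon (bushy vs chainy trees). Ranks are assigned by depth from
#' `ranks` (depths beyond the vector recycle its last element).
#' Observations are placed on uniformly chosen taxa — internal taxa may
#' carry observations directly.
#'
#' @param nTaxa number of taxa (>= 1).
#' @param nObs number of observations.
#' @param nRoots number of root taxa (trees in the forest).
#' @param maxDepth maximum depth (root = 0).
#' @param branching target mean children per internal taxon.
#' @param ranks character vector of rank labels by depth.
#' @param seed integer seed.
#' @return list with `taxmap` (a [Taxmap-class]), `parent` (named character
#'   vector: generating parent of each taxon ID, `NA` for roots) and
#'   `obsTaxon` (named character vector: generating taxon of each obs ID).
#' @export
randomTaxmap <- function(nTaxa = 30L, nObs = 60L, nRoots = 1L, maxDepth = 4L,
                         branching = 2, ranks = c("domain", "phylum", "class",
                                                  "order", "family", "genus",
                                                  "species"),
                         seed = 1L) {
  stopifnot(nTaxa >= 1L, nRoots >= 1L, nRoots <= nTaxa, maxDepth >= 0L,
            nObs >= 0L, branching >= 1)
  .withSeed(seed, {
    ids <- paste0("t_", seq_len(nTaxa))
    parent <- rep(NA_character_, nTaxa)
    depth <- integer(nTaxa)
    nKids <- integer(nTaxa)
    for (i in seq_len(nTaxa)) {
      if (i <= nRoots) {
        parent[i] <- NA_character_
        depth[i] <- 0L
      } else {
        cand <- which(depth[seq_len(i - 1L)] < maxDepth)
        if (!length(cand)) {
          stop("cannot place taxon ", i, ": all existing taxa at maxDepth",
               call. = FALSE)
        }
        w <- ifelse(nKids[cand] < branching, 1, 0.05)
        p <- cand[sample.int(length(cand), 1L, prob = w)]
        parent[i] <- ids[p]
        depth[i] <- depth[p] + 1L
        nKids[p] <- nKids[p] + 1L
      }
    }
    rankOf <- ranks[pmin(depth + 1L, length(ranks))]
    taxa <- data.frame(taxon_id = ids, supertaxon_id = parent,
                       name = paste0("taxon_", seq_len(nTaxa)),
                       rank = rankOf, stringsAsFactors = FALSE)
    obsTaxon <- ids[sample.int(nTaxa, nObs, replace = TRUE)]
    obs <- data.frame(obs_id = sprintf("o_%d", seq_len(nObs)),
                      taxon_id = obsTaxon, stringsAsFactors = FALSE)
    tm <- taxmap(taxa, obs)
    list(taxmap = tm,
         parent = stats::setNames(parent, ids),
         obsTaxon = stats::setNames(obsTaxon, obs$obs_id))
  })
}

#' Generate random DNA templates with plantable primer sites
#'
#' Sequences are i.i.d. uniform A/C/G/T. For a fraction of them a forward
#' binding site and, strictly downstream, the reverse complement of the
#' reverse primer are written into the sequence at recorded positions;
#' `mismatches` positions of each planted site are flipped to a
#' non-matching base so tests can reason about the mismatch budget exactly.
#'
#' @param n number of sequences.
#' @param seqLength template length (must fit both primers plus one spacer
#'   base when planting).
#' @param primers a [PrimerPair-class] or `NULL` for plain random sequences.
#' @param plantedFraction fraction of sequences receiving a planted site
#'   pair.
#' @param mismatches integer; how many positions to corrupt in each planted
#'   site (applied to both primers' sites).
#' @param seed integer seed.
#' @return list with `sequences` (character vector) and `truth`
#'   (`data.frame`: `planted`, `fwd_start`, `rev_start` 0-based,
#'   `fwd_mm`, `rev_mm`).
#' @export
randomSequences <- function(n, seqLength = 200L, primers = NULL,
                            plantedFraction = 0, mismatches = 0L, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  .withSeed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(bases[sample.int(4L, seqLength, replace = TRUE)], collapse = ""),
      character(1))
    truth <- data.frame(planted = rep(FALSE, n), fwd_start = NA_integer_,
                        rev_start = NA_integer_, fwd_mm = NA_integer_,
                        rev_mm = NA_integer_)
    if (!is.null(primers) && plantedFraction > 0) {
      Lf <- nchar(primers@forward)
      Lr <- nchar(primers@reverse)
      if (seqLength < Lf + Lr + 1L) {
        stop("seqLength too short to plant both primer sites", call. = FALSE)
      }
      nPlant <- round(plantedFraction * n)
      chosen <- if (nPlant) sort(sample.int(n, nPlant)) else integer()
      for (i in chosen) {
        gapMax <- seqLength - Lf - Lr
        fStart <- sample.int(gapMax, 1L)            # 1-based, leaves room
        gap <- sample.int(seqLength - Lf - Lr - fStart + 2L, 1L) - 1L
        rStart <- fStart + Lf + gap                  # 1-based start of rev site
        fwdSite <- .concretize(primers@forward)
        revSite <- .concretize(revComp(primers@reverse))
        fwdSite <- .corrupt(fwdSite, primers@forward, mismatches)
        revSite <- .corrupt(revSite, revComp(primers@reverse), mismatches)
        s <- strsplit(seqs[i], "")[[1]]
        s[fStart:(fStart + Lf - 1L)] <- strsplit(fwdSite, "")[[1]]
        s[rStart:(rStart + Lr - 1L)] <- strsplit(revSite, "")[[1]]
        seqs[i] <- paste(s, collapse = "")
        truth$planted[i] <- TRUE
        truth$fwd_start[i] <- fStart - 1L
        truth$rev_start[i] <- rStart - 1L
        truth$fwd_mm[i] <- mismatches
        truth$rev_mm[i] <- mismatches
      }
    }
    list(sequences = seqs, truth = truth)
  })
}

# Pick one concrete base per (possibly degenerate) primer position.
.concretize <- function(primer) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(primer), "")[[1]]
  out <- vapply(chars, function(ch) {
    opts <- bases[bitwAnd(.IUPAC_BITS[bases], .IUPAC_BITS[[ch]]) > 0L]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

# Flip `k` positions of a concrete site to bases that do NOT match the
# primer's degenerate code at that position (skips all-degenerate N slots).
.corrupt <- function(site, primer, k) {
  if (k <= 0L) return(site)
  bases <- c("A", "C", "G", "T")
  s <- strsplit(site, "")[[1]]
  p <- strsplit(toupper(primer), "")[[1]]
  flippable <- which(vapply(p, function(ch)
    any(bitwAnd(.IUPAC_BITS[bases], .IUPAC_BITS[[ch]]) == 0L), logical(1)))
  if (length(flippable) < k) {
    stop("cannot inject ", k, " mismatches: primer too degenerate", call. = FALSE)
  }
  pos <- flippable[sample.int(length(flippable), k)]
  for (i in pos) {
    opts <- bases[bitwAnd(.IUPAC_BITS[bases], .IUPAC_BITS[[p[i]]]) == 0L]
    s[i] <- opts[sample.int(length(opts), 1L)]
  }
  paste(s, collapse = "")
}

#' Generate a two-group abundance matrix with plantable effects
#'
#' Baseline taxon weights are drawn log-normal (a long-tailed
#' rank-abundance shape typical of microbiome communities); per-sample
#' counts are multinomial given a library size. Fold-changes in
#' `effectTaxa` multiply the weights in group B only.
#'
#' @param taxonIds character vector of taxon IDs (matrix rows).
#' @param nPerGroup samples per group.
#' @param librarySize reads per sample.
#' @param effectTaxa named numeric vector: fold-change applied in group B,
#'   names are taxon IDs (e.g. `c(t_3 = 4)`).
#' @param sdlog log-normal shape parameter of the baseline weights.
#' @param seed integer seed.
#' @return list with `counts` (matrix), `treatments` (named vector with
#'   levels `"A"`/`"B"`) and `truth` (the effect vector).
#' @export
randomAbundance <- function(taxonIds, nPerGroup = 10L, librarySize = 10000L,
                            effectTaxa = numeric(), sdlog = 1.5, seed = 1L) {
  nt <- length(taxonIds)
  .withSeed(seed, {
    base <- stats::rlnorm(nt, meanlog = 0, sdlog = sdlog)
    names(base) <- taxonIds
    wA <- base
    wB <- base
    if (length(effectTaxa)) {
      unknown <- setdiff(names(effectTaxa), taxonIds)
      if (length(unknown)) stop("unknown effect taxa: ", .fmtIds(unknown),
                                call. = FALSE)
      wB[names(effectTaxa)] <- wB[names(effectTaxa)] * effectTaxa
    }
    samp <- function(w) stats::rmultinom(nPerGroup, librarySize, prob = w / sum(w))
    counts <- cbind(samp(wA), samp(wB))
    rownames(counts) <- taxonIds
    colnames(counts) <- c(paste0("A_", seq_len(nPerGroup)),
                          paste0("B_", seq_len(nPerGroup)))
    treatments <- stats::setNames(rep(c("A", "B"), each = nPerGroup),
                                  colnames(counts))
    list(counts = counts, treatments = treatments, truth = effectTaxa)
  })
}
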
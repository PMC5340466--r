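# Independent brute-force oracles. These deliberately avoid the package's
# internal index structures: they work on plain parent-pointer vectors and
# base-set expansions so they can disagree with the implementation.

# parent: named character vector, parent[id] = parent id or NA.
oracleDescendants <- function(parent, id) {
  out <- character()
  frontier <- id
  repeat {
    nxt <- names(parent)[!is.na(parent) & parent %in% frontier]
    nxt <- setdiff(nxt, out)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

oracleChildren <- function(parent, id) {
  names(parent)[!is.na(parent) & parent == id]
}

oracleAncestors <- function(parent, id) {
  out <- character()
  p <- parent[[id]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- parent[[p]]
  }
  out
}

oracleRoots <- function(parent) {
  names(parent)[is.na(parent)]
}

# obsTaxon: named character vector obs_id -> taxon_id.
oracleObservations <- function(parent, obsTaxon, id, recursive = TRUE) {
  members <- if (recursive) c(id, oracleDescendants(parent, id)) else id
  names(obsTaxon)[obsTaxon %in% members]
}

# Set-based filter_taxa oracle, straight from the contract: compute the
# final selected set, re-parent survivors via ancestor walks, reassign or
# drop observations via ancestor walks. Returns list(parent=, obsTaxon=).
oracleFilterTaxa <- function(parent, obsTaxon, selected,
                             keepSubtaxa = FALSE, keepSupertaxa = FALSE,
                             reassignObs = TRUE, reassignTaxa = TRUE,
                             invert = FALSE) {
  sel <- selected
  if (keepSubtaxa) {
    for (id in selected) sel <- union(sel, oracleDescendants(parent, id))
  }
  if (keepSupertaxa) {
    for (id in selected) sel <- union(sel, oracleAncestors(parent, id))
  }
  if (invert) sel <- setdiff(names(parent), sel)
  nearestKept <- function(id) {
    for (a in oracleAncestors(parent, id)) if (a %in% sel) return(a)
    NA_character_
  }
  newParent <- stats::setNames(rep(NA_character_, length(sel)), sel)
  for (id in sel) {
    p <- parent[[id]]
    if (!is.na(p) && p %in% sel) {
      newParent[[id]] <- p
    } else if (reassignTaxa) {
      newParent[[id]] <- nearestKept(id)
    }
  }
  newObs <- character()
  newNames <- character()
  for (o in names(obsTaxon)) {
    t <- obsTaxon[[o]]
    if (t %in% sel) {
      newObs <- c(newObs, t); newNames <- c(newNames, o)
    } else if (reassignObs) {
      a <- nearestKept(t)
      if (!is.na(a)) { newObs <- c(newObs, a); newNames <- c(newNames, o) }
    }
  }
  # keep original taxon order for comparability
  ord <- names(parent)[names(parent) %in% sel]
  list(parent = newParent[ord], obsTaxon = stats::setNames(newObs, newNames))
}

# ---- digital PCR oracles -------------------------------------------------

# IUPAC base sets built from scratch (independent of the package's bitmasks)
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracleIupacMatch <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0
}

oracleRevComp <- function(s) {
  comp <- c(A = "T", T = "A", C = "G", G = "C", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Exhaustive sliding-window site search.
oracleSites <- function(primer, template, pct) {
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template, "")[[1]]
  L <- length(p)
  budget <- floor(pct / 100 * L)
  res <- data.frame(start = integer(), mismatches = integer())
  if (L > length(t)) return(res)
  for (off in 0:(length(t) - L)) {
    mm <- 0L
    for (j in seq_len(L)) {
      if (!oracleIupacMatch(p[j], t[off + j])) mm <- mm + 1L
    }
    if (mm <= budget) res <- rbind(res, data.frame(start = off, mismatches = mm))
  }
  res
}

# Pair every forward site with every downstream reverse site; pick the
# shortest product, leftmost forward on ties.
oracleAmplify <- function(template, fwd, rev, pct) {
  f <- oracleSites(fwd, template, pct)
  r <- oracleSites(oracleRevComp(rev), template, pct)
  Lf <- nchar(fwd); Lr <- nchar(rev)
  best <- NULL
  if (nrow(f) && nrow(r)) {
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(r))) {
        if (r$start[j] >= f$start[i] + Lf) {
          len <- r$start[j] + Lr - f$start[i]
          cand <- list(amplified = TRUE, start = f$start[i],
                       end = r$start[j] + Lr, length = len,
                       fwd_mm = f$mismatches[i], rev_mm = r$mismatches[j])
          # forward sites are visited left to right, so keeping only strict
          # improvements implements "shortest product, leftmost fwd on ties"
          if (is.null(best) || cand$length < best$length) best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    list(amplified = FALSE, start = NA_integer_, end = NA_integer_,
         length = NA_integer_, fwd_mm = NA_integer_, rev_mm = NA_integer_)
  } else best
}

# ---- statistics oracles --------------------------------------------------

# Exact two-sided Wilcoxon rank-sum p by full labeling enumeration:
# p = min(1, 2 * min(P(W <= w), P(W >= w))) over all C(m+n, m) labelings.
oracleWilcoxonExact <- function(x, y) {
  all <- c(x, y)
  m <- length(x)
  rk <- rank(all)
  wObs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(all), m)
  ws <- apply(combs, 2L, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  pLe <- mean(ws <= wObs)
  pGe <- mean(ws >= wObs)
  min(1, 2 * min(pLe, pGe))
}

# Textbook BH step-up computed independently of p.adjust.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    i <- ord[k]
    val <- min(prev, m / k * p[i])
    adj[i] <- val
    prev <- val
  }
  adj
}

# Exact marginal inclusion probabilities of sequential weighted draws
# without replacement (enumeration over ordered selections).
oracleInclusionProbs <- function(weights, n) {
  k <- length(weights)
  probs <- numeric(k)
  recurse <- function(remaining, w, pAcc, depth) {
    if (depth == 0L) return()
    for (i in seq_along(remaining)) {
      pi <- pAcc * w[i] / sum(w)
      probs[remaining[i]] <<- probs[remaining[i]] + pi
      recurse(remaining[-i], w[-i], pi, depth - 1L)
    }
  }
  recurse(seq_len(k), weights, 1, n)
  probs
}

# ---- shared fixtures -----------------------------------------------------

chainTaxmap <- function(n = 3L, obsOn = n) {
  ids <- letters[seq_len(n)]
  tm <- taxmap(
    data.frame(taxon_id = ids,
               supertaxon_id = c(NA, ids[-n]),
               name = toupper(ids), stringsAsFactors = FALSE),
    data.frame(obs_id = paste0("o", seq_along(obsOn)),
               taxon_id = ids[obsOn], stringsAsFactors = FALSE))
  tm
}

expectValidTaxmap <- function(tm) {
  expect_true(validateTaxmap(tm))
}
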
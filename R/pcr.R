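# Native in-silico PCR. A primer binds where the number of mismatching
# positions in an ungapped alignment is within floor(p/100 * L) of the
# primer length L; two IUPAC codes match when their base sets intersect.

# Bitmask per IUPAC code over the base set {A=1, C=2, G=4, T=8}.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.toBits <- function(s, what = "sequence") {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  bits <- unname(.IUPAC_BITS[chars])
  if (anyNA(bits)) {
    bad <- unique(chars[is.na(bits)])
    stop("non-IUPAC character(s) in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bits
}

#' Do two IUPAC codes match?
#'
#' Two degenerate nucleotide codes match when the base sets they denote
#' intersect: `N` matches anything, `A` matches `R` (= A/G) but not
#' `Y` (= C/T). Vectorized over both arguments.
#'
#' @param a,b characters from the IUPAC DNA alphabet.
#' @return Logical vector.
#' @examples
#' iupacMatch("A", "R")  # TRUE
#' iupacMatch("A", "Y")  # FALSE
#' @export
iupacMatch <- function(a, b) {
  ba <- unname(.IUPAC_BITS[toupper(a)])
  bb <- unname(.IUPAC_BITS[toupper(b)])
  if (anyNA(ba) || anyNA(bb)) {
    bad <- unique(c(a[is.na(ba)], b[is.na(bb)]))
    stop("non-IUPAC character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bitwAnd(ba, bb) > 0L
}

#' Reverse complement of an IUPAC DNA string
#'
#' Complements degenerate codes correctly (R to Y, K to M, B to V, N to N)
#' and reverses the sequence; an involution.
#'
#' @param s IUPAC DNA string(s).
#' @return Character vector of the same length.
#' @examples
#' revComp("ACGT")  # "ACGT"
#' revComp("RN")    # "NY"
#' @export
revComp <- function(s) {
  vapply(s, function(x) {
    chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
    comp <- unname(.IUPAC_COMPLEMENT[chars])
    if (anyNA(comp)) {
      stop("non-IUPAC character(s): ",
           paste(unique(chars[is.na(comp)]), collapse = ", "), call. = FALSE)
    }
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Create a PrimerPair
#'
#' @param forward,reverse IUPAC DNA strings, both 5'\eqn{\to}3' (the
#'   reverse primer as ordered on the opposite strand).
#' @param maxMismatchPercent mismatch budget in percent of primer length.
#' @return A validated [PrimerPair-class].
#' @export
primerPair <- function(forward, reverse, maxMismatchPercent = 10) {
  methods::new("PrimerPair", forward = toupper(forward),
               reverse = toupper(reverse),
               maxMismatchPercent = as.numeric(maxMismatchPercent))
}

#' Find primer binding sites on a template
#'
#' Scans every ungapped alignment offset of the primer against the
#' template (alphabet A/C/G/T/N) and reports those with at most
#' `floor(maxMismatchPercent/100 * nchar(primer))` mismatches, where a
#' position mismatches when the IUPAC base sets do not intersect.
#'
#' @param primer IUPAC DNA string.
#' @param template DNA string (A/C/G/T/N).
#' @param maxMismatchPercent mismatch budget in percent.
#' @return `data.frame` with columns `start` (0-based offset) and
#'   `mismatches`; empty if the primer is longer than the template.
#' @export
findPrimerSites <- function(primer, template, maxMismatchPercent = 0) {
  p <- .toBits(primer, "primer")
  t <- .toBits(template, "template")
  if (any(!t %in% .IUPAC_BITS[c("A", "C", "G", "T", "N")])) {
    stop("template may only contain A, C, G, T, N", call. = FALSE)
  }
  L <- length(p)
  n <- length(t)
  if (L > n) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  budget <- floor(maxMismatchPercent / 100 * L)
  nOff <- n - L + 1L
  mism <- integer(nOff)
  # column-sliced comparison: position j of the primer against the template
  for (j in seq_len(L)) {
    mism <- mism + as.integer(bitwAnd(p[j], t[j:(j + nOff - 1L)]) == 0L)
  }
  hits <- which(mism <= budget)
  data.frame(start = hits - 1L, mismatches = mism[hits])
}

#' Run in-silico PCR over the sequences of a Taxmap
#'
#' An observation amplifies when a forward-primer site exists on the
#' template and a reverse-primer site (matched as the reverse complement
#' of the reverse primer) starts at or beyond the forward site's end. The
#' predicted product runs from the forward site start to the reverse site
#' end (0-based, half-open). When several site pairs qualify, the shortest
#' product wins; ties go to the leftmost forward site.
#'
#' Adds per-observation columns `amplified`, `product_start`,
#' `product_end`, `product_length`, `fwd_mismatches`, `rev_mismatches`,
#' and registers the computed taxon columns `n_amplified`,
#' `n_not_amplified` and `prop_amplified` (amplified observations in the
#' subtree over `n_obs`; `NA` for taxa with no observations).
#'
#' @param tm a [Taxmap-class] with a sequence column.
#' @param primers a [PrimerPair-class].
#' @param sequenceColumn name of the observation column holding templates.
#' @param bothStrands also scan the reverse complement of each template
#'   and accept a hit on either strand (a `strand` column records which).
#' @return A new [Taxmap-class] with amplification columns.
#' @export
digitalPcr <- function(tm, primers, sequenceColumn = "sequence",
                       bothStrands = FALSE) {
  stopifnot(methods::is(primers, "PrimerPair"))
  methods::validObject(primers)
  ob <- tm@observations
  if (!sequenceColumn %in% names(ob)) {
    stop("missing sequence column: '", sequenceColumn, "'", call. = FALSE)
  }
  seqs <- ob[[sequenceColumn]]
  res <- lapply(seqs, .amplifyOne, primers = primers, bothStrands = bothStrands)
  ob$amplified <- vapply(res, `[[`, logical(1), "amplified")
  ob$product_start <- vapply(res, `[[`, integer(1), "start")
  ob$product_end <- vapply(res, `[[`, integer(1), "end")
  ob$product_length <- vapply(res, `[[`, integer(1), "length")
  ob$fwd_mismatches <- vapply(res, `[[`, integer(1), "fwd_mm")
  ob$rev_mismatches <- vapply(res, `[[`, integer(1), "rev_mm")
  if (bothStrands) ob$strand <- vapply(res, `[[`, character(1), "strand")
  tm@observations <- ob
  tm <- .registerPcrColumns(tm)
  methods::validObject(tm)
  tm
}

.registerPcrColumns <- function(tm) {
  tm <- registerColumn(tm, "n_amplified", function(x) {
    amp <- x@observations$obs_id[x@observations$amplified %in% TRUE]
    vapply(observations(x, recursive = TRUE),
           function(o) sum(o %in% amp), integer(1))
  }, table = "taxa")
  tm <- registerColumn(tm, "n_not_amplified", function(x) {
    nObs(x) - x@taxonFuns$n_amplified(x)
  }, table = "taxa")
  tm <- registerColumn(tm, "prop_amplified", function(x) {
    n <- nObs(x)
    ifelse(n > 0L, x@taxonFuns$n_amplified(x) / n, NA_real_)
  }, table = "taxa")
  tm
}

# Best amplification for one template: shortest product, leftmost forward.
.amplifyOne <- function(template, primers, bothStrands = FALSE) {
  miss <- list(amplified = FALSE, start = NA_integer_, end = NA_integer_,
               length = NA_integer_, fwd_mm = NA_integer_, rev_mm = NA_integer_,
               strand = NA_character_)
  scan <- function(tmpl) {
    fwd <- findPrimerSites(primers@forward, tmpl, primers@maxMismatchPercent)
    if (!nrow(fwd)) return(NULL)
    rev <- findPrimerSites(revComp(primers@reverse), tmpl,
                           primers@maxMismatchPercent)
    if (!nrow(rev)) return(NULL)
    Lf <- nchar(primers@forward)
    Lr <- nchar(primers@reverse)
    best <- NULL
    for (i in seq_len(nrow(fwd))) {
      fEnd <- fwd$start[i] + Lf
      ok <- rev$start >= fEnd
      if (!any(ok)) next
      rs <- rev$start[ok]
      rm <- rev$mismatches[ok]
      pend <- rs + Lr
      plen <- pend - fwd$start[i]
      j <- which.min(plen)  # shortest for this forward site; earliest on tie
      cand <- list(amplified = TRUE, start = fwd$start[i],
                   end = as.integer(pend[j]), length = as.integer(plen[j]),
                   fwd_mm = fwd$mismatches[i], rev_mm = rm[j],
                   strand = "+")
      if (is.null(best) || cand$length < best$length) best <- cand
    }
    best
  }
  out <- scan(template)
  if (is.null(out) && bothStrands) {
    out <- scan(revComp(template))
    if (!is.null(out)) out$strand <- "-"
  }
  if (is.null(out)) miss else out
}

#' Per-taxon amplification summary
#'
#' @param tm a [Taxmap-class] returned by [digitalPcr()].
#' @return `data.frame` with `taxon_id`, `name`, `n_obs`, `n_amplified`,
#'   `n_not_amplified`, `prop_amplified`.
#' @export
pcrSummary <- function(tm) {
  if (!"amplified" %in% names(tm@observations)) {
    stop("run digitalPcr() first", call. = FALSE)
  }
  df <- .materialize(tm, "taxa")
  df[, c("taxon_id", "name", "n_obs", "n_amplified", "n_not_amplified",
         "prop_amplified")]
}
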
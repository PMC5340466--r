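# Hierarchy-aware table verbs. All verbs return a new Taxmap that satisfies
# the class invariants; none renumber taxon IDs.

# Core structural subset: keep the taxa in `keepRows` (integer row indices).
# reassignTaxa: surviving taxa whose parent is removed are re-parented to
#   their nearest surviving ancestor (or become roots).
# reassignObs: observations on removed taxa move to their nearest surviving
#   ancestor (or are dropped if none survives); FALSE drops them.
.subsetTaxa <- function(tm, keepRows, reassignObs = TRUE, reassignTaxa = TRUE) {
  tx <- tm@taxa
  n <- nrow(tx)
  keep <- logical(n)
  keep[keepRows] <- TRUE
  pidx <- .parentIndex(tm)

  nearestKept <- function(i) {
    j <- pidx[i]
    while (!is.na(j) && !keep[j]) j <- pidx[j]
    j  # NA if no surviving ancestor
  }

  newTaxa <- tx[keep, , drop = FALSE]
  oldRow <- which(keep)
  # re-parent survivors
  newSup <- character(nrow(newTaxa))
  for (k in seq_along(oldRow)) {
    i <- oldRow[k]
    p <- pidx[i]
    if (!is.na(p) && keep[p]) {
      newSup[k] <- tx$taxon_id[p]
    } else if (reassignTaxa) {
      a <- nearestKept(i)
      newSup[k] <- if (is.na(a)) NA_character_ else tx$taxon_id[a]
    } else {
      newSup[k] <- NA_character_
    }
  }
  newTaxa$supertaxon_id <- newSup

  ob <- tm@observations
  obRow <- match(ob$taxon_id, tx$taxon_id)
  obKeep <- keep[obRow]
  if (reassignObs && any(!obKeep)) {
    dest <- vapply(obRow[!obKeep], nearestKept, integer(1))
    ok <- !is.na(dest)
    moved <- ob[!obKeep, , drop = FALSE][ok, , drop = FALSE]
    if (nrow(moved)) moved$taxon_id <- tx$taxon_id[dest[ok]]
    newObs <- rbind(ob[obKeep, , drop = FALSE], moved)
    # restore original row order
    newObs <- newObs[order(match(newObs$obs_id, ob$obs_id)), , drop = FALSE]
  } else {
    newObs <- ob[obKeep, , drop = FALSE]
  }
  rownames(newTaxa) <- NULL
  rownames(newObs) <- NULL
  out <- methods::new("Taxmap", taxa = newTaxa, observations = newObs,
                      taxonFuns = tm@taxonFuns, obsFuns = tm@obsFuns)
  methods::validObject(out)
  out
}

#' Filter taxa, preserving or discarding their relatives
#'
#' Keeps the taxa for which `pred` is `TRUE`, with explicit control over
#' what happens to everything attached to the removed taxa. Expansion
#' happens first (`keepSubtaxa`, `keepSupertaxa` add descendants /
#' ancestors of the selected set), then `invert` complements the final
#' set. Removed taxa's surviving children are re-parented to their nearest
#' surviving ancestor when `reassignTaxa = TRUE` (otherwise they become
#' roots), and observations of removed taxa move to their nearest surviving
#' ancestor when `reassignObs = TRUE` (otherwise they are dropped).
#'
#' @param tm a [Taxmap-class] object.
#' @param pred an expression over taxon columns (user or computed, e.g.
#'   `n_obs >= 10`), or a logical vector, or a vector of taxon IDs.
#' @param keepSubtaxa,keepSupertaxa also keep descendants / ancestors of
#'   taxa passing the filter.
#' @param reassignObs,reassignTaxa see Description.
#' @param invert complement the selection (after expansion).
#' @return A new [Taxmap-class].
#' @examples
#' tm <- parseRecords(c("A;B;C", "A;B;D"), parseSpec("(.*)", "class", ";"))
#' filterTaxa(tm, name != "C")
#' @export
filterTaxa <- function(tm, pred, keepSubtaxa = FALSE, keepSupertaxa = FALSE,
                       reassignObs = TRUE, reassignTaxa = TRUE, invert = FALSE) {
  sel <- .resolveTaxonSelection(tm, substitute(pred), parent.frame())
  selRows <- which(sel)
  if (keepSubtaxa && length(selRows)) {
    kids <- .childIndex(tm)
    selRows <- unique(c(selRows, unlist(lapply(selRows, function(i)
      .descendants(kids, i)), use.names = FALSE)))
  }
  if (keepSupertaxa && length(selRows)) {
    pidx <- .parentIndex(tm)
    anc <- integer()
    for (i in selRows) {
      j <- pidx[i]
      while (!is.na(j)) {
        anc <- c(anc, j)
        j <- pidx[j]
      }
    }
    selRows <- unique(c(selRows, anc))
  }
  if (invert) selRows <- setdiff(seq_len(nTaxa(tm)), selRows)
  .subsetTaxa(tm, sort(selRows), reassignObs = reassignObs,
              reassignTaxa = reassignTaxa)
}

# pred may be: logical vector, character vector of taxon ids, or an
# expression over (computed) taxon columns.
.resolveTaxonSelection <- function(tm, expr, env) {
  val <- .evalInTable(tm, "taxa", expr, env)
  n <- nTaxa(tm)
  if (is.character(val)) {
    idx <- .taxonIndex(tm, val)
    sel <- logical(n)
    sel[idx] <- TRUE
    return(sel)
  }
  if (is.numeric(val) && !is.logical(val)) {
    if (any(val < 1 | val > n)) stop("taxon row index out of range", call. = FALSE)
    sel <- logical(n)
    sel[as.integer(val)] <- TRUE
    return(sel)
  }
  val <- .recycleToRows(val, n, "taxon predicate")
  if (!is.logical(val)) stop("taxon predicate must be logical", call. = FALSE)
  val & !is.na(val)
}

#' Filter observations
#'
#' Removes observation rows failing `pred`. With `dropEmptyTaxa = TRUE`,
#' taxa left with no observations anywhere in their subtree are removed as
#' well.
#'
#' @param tm a [Taxmap-class] object.
#' @param pred expression over observation columns, or a logical vector.
#' @param dropEmptyTaxa remove taxa whose recursive observation count
#'   becomes zero.
#' @return A new [Taxmap-class].
#' @export
filterObs <- function(tm, pred, dropEmptyTaxa = FALSE) {
  val <- .evalInTable(tm, "obs", substitute(pred), parent.frame())
  n <- nrow(tm@observations)
  if (is.character(val)) {
    keep <- tm@observations$obs_id %in% val
  } else {
    val <- .recycleToRows(val, n, "observation predicate")
    if (!is.logical(val)) stop("observation predicate must be logical", call. = FALSE)
    keep <- val & !is.na(val)
  }
  tm@observations <- tm@observations[keep, , drop = FALSE]
  rownames(tm@observations) <- NULL
  if (dropEmptyTaxa) {
    counts <- nObs(tm)
    tm <- .subsetTaxa(tm, which(counts > 0L), reassignObs = FALSE,
                      reassignTaxa = TRUE)
  }
  methods::validObject(tm)
  tm
}

.PROTECTED_TAXA <- c("taxon_id", "supertaxon_id")
.PROTECTED_OBS <- c("obs_id", "taxon_id")

.mutateTable <- function(tm, table, exprs, env, transmute = FALSE) {
  df <- if (table == "taxa") tm@taxa else tm@observations
  protected <- if (table == "taxa") .PROTECTED_TAXA else .PROTECTED_OBS
  nms <- names(exprs)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("all new columns must be named", call. = FALSE)
  }
  clash <- intersect(nms, protected)
  if (length(clash)) {
    stop("cannot overwrite protected column(s): ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  newCols <- list()
  for (k in seq_along(exprs)) {
    # each expression sees prior new columns, like dplyr::mutate
    tmEval <- tm
    if (table == "taxa") tmEval@taxa <- df else tmEval@observations <- df
    val <- .evalInTable(tmEval, table, exprs[[k]], env)
    val <- .recycleToRows(val, nrow(df), paste0("column '", nms[k], "'"))
    df[[nms[k]]] <- val
    newCols[[nms[k]]] <- val
  }
  if (transmute) {
    df <- df[, c(protected, setdiff(nms, protected)), drop = FALSE]
  }
  if (table == "taxa") tm@taxa <- df else tm@observations <- df
  methods::validObject(tm)
  tm
}

#' Add or replace columns in the taxon or observation table
#'
#' `mutateTaxa()`/`mutateObs()` append columns computed from expressions
#' over existing or computed columns; `transmuteTaxa()`/`transmuteObs()`
#' keep only the protected key columns plus the new ones. The hierarchy and
#' the observation mapping are unchanged.
#'
#' @param tm a [Taxmap-class] object.
#' @param ... named expressions, e.g. `mutateTaxa(tm, double_obs = n_obs * 2)`.
#' @return A new [Taxmap-class].
#' @export
mutateTaxa <- function(tm, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  .mutateTable(tm, "taxa", exprs, parent.frame())
}

#' @rdname mutateTaxa
#' @export
mutateObs <- function(tm, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  .mutateTable(tm, "obs", exprs, parent.frame())
}

#' @rdname mutateTaxa
#' @export
transmuteTaxa <- function(tm, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  .mutateTable(tm, "taxa", exprs, parent.frame(), transmute = TRUE)
}

#' @rdname mutateTaxa
#' @export
transmuteObs <- function(tm, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  .mutateTable(tm, "obs", exprs, parent.frame(), transmute = TRUE)
}

#' Subset columns of the taxon or observation table
#'
#' Protected key columns (`taxon_id`, `supertaxon_id`; `obs_id`,
#' `taxon_id`) are always kept. `name` and `rank` are kept in the taxon
#' table (the class requires them).
#'
#' @param tm a [Taxmap-class] object.
#' @param columns character vector of column names to keep.
#' @return A new [Taxmap-class].
#' @export
selectTaxa <- function(tm, columns = character()) {
  unknown <- setdiff(columns, names(tm@taxa))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  keep <- unique(c("taxon_id", "supertaxon_id", "name", "rank", columns))
  tm@taxa <- tm@taxa[, keep, drop = FALSE]
  methods::validObject(tm)
  tm
}

#' @rdname selectTaxa
#' @export
selectObs <- function(tm, columns = character()) {
  unknown <- setdiff(columns, names(tm@observations))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  keep <- unique(c(.PROTECTED_OBS, columns))
  tm@observations <- tm@observations[, keep, drop = FALSE]
  methods::validObject(tm)
  tm
}

.arrangeTable <- function(tm, table, exprs, env) {
  df <- if (table == "taxa") tm@taxa else tm@observations
  keys <- lapply(exprs, function(e) .evalInTable(tm, table, e, env))
  ord <- do.call(order, keys)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (table == "taxa") tm@taxa <- df else tm@observations <- df
  methods::validObject(tm)
  tm
}

#' Order rows of the taxon or observation table
#'
#' Row order affects presentation and the ordering of traversal results
#' (which follow table row order) but never which taxa or observations are
#' related: filtering and traversal outcomes are invariant to arrangement.
#'
#' @param tm a [Taxmap-class] object.
#' @param ... sort-key expressions over (computed) columns; prefix a
#'   numeric key with `-` for decreasing order.
#' @return A new [Taxmap-class].
#' @export
arrangeTaxa <- function(tm, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  .arrangeTable(tm, "taxa", exprs, parent.frame())
}

#' @rdname arrangeTaxa
#' @export
arrangeObs <- function(tm, ...) {
  exprs <- as.list(substitute(list(...)))[-1L]
  .arrangeTable(tm, "obs", exprs, parent.frame())
}

# Sequential weighted draws without replacement: each draw picks index i
# with probability w[i] / sum(w over remaining), then removes it. This is
# the distribution the documentation and the tests' oracle assume.
.weightedDraw <- function(n, weights) {
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (sum(weights > 0) < n) {
    stop("fewer positively weighted rows (", sum(weights > 0),
         ") than requested (", n, ")", call. = FALSE)
  }
  remaining <- seq_along(weights)
  w <- weights
  out <- integer(n)
  for (k in seq_len(n)) {
    pick <- remaining[sample.int(length(remaining), 1L, prob = w)]
    out[k] <- pick
    drop <- match(pick, remaining)
    remaining <- remaining[-drop]
    w <- w[-drop]
  }
  out
}

#' Randomly subsample taxa or observations
#'
#' Weighted sampling without replacement by sequential renormalized draws:
#' each successive draw selects a row with probability proportional to its
#' weight among the rows still available. The selected rows are then
#' treated exactly as a [filterTaxa()] / [filterObs()] selection, so the
#' same flags control what happens to relatives of unselected taxa.
#'
#' @param tm a [Taxmap-class] object.
#' @param n number of rows to sample (must not exceed the table size).
#' @param weights non-negative numeric weights, one per row, or `NULL` for
#'   uniform; at least `n` must be positive.
#' @param seed integer seed; the draw is deterministic given the seed and
#'   global RNG state is left untouched.
#' @param keepSubtaxa,keepSupertaxa,reassignObs,reassignTaxa,invert passed
#'   to [filterTaxa()].
#' @return A new [Taxmap-class].
#' @export
sampleNTaxa <- function(tm, n, weights = NULL, seed = 1L,
                        keepSubtaxa = FALSE, keepSupertaxa = FALSE,
                        reassignObs = TRUE, reassignTaxa = TRUE,
                        invert = FALSE) {
  nt <- nTaxa(tm)
  if (n > nt) stop("cannot sample ", n, " of ", nt, " taxa", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nt)
  weights <- .recycleToRows(weights, nt, "weights")
  rows <- .withSeed(seed, .weightedDraw(n, weights))
  sel <- tm@taxa$taxon_id[rows]
  filterTaxa(tm, sel, keepSubtaxa = keepSubtaxa, keepSupertaxa = keepSupertaxa,
             reassignObs = reassignObs, reassignTaxa = reassignTaxa,
             invert = invert)
}

#' @rdname sampleNTaxa
#' @param dropEmptyTaxa passed to [filterObs()].
#' @export
sampleNObs <- function(tm, n, weights = NULL, seed = 1L, dropEmptyTaxa = FALSE) {
  no <- nrow(tm@observations)
  if (n > no) stop("cannot sample ", n, " of ", no, " observations", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, no)
  weights <- .recycleToRows(weights, no, "weights")
  rows <- .withSeed(seed, .weightedDraw(n, weights))
  sel <- tm@observations$obs_id[rows]
  filterObs(tm, sel, dropEmptyTaxa = dropEmptyTaxa)
}

#' Rank-targeted taxonomic subsampling
#'
#' For every taxon at the given rank: if its recursive observation count is
#' below `minCounts` the whole subtree is removed (observations dropped);
#' if above `maxCounts` its observations are uniformly subsampled down to
#' exactly `maxCounts`. Observations not under any taxon of the given rank
#' are untouched.
#'
#' @param tm a [Taxmap-class] object.
#' @param rank rank label to target (must occur in the taxon table).
#' @param minCounts minimum recursive observation count; below it the
#'   taxon and its subtree are excluded.
#' @param maxCounts maximum count; above it observations are subsampled.
#' @param seed integer seed for the subsampling draws.
#' @return A new [Taxmap-class].
#' @export
taxonomicSample <- function(tm, rank, minCounts = 0L, maxCounts = Inf, seed = 1L) {
  have <- unique(tm@taxa$rank[!is.na(tm@taxa$rank)])
  if (!rank %in% have) {
    stop("rank '", rank, "' not present; available ranks: ",
         paste(have, collapse = ", "), call. = FALSE)
  }
  stopifnot(minCounts >= 0, maxCounts > 0)
  rankRows <- which(!is.na(tm@taxa$rank) & tm@taxa$rank == rank)
  rankIds <- tm@taxa$taxon_id[rankRows]
  obsUnder <- observations(tm, rankIds, recursive = TRUE)

  removeTaxa <- character()
  removeObs <- character()
  .withSeed(seed, {
    for (tid in rankIds) {
      o <- obsUnder[[tid]]
      if (length(o) < minCounts) {
        removeTaxa <- c(removeTaxa, tid)
        removeObs <- c(removeObs, o)
      } else if (length(o) > maxCounts) {
        keep <- sort(sample.int(length(o), maxCounts))
        removeObs <- c(removeObs, o[-keep])
      }
    }
  })
  if (length(removeObs)) {
    keepObs <- !(tm@observations$obs_id %in% removeObs)
    tm@observations <- tm@observations[keepObs, , drop = FALSE]
    rownames(tm@observations) <- NULL
  }
  if (length(removeTaxa)) {
    drop <- unique(c(unlist(subtaxa(tm, removeTaxa, recursive = TRUE,
                                    includeInput = TRUE), use.names = FALSE)))
    tm <- .subsetTaxa(tm, which(!(tm@taxa$taxon_id %in% drop)),
                      reassignObs = FALSE, reassignTaxa = TRUE)
  }
  methods::validObject(tm)
  tm
}
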
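#' Construct a Taxmap
#'
#' @param taxa `data.frame` with at least `taxon_id` and `supertaxon_id`
#'   columns (`NA` supertaxon for roots); `name` defaults to `taxon_id` and
#'   `rank` to `NA` if absent.
#' @param observations `data.frame` with at least `obs_id` and `taxon_id`;
#'   may be omitted for a taxonomy with no observations.
#' @param taxonFuns,obsFuns named lists of column-generating functions,
#'   each `function(tm)` returning one value per row of the respective
#'   table. `n_obs` (see [nObs()]) is always registered.
#'
#' @return A validated [Taxmap-class] object.
#' @examples
#' tm <- taxmap(
#'   taxa = data.frame(taxon_id = c("t_1", "t_2"),
#'                     supertaxon_id = c(NA, "t_1"),
#'                     name = c("Bacteria", "Firmicutes")),
#'   observations = data.frame(obs_id = "o_1", taxon_id = "t_2")
#' )
#' roots(tm)
#' @export
taxmap <- function(taxa,
                   observations = data.frame(obs_id = character(),
                                             taxon_id = character()),
                   taxonFuns = list(),
                   obsFuns = list()) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(taxa)) stop("taxa needs a taxon_id column")
  if (!"supertaxon_id" %in% names(taxa)) stop("taxa needs a supertaxon_id column")
  if (!"name" %in% names(taxa)) taxa$name <- taxa$taxon_id
  if (!"rank" %in% names(taxa)) taxa$rank <- rep(NA_character_, nrow(taxa))
  taxa$taxon_id <- as.character(taxa$taxon_id)
  taxa$supertaxon_id <- as.character(taxa$supertaxon_id)
  taxa$name <- as.character(taxa$name)
  taxa$rank <- as.character(taxa$rank)
  first <- c("taxon_id", "supertaxon_id", "name", "rank")
  taxa <- taxa[, c(first, setdiff(names(taxa), first)), drop = FALSE]
  if (!"obs_id" %in% names(observations)) stop("observations needs an obs_id column")
  if (!"taxon_id" %in% names(observations)) stop("observations needs a taxon_id column")
  observations$obs_id <- as.character(observations$obs_id)
  observations$taxon_id <- as.character(observations$taxon_id)
  ofirst <- c("obs_id", "taxon_id")
  observations <- observations[, c(ofirst, setdiff(names(observations), ofirst)),
                               drop = FALSE]
  rownames(taxa) <- NULL
  rownames(observations) <- NULL
  if (!"n_obs" %in% names(taxonFuns)) taxonFuns$n_obs <- nObs
  methods::new("Taxmap", taxa = taxa, observations = observations,
               taxonFuns = taxonFuns, obsFuns = obsFuns)
}

#' @describeIn taxmap Number of taxa.
#' @param tm a [Taxmap-class] object.
#' @export
nTaxa <- function(tm) nrow(tm@taxa)

#' Accessors for the two Taxmap tables
#'
#' `taxonTable()` and `obsTable()` return the stored tables. With
#' `computed = TRUE`, registered column-generating functions are evaluated
#' and appended (user columns shadow computed ones with a warning), so the
#' result always reflects the current state of the object.
#'
#' @param tm a [Taxmap-class] object.
#' @param computed logical; append computed columns?
#' @return A `data.frame`.
#' @export
taxonTable <- function(tm, computed = FALSE) {
  if (computed) .materialize(tm, "taxa") else tm@taxa
}

#' @rdname taxonTable
#' @export
obsTable <- function(tm, computed = FALSE) {
  if (computed) .materialize(tm, "obs") else tm@observations
}

#' @rdname taxonTable
#' @export
taxonIds <- function(tm) tm@taxa$taxon_id

#' @rdname taxonTable
#' @export
obsIds <- function(tm) tm@observations$obs_id

# Materialize a table with its computed columns.
.materialize <- function(tm, table = c("taxa", "obs")) {
  table <- match.arg(table)
  df <- if (table == "taxa") tm@taxa else tm@observations
  funs <- if (table == "taxa") tm@taxonFuns else tm@obsFuns
  for (nm in names(funs)) {
    if (nm %in% names(df)) {
      warning("user column '", nm, "' shadows the computed column of the same name",
              call. = FALSE)
      next
    }
    df[[nm]] <- funs[[nm]](tm)
  }
  df
}

#' Register a column-generating function
#'
#' @param tm a [Taxmap-class] object.
#' @param name column name the function generates.
#' @param fun `function(tm)` returning one value per row.
#' @param table which table the column belongs to.
#' @return The modified `Taxmap`.
#' @export
registerColumn <- function(tm, name, fun, table = c("taxa", "obs")) {
  table <- match.arg(table)
  stopifnot(is.function(fun), is.character(name), length(name) == 1L)
  if (table == "taxa") tm@taxonFuns[[name]] <- fun else tm@obsFuns[[name]] <- fun
  tm
}

#' Display a Taxmap summary
#' @param object a [Taxmap-class] object.
#' @return `NULL`, invisibly.
#' @export
setMethod("show", "Taxmap", function(object) {
  tx <- object@taxa
  ob <- object@observations
  cat("Taxmap object\n")
  cat(sprintf("  %d taxa (%d roots), %d observations\n",
              nrow(tx), sum(is.na(tx$supertaxon_id)), nrow(ob)))
  utx <- setdiff(names(tx), c("taxon_id", "supertaxon_id", "name", "rank"))
  uob <- setdiff(names(ob), c("obs_id", "taxon_id"))
  cat("  taxon columns:", paste(c("taxon_id", "supertaxon_id", "name", "rank", utx),
                                collapse = ", "), "\n")
  cat("  obs columns:  ", paste(c("obs_id", "taxon_id", uob), collapse = ", "), "\n")
  cat("  computed:     ",
      paste(c(paste0(names(object@taxonFuns), " (taxa)"),
              paste0(names(object@obsFuns), " (obs)")), collapse = ", "), "\n")
  invisible(NULL)
})

# ---- index helpers -------------------------------------------------------

# Row indices of taxon ids, with a clear error on unknown ids.
.taxonIndex <- function(tm, ids) {
  idx <- match(ids, tm@taxa$taxon_id)
  if (anyNA(idx)) {
    stop("unknown taxon ID(s): ", .fmtIds(ids[is.na(idx)]), call. = FALSE)
  }
  idx
}

# Parent row index per taxon (NA for roots).
.parentIndex <- function(tm) {
  match(tm@taxa$supertaxon_id, tm@taxa$taxon_id)
}

# children[[i]] = integer row indices of direct children of taxon row i.
.childIndex <- function(tm) {
  n <- nrow(tm@taxa)
  pidx <- .parentIndex(tm)
  kids <- vector("list", n)
  nonroot <- which(!is.na(pidx))
  if (length(nonroot)) {
    sp <- split(nonroot, pidx[nonroot])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

# All descendant row indices of row i (excluding i), in row order.
.descendants <- function(kids, i) {
  out <- integer()
  queue <- kids[[i]]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(kids[queue], use.names = FALSE)
  }
  sort(unique(out))
}

# ---- traversal primitives ------------------------------------------------

#' Root taxa of a Taxmap
#'
#' @param tm a [Taxmap-class] object.
#' @return Character vector of the taxon IDs with no supertaxon, in
#'   taxon-table row order.
#' @export
roots <- function(tm) {
  tm@taxa$taxon_id[is.na(tm@taxa$supertaxon_id)]
}

#' Subtaxa, supertaxa and observations of taxa
#'
#' The traversal primitives of the Taxmap hierarchy. `subtaxa()` walks the
#' child relation, `supertaxa()` the parent relation, and `observations()`
#' maps taxa to the observation records assigned to them (directly, or
#' anywhere in their subtree with `recursive = TRUE`).
#'
#' Results for `subtaxa()` and `observations()` are ordered by table row
#' order; `supertaxa()` returns nearest ancestor first (the query taxon
#' first when `includeInput = TRUE`).
#'
#' @param tm a [Taxmap-class] object.
#' @param ids taxon IDs to query; defaults to all taxa.
#' @param recursive logical; transitive closure (`TRUE`) or one step only.
#' @param includeInput logical; include the query taxon itself.
#' @return A named list, one element per queried ID.
#' @examples
#' tm <- taxmap(data.frame(taxon_id = c("a", "b", "c"),
#'                         supertaxon_id = c(NA, "a", "b")))
#' subtaxa(tm, "a")          # list(a = c("b", "c"))
#' supertaxa(tm, "c")        # list(c = c("b", "a"))
#' @export
subtaxa <- function(tm, ids = taxonIds(tm), recursive = TRUE, includeInput = FALSE) {
  idx <- .taxonIndex(tm, ids)
  kids <- .childIndex(tm)
  all_ids <- tm@taxa$taxon_id
  out <- lapply(idx, function(i) {
    rows <- if (recursive) .descendants(kids, i) else sort(kids[[i]] %||% integer())
    if (includeInput) rows <- sort(unique(c(i, rows)))
    all_ids[rows]
  })
  names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname subtaxa
#' @export
supertaxa <- function(tm, ids = taxonIds(tm), recursive = TRUE, includeInput = FALSE) {
  idx <- .taxonIndex(tm, ids)
  pidx <- .parentIndex(tm)
  all_ids <- tm@taxa$taxon_id
  out <- lapply(idx, function(i) {
    rows <- if (includeInput) i else integer()
    j <- pidx[i]
    while (!is.na(j)) {
      rows <- c(rows, j)
      if (!recursive) break
      j <- pidx[j]
    }
    all_ids[rows]
  })
  names(out) <- ids
  out
}

#' @rdname subtaxa
#' @export
observations <- function(tm, ids = taxonIds(tm), recursive = TRUE) {
  idx <- .taxonIndex(tm, ids)
  obs_taxon_row <- match(tm@observations$taxon_id, tm@taxa$taxon_id)
  kids <- .childIndex(tm)
  out <- lapply(idx, function(i) {
    rows <- if (recursive) c(i, .descendants(kids, i)) else i
    tm@observations$obs_id[obs_taxon_row %in% rows]
  })
  names(out) <- ids
  out
}

#' Number of observations per taxon (computed column)
#'
#' Counts the observations assigned to each taxon or any of its subtaxa.
#' Registered by default as the computed taxon column `n_obs`, so filtering
#' or sampling the object never leaves stale counts.
#'
#' @param tm a [Taxmap-class] object.
#' @return Integer vector, one count per taxon row.
#' @export
nObs <- function(tm) {
  n <- nrow(tm@taxa)
  counts <- integer(n)
  obs_row <- match(tm@observations$taxon_id, tm@taxa$taxon_id)
  direct <- tabulate(obs_row, nbins = n)
  # accumulate direct counts up the parent chain
  pidx <- .parentIndex(tm)
  counts <- direct
  ord <- order(.depths(pidx), decreasing = TRUE)  # deepest first
  for (i in ord) {
    p <- pidx[i]
    if (!is.na(p)) counts[p] <- counts[p] + counts[i]
  }
  counts
}

# depth of each taxon row (roots = 0)
.depths <- function(pidx) {
  n <- length(pidx)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- integer()
    j <- i
    while (!is.na(j) && is.na(depth[j])) {
      chain <- c(chain, j)
      j <- pidx[j]
    }
    base <- if (is.na(j)) -1L else depth[j]
    depth[rev(chain)] <- base + seq_along(chain)
  }
  depth
}

#' Validate a Taxmap
#'
#' Checks referential integrity (unique IDs, parents present, observations
#' mapped to existing taxa) and the forest property (no cycles). Called
#' implicitly by the class validity machinery; exported so pipelines and
#' tests can assert integrity explicitly.
#'
#' @param tm a [Taxmap-class] object.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validateTaxmap <- function(tm) {
  res <- .validTaxmap(tm)
  if (!isTRUE(res)) stop(paste(res, collapse = "; "), call. = FALSE)
  invisible(TRUE)
}
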
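#' Taxmap: a taxonomic hierarchy plus observations mapped to it
#'
#' A `Taxmap` couples two tables. The taxon table is an edge list encoding a
#' forest: each row is a taxon with a unique `taxon_id`, a `supertaxon_id`
#' (`NA` for roots), a `name`, an optional `rank`, and any number of user
#' columns. The observation table holds records (sequences, OTUs, votes --
#' anything assigned to exactly one taxon) keyed by `obs_id`, with a
#' `taxon_id` pointing into the taxon table plus arbitrary user columns.
#'
#' In addition, each table carries a registry of column-generating functions
#' (`taxonFuns`, `obsFuns`). A registered function takes the `Taxmap` and
#' returns one value per row; the column it generates is re-evaluated every
#' time it is referenced, so derived quantities such as [nObs()] never go
#' stale when the object is filtered or subsampled. If a user column shares
#' a name with a registered function, the user column wins and a warning is
#' emitted.
#'
#' @slot taxa `data.frame` with columns `taxon_id`, `supertaxon_id`, `name`,
#'   `rank`, plus user columns.
#' @slot observations `data.frame` with columns `obs_id`, `taxon_id`, plus
#'   user columns.
#' @slot taxonFuns named list of `function(tm)` returning one value per taxon.
#' @slot obsFuns named list of `function(tm)` returning one value per
#'   observation.
#'
#' @seealso [taxmap()], [roots()], [subtaxa()], [supertaxa()],
#'   [observations()], [filterTaxa()]
#' @aliases Taxmap-class
#' @exportClass Taxmap
setClass("Taxmap",
  representation(
    taxa = "data.frame",
    observations = "data.frame",
    taxonFuns = "list",
    obsFuns = "list"
  )
)

.validTaxmap <- function(object) {
  msgs <- character()
  tx <- object@taxa
  ob <- object@observations
  need <- c("taxon_id", "supertaxon_id", "name", "rank")
  if (!all(need %in% names(tx))) {
    return(paste("taxon table must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(c("obs_id", "taxon_id") %in% names(ob))) {
    return("observation table must have columns: obs_id, taxon_id")
  }
  ids <- tx$taxon_id
  if (anyNA(ids) || any(!nzchar(ids))) msgs <- c(msgs, "taxon_id values must be non-empty")
  if (anyDuplicated(ids)) msgs <- c(msgs, "taxon_id values must be unique")
  sup <- tx$supertaxon_id
  bad <- !is.na(sup) & !(sup %in% ids)
  if (any(bad)) {
    msgs <- c(msgs, paste0("supertaxon_id not found in taxon table: ",
                           .fmtIds(sup[bad])))
  }
  # acyclicity: walking parent pointers must terminate within n steps
  if (length(ids) && !length(msgs)) {
    pidx <- match(sup, ids)
    depth <- rep(NA_integer_, length(ids))
    for (i in seq_along(ids)) {
      j <- i
      steps <- 0L
      while (!is.na(j)) {
        steps <- steps + 1L
        if (steps > length(ids)) {
          msgs <- c(msgs, paste0("cycle in supertaxon_id pointers at taxon ", ids[i]))
          break
        }
        j <- pidx[j]
      }
      depth[i] <- steps
    }
  }
  if (anyDuplicated(ob$obs_id)) msgs <- c(msgs, "obs_id values must be unique")
  orphan <- !(ob$taxon_id %in% ids)
  if (any(orphan)) {
    msgs <- c(msgs, paste0("observation taxon_id not found in taxon table: ",
                           .fmtIds(ob$taxon_id[orphan])))
  }
  if (length(object@taxonFuns) && is.null(names(object@taxonFuns))) {
    msgs <- c(msgs, "taxonFuns must be a named list")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("Taxmap", .validTaxmap)

#' ParseSpec: a regex plus a key describing its capture groups
#'
#' Drives [parseRecords()] and [parseFasta()]. The regular expression must
#' contain at least one capture group; `key` names the role of each group:
#' `"class"` (a full lineage string, split on `classSep` into ordered levels,
#' optionally split again on `rankSep` into `rank` and `name`),
#' `"taxon_name"` (a single taxon name), `"taxon_id"` (an identifier stored
#' verbatim as a taxon column), or `"obs_info"` (stored as an observation
#' column named by the key element's name).
#'
#' @slot regex character(1), a regular expression with capture groups.
#' @slot key character vector of role tags, one per capture group; may be
#'   named (`names(key)` become column names for `obs_info` captures).
#' @slot classSep character(1) separator between lineage levels.
#' @slot rankSep character(1) or `NA` separator between rank and name inside
#'   one level (e.g. `"__"` in `"p__Firmicutes"`).
#' @slot reverseLevels logical(1); `TRUE` for leaf-first lineage formats.
#' @aliases ParseSpec-class
#' @seealso [parseSpec()]
#' @exportClass ParseSpec
setClass("ParseSpec",
  representation(
    regex = "character",
    key = "character",
    classSep = "character",
    rankSep = "character",
    reverseLevels = "logical"
  )
)

.countCaptureGroups <- function(regex) {
  # capture groups = unescaped "(" not followed by "?" (no named-group syntax)
  chars <- strsplit(regex, "", fixed = TRUE)[[1]]
  n <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\") {
      i <- i + 2L
      next
    }
    if (ch == "(" && !(i < length(chars) && chars[i + 1L] == "?")) n <- n + 1L
    i <- i + 1L
  }
  n
}

.validParseSpec <- function(object) {
  msgs <- character()
  roles <- c("class", "taxon_name", "taxon_id", "obs_info")
  if (length(object@regex) != 1L || is.na(object@regex)) {
    msgs <- c(msgs, "regex must be a single string")
  }
  if (!all(object@key %in% roles)) {
    msgs <- c(msgs, paste0("key roles must be in {", paste(roles, collapse = ", "), "}"))
  }
  ng <- .countCaptureGroups(object@regex)
  if (length(object@key) != ng) {
    msgs <- c(msgs, paste0("key has ", length(object@key), " entries but regex has ",
                           ng, " capture groups"))
  }
  for (r in c("class", "taxon_name", "taxon_id")) {
    if (sum(object@key == r) > 1L) msgs <- c(msgs, paste0("at most one '", r, "' key allowed"))
  }
  if (!any(object@key %in% c("class", "taxon_name", "taxon_id"))) {
    msgs <- c(msgs, "key must contain a classification-bearing role (class, taxon_name or taxon_id)")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("ParseSpec", .validParseSpec)

#' PrimerPair: a degenerate primer pair for in-silico PCR
#'
#' Both primers are written 5'\eqn{\to}3' in IUPAC DNA code, the reverse
#' primer as ordered on the opposite strand (as it would be supplied to a
#' thermocycler). `maxMismatchPercent` is the binding-site mismatch budget:
#' a primer of length L may mismatch at up to `floor(maxMismatchPercent/100
#' * L)` positions.
#'
#' @slot forward character(1) IUPAC DNA string.
#' @slot reverse character(1) IUPAC DNA string.
#' @slot maxMismatchPercent numeric(1) in \[0, 100\].
#' @aliases PrimerPair-class
#' @seealso [primerPair()], [digitalPcr()]
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(
    forward = "character",
    reverse = "character",
    maxMismatchPercent = "numeric"
  )
)

.validPrimerPair <- function(object) {
  msgs <- character()
  for (side in c("forward", "reverse")) {
    s <- slot(object, side)
    if (length(s) != 1L || is.na(s) || !nzchar(s)) {
      msgs <- c(msgs, paste(side, "primer must be a non-empty string"))
    } else {
      bad <- setdiff(strsplit(toupper(s), "")[[1]], names(.IUPAC_BITS))
      if (length(bad)) {
        msgs <- c(msgs, paste0(side, " primer has non-IUPAC characters: ",
                               paste(unique(bad), collapse = ", ")))
      }
    }
  }
  p <- object@maxMismatchPercent
  if (length(p) != 1L || is.na(p) || p < 0 || p > 100) {
    msgs <- c(msgs, "maxMismatchPercent must be in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("PrimerPair", .validPrimerPair)
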
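#' Create a ParseSpec
#'
#' @param regex regular expression with \eqn{\ge}1 capture group.
#' @param key character vector of role tags (`"class"`, `"taxon_name"`,
#'   `"taxon_id"`, `"obs_info"`), one per capture group. Names of
#'   `obs_info` elements become observation column names (unnamed
#'   `obs_info` captures are called `info_1`, `info_2`, ...).
#' @param classSep separator between lineage levels in a `class` capture.
#' @param rankSep separator between rank label and name within one level
#'   (e.g. `"__"` for `"p__Firmicutes"`), or `NA` for plain names.
#' @param reverseLevels `TRUE` if lineages are written leaf-first.
#' @return A validated [ParseSpec-class].
#' @examples
#' parseSpec("(.*)", key = "class", classSep = ";")
#' @export
parseSpec <- function(regex, key, classSep = ";", rankSep = NA_character_,
                      reverseLevels = FALSE) {
  methods::new("ParseSpec", regex = regex, key = key,
               classSep = as.character(classSep),
               rankSep = as.character(rankSep),
               reverseLevels = isTRUE(reverseLevels))
}

#' Load a ParseSpec from a YAML or JSON config block
#'
#' The block must contain `regex` and `key`, and may contain
#' `class_separator`, `rank_separator` and `reverse_levels`.
#'
#' @param path file path to a YAML (or JSON, a YAML subset) file.
#' @return A [ParseSpec-class].
#' @export
parseSpecFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regex) || is.null(cfg$key)) {
    stop("config must contain 'regex' and 'key'")
  }
  parseSpec(cfg$regex, unlist(cfg$key),
            classSep = cfg$class_separator %||% ";",
            rankSep = cfg$rank_separator %||% NA_character_,
            reverseLevels = isTRUE(cfg$reverse_levels))
}

# Split one "class" capture into a lineage: list(name=, rank=) per level,
# root-most first. Empty levels are dropped with a warning.
.splitLineage <- function(text, spec) {
  levels <- strsplit(text, spec@classSep, fixed = TRUE)[[1]]
  levels <- trimws(levels)
  if (any(!nzchar(levels))) {
    warning("dropping empty lineage level(s) in: ", text, call. = FALSE)
    levels <- levels[nzchar(levels)]
  }
  if (spec@reverseLevels) levels <- rev(levels)
  if (!is.na(spec@rankSep)) {
    parts <- strsplit(levels, spec@rankSep, fixed = TRUE)
    rank <- vapply(parts, function(p) if (length(p) >= 2L) p[[1]] else NA_character_,
                   character(1))
    name <- vapply(parts, function(p) if (length(p) >= 2L)
      paste(p[-1L], collapse = spec@rankSep) else p[[1]], character(1))
  } else {
    rank <- rep(NA_character_, length(levels))
    name <- levels
  }
  list(name = name, rank = rank)
}

#' Parse taxonomic data from arbitrary text into a Taxmap
#'
#' The universal parser: any format definable by a regular expression with
#' capture groups can be converted into a [Taxmap-class]. Each input string
#' becomes one observation; lineages are deduplicated so inputs sharing a
#' classification prefix share taxon rows. Two taxa with the same name
#' under different parents stay distinct: taxon identity is the full
#' root-to-taxon path of (name, rank) pairs.
#'
#' @param texts character vector of input records (e.g. FASTA headers).
#' @param spec a [ParseSpec-class] describing the format.
#' @param onMismatch what to do with texts not matching `spec@regex`:
#'   `"error"` (default; reports the first offender and its index) or
#'   `"skip"` (drop with a warning giving the count).
#' @return A [Taxmap-class]; observation column `input_index` records each
#'   record's position in `texts`.
#' @examples
#' tm <- parseRecords(c("K;A", "K;B"), parseSpec("(.*)", "class", ";"))
#' nTaxa(tm)  # 3: K and its children A, B
#' @export
parseRecords <- function(texts, spec, onMismatch = c("error", "skip")) {
  onMismatch <- match.arg(onMismatch)
  stopifnot(methods::is(spec, "ParseSpec"))
  m <- regmatches(texts, regexec(spec@regex, texts))
  ok <- lengths(m) == (length(spec@key) + 1L)
  if (!all(ok)) {
    if (onMismatch == "error") {
      i <- which(!ok)[1L]
      stop("input ", i, " does not match the parse regex: ", texts[i], call. = FALSE)
    }
    warning(sum(!ok), " input(s) did not match the parse regex and were skipped",
            call. = FALSE)
  }
  kept <- which(ok)
  caps <- lapply(m[kept], function(x) x[-1L])

  keyNames <- names(spec@key)
  if (is.null(keyNames)) keyNames <- rep("", length(spec@key))
  infoIdx <- which(spec@key == "obs_info")
  infoNames <- ifelse(nzchar(keyNames[infoIdx]), keyNames[infoIdx],
                      paste0("info_", seq_along(infoIdx)))

  classIdx <- which(spec@key == "class")
  nameIdx <- which(spec@key == "taxon_name")
  tidIdx <- which(spec@key == "taxon_id")

  # Taxon registry keyed by the full path.
  pathKey <- character()      # key -> position
  taxon_id <- character()
  supertaxon_id <- character()
  taxon_name <- character()
  taxon_rank <- character()
  taxon_extid <- character()  # verbatim ids from a taxon_id capture
  counter <- 0L

  internTaxon <- function(key, parent, name, rank) {
    pos <- match(key, pathKey)
    if (!is.na(pos)) {
      if (!is.na(rank) && !is.na(taxon_rank[pos]) && rank != taxon_rank[pos]) {
        warning("conflicting rank for taxon '", name, "': keeping '",
                taxon_rank[pos], "', ignoring '", rank, "'", call. = FALSE)
      }
      if (is.na(taxon_rank[pos]) && !is.na(rank)) taxon_rank[pos] <<- rank
      return(pos)
    }
    counter <<- counter + 1L
    pathKey[counter] <<- key
    taxon_id[counter] <<- paste0("t_", counter)
    supertaxon_id[counter] <<- if (is.na(parent)) NA_character_ else taxon_id[parent]
    taxon_name[counter] <<- name
    taxon_rank[counter] <<- rank
    taxon_extid[counter] <<- NA_character_
    counter
  }

  obs_taxon <- character(length(kept))
  infoCols <- lapply(infoIdx, function(i) character(length(kept)))
  names(infoCols) <- infoNames

  SEP <- "\x1f"  # path-key separator (unit separator control char)
  for (r in seq_along(kept)) {
    cp <- caps[[r]]
    if (length(classIdx)) {
      lin <- .splitLineage(cp[classIdx], spec)
      if (!length(lin$name)) {
        stop("input ", kept[r], " yields an empty lineage: ", texts[kept[r]],
             call. = FALSE)
      }
      parent <- NA_integer_
      key <- ""
      for (lv in seq_along(lin$name)) {
        key <- paste0(key, SEP, lin$name[lv], "\x1e", lin$rank[lv])
        parent <- internTaxon(key, parent, lin$name[lv], lin$rank[lv])
      }
      pos <- parent
    } else if (length(nameIdx)) {
      nm <- trimws(cp[nameIdx])
      pos <- internTaxon(paste0(SEP, nm), NA_integer_, nm, NA_character_)
    } else {
      ext <- trimws(cp[tidIdx])
      pos <- internTaxon(paste0(SEP, ext), NA_integer_, ext, NA_character_)
      taxon_extid[pos] <- ext
    }
    if (length(tidIdx) && length(classIdx) + length(nameIdx) > 0L) {
      taxon_extid[pos] <- trimws(cp[tidIdx])
    }
    obs_taxon[r] <- taxon_id[pos]
    for (k in seq_along(infoIdx)) infoCols[[k]][r] <- cp[infoIdx[k]]
  }

  taxa <- data.frame(taxon_id = taxon_id, supertaxon_id = supertaxon_id,
                     name = taxon_name, rank = taxon_rank,
                     stringsAsFactors = FALSE)
  if (any(!is.na(taxon_extid))) taxa$external_id <- taxon_extid
  obs <- data.frame(obs_id = sprintf("o_%d", seq_along(kept)),
                    taxon_id = obs_taxon,
                    input_index = kept,
                    stringsAsFactors = FALSE)
  for (nm in names(infoCols)) obs[[nm]] <- infoCols[[nm]]
  taxmap(taxa, obs)
}

#' Render observation lineages as delimited strings
#'
#' The inverse of [parseRecords()]: for each observation, the root-to-taxon
#' path of names (optionally `rank<rankSep>name`) joined with `classSep`.
#' `parseRecords(writeLineages(tm), ...)` reconstructs a Taxmap isomorphic
#' to `tm`.
#'
#' @param tm a [Taxmap-class] object.
#' @param classSep separator between levels.
#' @param rankSep separator between rank and name, or `NA` for names only.
#' @return Character vector, one lineage per observation row.
#' @export
writeLineages <- function(tm, classSep = ";", rankSep = NA_character_) {
  tx <- tm@taxa
  pidx <- .parentIndex(tm)
  renderLevel <- function(i) {
    nm <- tx$name[i]
    if (grepl(classSep, nm, fixed = TRUE)) {
      stop("taxon name '", nm, "' contains the class separator '", classSep,
           "'; rendering would be ambiguous", call. = FALSE)
    }
    if (is.na(rankSep)) return(nm)
    rk <- tx$rank[i]
    if (is.na(rk)) {
      stop("taxon '", nm, "' has no rank; cannot render with a rank separator",
           call. = FALSE)
    }
    if (grepl(rankSep, rk, fixed = TRUE) || grepl(rankSep, nm, fixed = TRUE)) {
      stop("rank separator '", rankSep, "' occurs inside '", rk, rankSep, nm,
           "'; rendering would be ambiguous", call. = FALSE)
    }
    paste0(rk, rankSep, nm)
  }
  # memoized path strings per taxon row
  paths <- rep(NA_character_, nrow(tx))
  pathOf <- function(i) {
    if (!is.na(paths[i])) return(paths[i])
    lev <- renderLevel(i)
    p <- pidx[i]
    res <- if (is.na(p)) lev else paste0(pathOf(p), classSep, lev)
    paths[i] <<- res
    res
  }
  idx <- match(tm@observations$taxon_id, tx$taxon_id)
  vapply(idx, pathOf, character(1))
}
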
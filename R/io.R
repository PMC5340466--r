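#' Parse a FASTA file with taxonomy-bearing headers into a Taxmap
#'
#' Headers (without the leading `>`) are parsed with `spec` exactly as in
#' [parseRecords()]; each record's sequence is stored in the observation
#' column `sequence`, uppercased, with whitespace and the alignment
#' characters `*` and `-` stripped. Wrapped sequence lines are joined.
#' Duplicate headers are allowed and yield distinct observations.
#'
#' @param path path to a FASTA file.
#' @param spec a [ParseSpec-class] applied to header lines.
#' @param onMismatch see [parseRecords()].
#' @return A [Taxmap-class] with a `sequence` observation column.
#' @export
parseFasta <- function(path, spec, onMismatch = c("error", "skip")) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(recs)
  seqs <- toupper(gsub("[\\s*-]", "", as.character(recs), perl = TRUE))
  tm <- parseRecords(headers, spec, onMismatch = onMismatch)
  obs <- tm@observations
  obs$sequence <- unname(seqs[obs$input_index])
  tm@observations <- obs
  methods::validObject(tm)
  tm
}

#' Read and write a Taxmap as a pair of TSV files
#'
#' `writeTaxmap()` writes `taxa.tsv` and `observations.tsv` into a
#' directory, each with a header row; `supertaxon_id` uses the literal
#' string `NA` for roots. `readTaxmap()` reads them back; the round trip is
#' lossless for string and integer columns. Computed columns are not
#' serialized (they are functions, re-registered on read: `n_obs` always,
#' plus the digital-PCR summary columns when the observation table carries
#' amplification results).
#'
#' @param tm a [Taxmap-class] object.
#' @param dir directory to write into (created if needed) / read from.
#' @return `writeTaxmap()` returns `dir` invisibly; `readTaxmap()` a
#'   [Taxmap-class].
#' @export
writeTaxmap <- function(tm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(tm@taxa, file.path(dir, "taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(tm@observations, file.path(dir, "observations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

#' @rdname writeTaxmap
#' @export
readTaxmap <- function(dir) {
  tfile <- file.path(dir, "taxa.tsv")
  ofile <- file.path(dir, "observations.tsv")
  if (!file.exists(tfile) || !file.exists(ofile)) {
    stop("directory must contain taxa.tsv and observations.tsv: ", dir,
         call. = FALSE)
  }
  taxa <- utils::read.delim(tfile, stringsAsFactors = FALSE,
                            colClasses = c(taxon_id = "character",
                                           supertaxon_id = "character",
                                           name = "character",
                                           rank = "character"))
  obs <- utils::read.delim(ofile, stringsAsFactors = FALSE,
                           colClasses = c(obs_id = "character",
                                          taxon_id = "character"))
  tm <- taxmap(taxa, obs)
  if ("amplified" %in% names(obs)) tm <- .registerPcrColumns(tm)
  tm
}

#' Export the taxon forest as Newick trees
#'
#' One Newick string per root, taxon names as labels, no branch lengths.
#' Labels containing Newick metacharacters are single-quoted.
#'
#' @param tm a [Taxmap-class] object.
#' @param path optional file; trees are written one per line.
#' @return Character vector of Newick strings (invisibly if `path` given).
#' @export
exportNewick <- function(tm, path = NULL) {
  kids <- .childIndex(tm)
  nms <- tm@taxa$name
  quoteLabel <- function(x) {
    if (grepl("[(),:;\\[\\]' \t]", x, perl = TRUE)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  build <- function(i) {
    ch <- kids[[i]]
    lab <- quoteLabel(nms[i])
    if (is.null(ch) || !length(ch)) return(lab)
    paste0("(", paste(vapply(ch, build, character(1)), collapse = ","), ")", lab)
  }
  rootRows <- which(is.na(tm@taxa$supertaxon_id))
  out <- vapply(rootRows, function(i) paste0(build(i), ";"), character(1))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
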
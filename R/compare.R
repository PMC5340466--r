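# Pairwise community comparison: per-taxon log2 ratio of median read
# proportions between two sample groups, Wilcoxon rank-sum significance,
# Benjamini-Hochberg FDR correction, and significance-gated values ready
# to be mapped onto heat-tree node color.

#' Per-sample read proportions
#'
#' Divides each sample (column) of a taxon-by-sample count matrix by its
#' column sum, so every column sums to one.
#'
#' @param counts numeric matrix, rows = taxa (rownames = taxon IDs),
#'   columns = samples.
#' @return Matrix of proportions with the same dimnames.
#' @export
readProportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  sums <- colSums(counts)
  zero <- sums == 0
  if (any(zero)) {
    nm <- colnames(counts)[zero] %||% which(zero)
    stop("zero-sum sample column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2L, sums, "/")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration of the null permutation distribution when
#' the combined sample size is at most 12 and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return Two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  if (all(c(x, y) == x[1L])) return(1)  # no evidence; avoids zero-variance NaN
  if (length(x) == length(y) && identical(sort(x), sort(y))) return(1)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Compare taxon abundances between two treatments
#'
#' For each taxon (row of `counts`): the log2 ratio of the median
#' per-sample read proportion in group `a` over group `b`, a two-sided
#' Wilcoxon rank-sum p-value over the two proportion vectors, and
#' Benjamini-Hochberg adjustment across all tested taxa. The column
#' `log2_ratio_gated` is the ratio where `p_adjusted < alpha` and zero
#' elsewhere — only significant differences carry color when it is mapped
#' onto a heat tree.
#'
#' Zero-median policy: both medians zero gives ratio 0; exactly one zero
#' gives a capped ratio of (largest finite |ratio| among taxa) + 1 with the
#' sign of the non-zero side, flagged in `ratio_capped`.
#'
#' @param tm a [Taxmap-class]; rows of `counts` must be its taxon IDs.
#' @param counts taxon-by-sample count matrix (rownames = taxon IDs).
#' @param treatments character vector of group labels, one per sample
#'   (named by sample or in column order).
#' @param a,b the two treatment labels to compare (ratio is a over b).
#' @param alpha significance level applied to adjusted p-values.
#' @return A list with `result` (a `data.frame`: `taxon_id`, `log2_ratio`,
#'   `p_raw`, `p_adjusted`, `significant`, `ratio_capped`,
#'   `log2_ratio_gated`) and `taxmap` (the input with these columns merged
#'   into the taxon table; taxa absent from `counts` get `NA`).
#' @export
compareTreatments <- function(tm, counts, treatments, a, b, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have taxon IDs as rownames")
  unknown <- setdiff(rownames(counts), tm@taxa$taxon_id)
  if (length(unknown)) {
    stop("counts rows not in the Taxmap: ", .fmtIds(unknown), call. = FALSE)
  }
  if (!is.null(names(treatments)) && !is.null(colnames(counts))) {
    treatments <- treatments[colnames(counts)]
  }
  if (length(treatments) != ncol(counts)) {
    stop("need one treatment label per sample column", call. = FALSE)
  }
  for (g in c(a, b)) {
    if (!g %in% treatments) stop("unknown group label: '", g, "'", call. = FALSE)
  }
  props <- readProportions(counts)
  pa <- props[, treatments == a, drop = FALSE]
  pb <- props[, treatments == b, drop = FALSE]

  medA <- apply(pa, 1L, stats::median)
  medB <- apply(pb, 1L, stats::median)
  raw <- log2(medA / medB)           # finite when both medians > 0
  finite <- is.finite(raw)
  bothZero <- medA == 0 & medB == 0
  capped <- !finite & !bothZero
  cap <- if (any(finite)) max(abs(raw[finite])) + 1 else 1
  log2_ratio <- raw
  log2_ratio[bothZero] <- 0
  log2_ratio[capped] <- ifelse(medA[capped] > 0, cap, -cap)

  p_raw <- vapply(seq_len(nrow(props)), function(i) {
    wilcoxonRankSum(pa[i, ], pb[i, ])
  }, numeric(1))
  p_adjusted <- benjaminiHochberg(p_raw)
  significant <- p_adjusted < alpha

  result <- data.frame(
    taxon_id = rownames(counts),
    log2_ratio = log2_ratio,
    p_raw = p_raw,
    p_adjusted = p_adjusted,
    significant = significant,
    ratio_capped = capped,
    log2_ratio_gated = ifelse(significant, log2_ratio, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tx <- tm@taxa
  for (col in setdiff(names(result), "taxon_id")) {
    tx[[col]] <- result[[col]][match(tx$taxon_id, result$taxon_id)]
  }
  tm@taxa <- tx
  methods::validObject(tm)
  list(result = result, taxmap = tm)
}

#' Read an abundance matrix and treatment map from TSV files
#'
#' The matrix file has a `taxon_id` first column and one column per
#' sample; the groups file has two columns, `sample` and `treatment`.
#'
#' @param matrixPath,groupsPath file paths.
#' @return list(counts = matrix, treatments = named character vector).
#' @export
readAbundance <- function(matrixPath, groupsPath) {
  m <- utils::read.delim(matrixPath, stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(m[, -1L, drop = FALSE])
  rownames(counts) <- m[[1L]]
  g <- utils::read.delim(groupsPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "treatment") %in% names(g))) {
    stop("groups file needs columns 'sample' and 'treatment'", call. = FALSE)
  }
  treatments <- stats::setNames(g$treatment, g$sample)
  list(counts = counts, treatments = treatments)
}
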
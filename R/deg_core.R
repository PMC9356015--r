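#' Construct a count matrix with case/control labels
#'
#' Bundles a gene-by-sample matrix of non-negative integer counts with a
#' case/control group label per sample. This is the substrate for count
#' filtering and the differential-expression stand-in test.
#'
#' @param counts Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). All values must be
#'   non-negative and finite.
#' @param group Character or factor of length `ncol(counts)` with values
#'   `"case"` or `"control"`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (the matrix) and `group` (a factor with levels
#'   `control`, `case`).
#' @export
count_matrix <- function(counts, group) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("counts must have gene ids as rownames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  group <- as.character(group)
  if (length(group) != ncol(counts)) {
    stop("group must have one label per sample")
  }
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  structure(
    list(counts = counts, group = factor(group, levels = c("control", "case"))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (%d case, %d control)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$group == "case"), sum(x$group == "control")
  ))
  invisible(x)
}

#' Remove genes with low total counts
#'
#' Drops genes whose summed count across all samples (case and control
#' together) is below `min_total`. A gene whose total equals `min_total`
#' exactly is kept; the exclusion rule is "less than".
#'
#' @param m A [count_matrix()].
#' @param min_total Non-negative integer; default 10.
#' @return A `count_matrix` with the surviving genes, original order
#'   preserved.
#' @export
filter_low_counts <- function(m, min_total = 10) {
  stopifnot(inherits(m, "count_matrix"))
  if (!is.numeric(min_total) || length(min_total) != 1 || min_total < 0) {
    stop("min_total must be a single non-negative number")
  }
  keep <- rowSums(m$counts) >= min_total
  count_matrix(m$counts[keep, , drop = FALSE], as.character(m$group))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values. Thin
#' validating wrapper around [stats::p.adjust()] with `method = "BH"`;
#' NA values are passed through.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between case and control samples
#'
#' A two-sample location test on library-size-normalised log-scale
#' counts: counts are scaled to counts-per-million (total-count
#' normalisation), transformed to `log2(CPM + pseudocount)`, and each
#' gene is tested with a Welch-type unequal-variance t-test between the
#' case and control groups. This is a deliberately simple, self-contained
#' stand-in -- it is NOT the DESeq2 negative-binomial model; externally
#' produced DEG tables (e.g. real DESeq2 output) can be supplied to all
#' downstream stages through the same table schema (see
#' [read_deg_table()]).
#'
#' The reported fold change is
#' `log2(mean case CPM + pseudocount) - log2(mean control CPM + pseudocount)`.
#' Genes with zero variance in both groups and equal means have an
#' undefined test statistic and receive `p_raw = NA` (and are never
#' selected by [select_degs()]).
#'
#' @param m A [count_matrix()] with at least 2 samples per group.
#' @param pseudocount Positive value added on the CPM scale before the
#'   log transform; default 1.
#' @return A data frame (one row per gene) with columns `gene_id`,
#'   `log2_fold_change`, `p_raw`, `p_adj` (BH-adjusted).
#' @export
differential_expression <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"))
  is_case <- m$group == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 < 2 || n0 < 2) {
    stop("differential_expression needs at least 2 samples per group")
  }
  libsize <- colSums(m$counts)
  if (any(libsize == 0)) stop("sample with zero total counts")
  cpm <- sweep(m$counts, 2, libsize, "/") * 1e6
  x <- log2(cpm + pseudocount)

  xc <- x[, is_case, drop = FALSE]
  x0 <- x[, !is_case, drop = FALSE]
  m1 <- rowMeans(xc)
  m0 <- rowMeans(x0)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)

  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  # zero variance in both groups: equal means -> NA (undefined test);
  # different means -> t = +-Inf -> p = 0, handled by pt already
  p_raw[se2 == 0 & m1 == m0] <- NA_real_

  lfc <- log2(rowMeans(cpm[, is_case, drop = FALSE]) + pseudocount) -
    log2(rowMeans(cpm[, !is_case, drop = FALSE]) + pseudocount)

  data.frame(
    gene_id = rownames(m$counts),
    log2_fold_change = unname(lfc),
    p_raw = unname(p_raw),
    p_adj = unname(bh_adjust(p_raw)),
    stringsAsFactors = FALSE
  )
}

#' Select differentially expressed genes
#'
#' Thresholds a DEG table under one of two regimes: `"adjusted"`
#' (BH-adjusted p < alpha, the primary human rule) or `"raw"`
#' (uncorrected p < alpha, used for the mouse datasets). The inequality
#' is strict; genes with a missing p-value are never selected.
#'
#' @param t DEG table as returned by [differential_expression()] or
#'   [read_deg_table()].
#' @param regime `"adjusted"` or `"raw"`; must be named explicitly.
#' @param alpha Significance threshold; default 0.05.
#' @return Character vector of selected gene ids.
#' @export
select_degs <- function(t, regime = c("adjusted", "raw"), alpha = 0.05) {
  regime <- match.arg(regime)
  stopifnot(is.data.frame(t))
  if (nrow(t) == 0) return(character(0))
  p <- if (regime == "adjusted") t$p_adj else t$p_raw
  t$gene_id[!is.na(p) & p < alpha]
}
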
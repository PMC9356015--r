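#' Dosage check of deletion-region genes against tissue expression
#'
#' Partitions the deletion-region genes, per tissue, into those
#' expressed above the threshold (strictly greater, "higher than") and
#' the rest. Region genes absent from the expression table are reported
#' as missing rather than silently dropped.
#'
#' @param region_genes Character vector of deletion-region gene ids.
#' @param expr Tissue-expression data frame: column `gene_id` plus one
#'   numeric TPM column per tissue.
#' @param threshold TPM threshold; default 1.5.
#' @return Named list (one element per tissue), each a list with
#'   `expressed`, `low`, and `missing` gene-id vectors.
#' @export
dosage_check <- function(region_genes, expr, threshold = 1.5) {
  region_genes <- unique(as.character(region_genes))
  if (length(region_genes) == 0) stop("region_genes must be non-empty")
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  tissues <- setdiff(names(expr), "gene_id")
  idx <- match(region_genes, expr$gene_id)
  missing <- region_genes[is.na(idx)]
  found <- region_genes[!is.na(idx)]
  out <- lapply(tissues, function(tis) {
    v <- expr[[tis]][idx[!is.na(idx)]]
    list(
      expressed = found[v > threshold],
      low = found[v <= threshold],
      missing = missing
    )
  })
  names(out) <- tissues
  out
}

#' Select DEGs silenced in a reference adult tissue
#'
#' Returns the DEGs whose expression in the given tissue (adult brain
#' cortex by default) is strictly below the threshold. DEGs without a
#' row in the expression table cannot be classified; they are excluded
#' and tallied in the `no_data` attribute (mirroring the situation
#' where a reference resource covers only part of the gene list).
#'
#' @param degs Character vector of DEG ids.
#' @param expr Tissue-expression data frame (column `gene_id` plus TPM
#'   columns).
#' @param tissue Column name to threshold on; default `"brain_cortex"`.
#' @param threshold TPM threshold; default 1.5.
#' @return Character vector of selected DEGs, with attribute `no_data`
#'   listing DEGs absent from the table.
#' @export
select_brain_silent_degs <- function(degs, expr, tissue = "brain_cortex",
                                     threshold = 1.5) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  if (!tissue %in% names(expr)) {
    stop(sprintf("tissue column '%s' not found in expression table", tissue))
  }
  degs <- unique(as.character(degs))
  idx <- match(degs, expr$gene_id)
  no_data <- degs[is.na(idx)]
  if (length(no_data) > 0) {
    message(sprintf("select_brain_silent_degs: no expression data for %d DEG(s)",
                    length(no_data)))
  }
  found <- degs[!is.na(idx)]
  sel <- found[expr[[tissue]][idx[!is.na(idx)]] < threshold]
  attr(sel, "no_data") <- no_data
  sel
}

#' Tukey HSD test of a gene group's developmental-stage profile
#'
#' Tests whether a group of genes shows a different expression level
#' across brain developmental stages, treating each gene's RPKM in a
#' stage as one observation in a one-way layout (stages as groups) and
#' applying Tukey's honestly-significant-difference procedure for all
#' pairwise stage comparisons via the studentized range distribution.
#' Note the layout treats stages as independent groups even though
#' each gene contributes one value per stage; a paired analysis is out
#' of scope.
#'
#' @param genes Character vector of gene ids (at least 2 with data).
#' @param m Stage-expression data frame: column `gene_id` plus one
#'   numeric RPKM column per stage.
#' @return Data frame with columns `stage_a`, `stage_b`, `diff`
#'   (mean of `stage_a` minus mean of `stage_b`), `lwr`, `upr`, and
#'   `p_adj` (Tukey-adjusted p-value).
#' @export
stage_profile_test <- function(genes, m) {
  stopifnot(is.data.frame(m), "gene_id" %in% names(m))
  stages <- setdiff(names(m), "gene_id")
  if (length(stages) < 2) stop("need at least 2 stages")
  rows <- m[m$gene_id %in% as.character(genes), , drop = FALSE]
  if (nrow(rows) < 2) stop("need at least 2 genes with stage data")
  long <- data.frame(
    value = unlist(rows[stages], use.names = FALSE),
    stage = factor(rep(stages, each = nrow(rows)), levels = stages)
  )
  fit <- stats::aov(value ~ stage, data = long)
  tk <- stats::TukeyHSD(fit)$stage
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    stage_a = vapply(pairs, `[`, character(1), 1),
    stage_b = vapply(pairs, `[`, character(1), 2),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
}

#' Select genes with strict prenatal-maximum expression
#'
#' Keeps genes whose prenatal RPKM exceeds the threshold (strictly)
#' AND is strictly greater than the value in every other developmental
#' stage. Ties between the prenatal stage and another stage fail the
#' strict-maximum rule and are logged; genes absent from the table are
#' excluded with a message.
#'
#' @param genes Character vector of candidate gene ids.
#' @param m Stage-expression data frame: column `gene_id` plus one
#'   numeric column per stage, the first stage being `prenatal`.
#' @param prenatal_threshold RPKM threshold; default 1.5.
#' @param prenatal_stage Name of the prenatal column; default
#'   `"prenatal"`.
#' @return Character vector of selected gene ids.
#' @export
select_prenatal_max <- function(genes, m, prenatal_threshold = 1.5,
                                prenatal_stage = "prenatal") {
  stopifnot(is.data.frame(m), "gene_id" %in% names(m))
  if (!prenatal_stage %in% names(m)) {
    stop(sprintf("stage column '%s' not found", prenatal_stage))
  }
  stages <- setdiff(names(m), "gene_id")
  others <- setdiff(stages, prenatal_stage)
  genes <- unique(as.character(genes))
  idx <- match(genes, m$gene_id)
  if (anyNA(idx)) {
    message(sprintf("select_prenatal_max: %d gene(s) without stage data excluded",
                    sum(is.na(idx))))
  }
  found <- genes[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  pren <- m[[prenatal_stage]][idx]
  other_max <- do.call(pmax, m[others])[idx]
  ties <- found[pren > prenatal_threshold & pren == other_max]
  if (length(ties) > 0) {
    message(sprintf("select_prenatal_max: %d gene(s) tied between prenatal and another stage excluded",
                    length(ties)))
  }
  found[pren > prenatal_threshold & pren > other_max]
}

#' Binomial enrichment of DEGs in a disease gene list
#'
#' Tests whether a DEG set contains more genes from a disease list
#' (e.g. monogenic neurodevelopmental-disorder genes) than expected by
#' chance: with `k` DEGs in the list out of `n` DEGs total, and the
#' background proportion `p0 = |list| / |universe|`, computes the
#' one-sided upper-tail exact binomial probability `P(X >= k)` for
#' `X ~ Binomial(n, p0)`.
#'
#' @param degs Character vector of DEG ids; must be a subset of
#'   `universe`.
#' @param ndd_genes Character vector of disease gene ids; subset of
#'   `universe`.
#' @param universe Character vector: the gene universe (typically all
#'   genes tested for differential expression after count filtering).
#' @return List with `overlap` (k), `n_degs`, `p0`, and `p_value`.
#' @export
ndd_binomial_enrichment <- function(degs, ndd_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty")
  degs <- unique(as.character(degs))
  ndd_genes <- unique(as.character(ndd_genes))
  if (!all(degs %in% universe)) stop("degs must be a subset of universe")
  if (!all(ndd_genes %in% universe)) {
    stop("ndd_genes must be a subset of universe")
  }
  k <- length(intersect(degs, ndd_genes))
  n <- length(degs)
  p0 <- length(ndd_genes) / length(universe)
  p <- if (k <= 0) 1 else stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(overlap = k, n_degs = n, p0 = p0, p_value = p)
}
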
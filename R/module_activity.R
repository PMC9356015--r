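#' Rank genes by fold change
#'
#' Orders the full tested gene list by log2 fold change. The
#' `"downward"` direction (descending fold change, up-regulated genes
#' first) is used to assess module activity; `"upward"` (ascending,
#' down-regulated first) assesses inactivity. Ties are broken by gene
#' id, lexicographic ascending, so the ranking is deterministic. Genes
#' with a missing fold change are excluded with a message.
#'
#' @param t DEG table with columns `gene_id` and `log2_fold_change`.
#' @param direction `"downward"` or `"upward"`.
#' @return Object of class `ranked_list`: list with `gene_ids`,
#'   `values` (the fold changes in ranked order), and `direction`.
#' @export
rank_genes <- function(t, direction = c("downward", "upward")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(t), all(c("gene_id", "log2_fold_change") %in% names(t)))
  ok <- !is.na(t$log2_fold_change)
  if (any(!ok)) {
    message(sprintf("rank_genes: %d gene(s) without fold change excluded",
                    sum(!ok)))
  }
  gene_ids <- as.character(t$gene_id[ok])
  values <- t$log2_fold_change[ok]
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in DEG table")
  if (length(gene_ids) < 2) stop("ranked list needs at least 2 genes")
  o <- if (direction == "downward") {
    order(-values, gene_ids, method = "radix")
  } else {
    order(values, gene_ids, method = "radix")
  }
  structure(
    list(gene_ids = gene_ids[o], values = values[o], direction = direction),
    class = "ranked_list"
  )
}

#' Running-sum enrichment score of a module in a ranked list
#'
#' Walks down the ranked gene list accumulating a running sum that
#' rises by `1/N_f` at each of the `N_f` module genes and falls by
#' `1/(N - N_f)` at each of the other `N - N_f` genes. The enrichment
#' score is the maximum of the running sum over all positions. Because
#' the total rise equals the total fall, the running sum always returns
#' to zero at the end of the list, so the score lies in \[0, 1\] and
#' equals 1 exactly when the module genes occupy a prefix of the list.
#'
#' Module genes absent from the ranked list are dropped before `N_f`
#' is computed.
#'
#' @param r A [rank_genes()] result.
#' @param module_genes Character vector of module gene ids.
#' @return List with `es` (the enrichment score), `running_sum`
#'   (numeric vector of length `N`), and `n_module` (`N_f`).
#' @export
enrichment_score <- function(r, module_genes) {
  stopifnot(inherits(r, "ranked_list"))
  member <- r$gene_ids %in% as.character(module_genes)
  n <- length(member)
  nf <- sum(member)
  if (nf == 0) stop("no module gene present in the ranked list")
  if (nf == n) stop("module covers the entire ranked list; score undefined")
  steps <- ifelse(member, 1 / nf, -1 / (n - nf))
  s <- cumsum(steps)
  # the running sum ends at exactly 0 in exact arithmetic, so the max
  # is structurally >= 0; guard against accumulated rounding
  list(es = max(max(s), 0), running_sum = s, n_module = nf)
}

# Enrichment score from sorted member positions, without materialising
# the running sum. The running sum rises only at member positions and
# decays linearly between them, so its maximum over the whole list is
# attained at a member position; at the k-th member (list position
# p_k) the running sum equals k/N_f - (p_k - k)/(N - N_f).
es_from_positions <- function(pos_sorted, n, nf) {
  k <- seq_len(nf)
  max(max(k / nf - (pos_sorted - k) / (n - nf)), 0)
}

#' Permutation z-score of a module's enrichment score
#'
#' Standardises the observed enrichment score against a permutation
#' null: `n_perm` scores are computed from randomly permuted gene
#' lists, and `z = (ES - mu) / sigma` where `mu` and `sigma` are the
#' mean and (sample, n-1 denominator) standard deviation of the null
#' scores. Because the score depends on the ranking only through the
#' member positions, each null draw samples `N_f` positions uniformly
#' without replacement -- exactly equivalent to permuting the gene list.
#'
#' @param r A [rank_genes()] result.
#' @param module_genes Character vector of module gene ids.
#' @param n_perm Number of permutations; default 1000.
#' @param seed Integer seed.
#' @return List with `z`, `mu`, `sigma`, `es`, `n_module`, and
#'   `degenerate` (TRUE when `sigma == 0`, in which case `z` is NA).
#' @export
permutation_z <- function(r, module_genes, n_perm = 1000, seed = 1) {
  stopifnot(inherits(r, "ranked_list"), n_perm >= 2)
  obs <- enrichment_score(r, module_genes)
  n <- length(r$gene_ids)
  nf <- obs$n_module
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort.int(sample.int(n, nf)), n, nf)
    }, numeric(1))
  })
  mu <- mean(null_es)
  sigma <- stats::sd(null_es)
  degenerate <- !is.finite(sigma) || sigma == 0
  list(
    z = if (degenerate) NA_real_ else (obs$es - mu) / sigma,
    mu = mu, sigma = sigma, es = obs$es, n_module = nf,
    degenerate = degenerate
  )
}

#' Classify a module from its activity and inactivity z-scores
#'
#' A module is `"activated"` when its activity z (descending-ranking
#' score) exceeds 2 while its inactivity z is negative, `"inactivated"`
#' when the inactivity z exceeds 2 while the activity z is negative,
#' and `"neither"` otherwise. Non-finite z-values give `"degenerate"`.
#' The two sign conditions make activated and inactivated mutually
#' exclusive.
#'
#' @param z_act,z_inact Activity and inactivity z-scores.
#' @param z_threshold Classification threshold; default 2.
#' @return One of `"activated"`, `"inactivated"`, `"neither"`,
#'   `"degenerate"`.
#' @export
classify_module <- function(z_act, z_inact, z_threshold = 2) {
  if (!is.finite(z_act) || !is.finite(z_inact)) return("degenerate")
  if (z_act > z_threshold && z_inact < 0) return("activated")
  if (z_inact > z_threshold && z_act < 0) return("inactivated")
  "neither"
}

#' Score and classify every functional module
#'
#' For each module, computes the enrichment score and its permutation
#' z on the downward ranking (activity) and on the upward ranking
#' (inactivity), then applies [classify_module()]. Each
#' (module, direction) pair draws its null permutations from an
#' independent seeded substream, so single modules can be re-scored
#' reproducibly. Modules with no gene in the ranked list are skipped
#' with a warning; modules whose null score has zero spread are
#' reported as `"degenerate"`.
#'
#' @param t DEG table (full tested gene list) with `gene_id` and
#'   `log2_fold_change`.
#' @param modules List of `functional_module` objects (or a named list
#'   of gene-id vectors).
#' @param n_perm Permutations per (module, direction); default 1000.
#' @param seed Integer seed for the whole batch.
#' @param z_threshold Classification threshold; default 2.
#' @return Data frame with one row per scored module: `term_id`,
#'   `n_module_genes`, `es_activity`, `z_activity`, `es_inactivity`,
#'   `z_inactivity`, `status`.
#' @export
score_all_modules <- function(t, modules, n_perm = 1000, seed = 1,
                              z_threshold = 2) {
  gene_sets <- lapply(modules, function(m) {
    if (inherits(m, "functional_module")) m$genes else as.character(m)
  })
  ids <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (inherits(m, "functional_module")) m$term_id
    else if (!is.null(names(modules)) && nzchar(names(modules)[i])) names(modules)[i]
    else sprintf("module_%03d", i)
  }, character(1))
  down <- rank_genes(t, "downward")
  up <- rank_genes(t, "upward")
  n_mod <- length(gene_sets)
  # independent substream seed per (module, direction)
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, 2L * max(n_mod, 1L)))
  rows <- vector("list", n_mod)
  for (i in seq_len(n_mod)) {
    genes <- gene_sets[[i]]
    nf <- sum(down$gene_ids %in% genes)
    if (nf == 0 || nf == length(down$gene_ids)) {
      warning(sprintf("module %s skipped (%s)", ids[i],
                      if (nf == 0) "no gene in ranked list" else "covers whole list"))
      next
    }
    act <- permutation_z(down, genes, n_perm = n_perm, seed = sub_seeds[2 * i - 1])
    inact <- permutation_z(up, genes, n_perm = n_perm, seed = sub_seeds[2 * i])
    status <- if (act$degenerate || inact$degenerate) "degenerate" else {
      classify_module(act$z, inact$z, z_threshold = z_threshold)
    }
    rows[[i]] <- data.frame(
      term_id = ids[i], n_module_genes = nf,
      es_activity = act$es, z_activity = act$z,
      es_inactivity = inact$es, z_inactivity = inact$z,
      status = status, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(
      term_id = character(0), n_module_genes = integer(0),
      es_activity = numeric(0), z_activity = numeric(0),
      es_inactivity = numeric(0), z_inactivity = numeric(0),
      status = character(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
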
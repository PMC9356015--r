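#' Map a gene set through a 1:1 orthology table
#'
#' Translates gene ids (e.g. human symbols) into another species' id
#' space using a two-column table of orthology pairs. Source ids that
#' map to more than one distinct target (ambiguous orthology) or that
#' are absent from the table are dropped, with a message naming how
#' many were lost.
#'
#' @param genes Character vector of source gene ids (treated as a set).
#' @param table Data frame with two columns, `(source_id, target_id)`.
#' @return Character vector: the image of `genes` under the mapping.
#' @export
map_orthologs <- function(genes, table) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  genes <- unique(as.character(genes))
  if (length(genes) == 0) return(character(0))
  src <- as.character(table[[1]])
  tgt <- as.character(table[[2]])
  pairs <- unique(data.frame(src = src, tgt = tgt, stringsAsFactors = FALSE))
  ambiguous <- unique(pairs$src[duplicated(pairs$src)])
  absent <- setdiff(genes, pairs$src)
  dropped <- union(intersect(genes, ambiguous), absent)
  if (length(dropped) > 0) {
    message(sprintf(
      "map_orthologs: dropped %d gene(s) (%d ambiguous, %d unmapped)",
      length(dropped), length(intersect(genes, ambiguous)), length(absent)
    ))
  }
  keep <- setdiff(genes, dropped)
  unique(pairs$tgt[pairs$src %in% keep])
}

#' Pairwise and k-way intersections of gene sets
#'
#' @param sets Named (or unnamed) list of at least two character vectors,
#'   each treated as a set.
#' @return A list with `k_way` (size of the full intersection),
#'   `k_way_genes` (its members), and `pairwise` (data frame of set-pair
#'   intersection sizes).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  inter <- Reduce(intersect, sets)
  pairs <- utils::combn(length(sets), 2)
  pairwise <- data.frame(
    set_a = names(sets)[pairs[1, ]],
    set_b = names(sets)[pairs[2, ]],
    overlap = apply(pairs, 2, function(ij) {
      length(intersect(sets[[ij[1]]], sets[[ij[2]]]))
    }),
    stringsAsFactors = FALSE
  )
  list(k_way = length(inter), k_way_genes = inter, pairwise = pairwise)
}

#' Monte-Carlo permutation test for a k-way gene-set overlap
#'
#' Tests whether an observed k-way intersection of gene sets is larger
#' than expected by chance. For each of `n_samplings` random samplings,
#' independent uniform subsets of the given sizes are drawn from a
#' common gene universe and the size of their full intersection is
#' recorded. The empirical p-value uses the add-one convention
#' `(count_ge + 1) / (n_samplings + 1)`, so it is never exactly zero.
#'
#' @param set_sizes Integer vector (length >= 2) of the observed DEG-set
#'   sizes.
#' @param observed Observed k-way intersection count.
#' @param universe_size Size of the gene universe; default 20000.
#' @param n_samplings Number of random samplings; default 100000.
#' @param seed Integer seed for the sampling stream.
#' @return An object of class `overlap_result`: list with `set_sizes`,
#'   `universe_size`, `observed`, `n_samplings`, `count_ge`,
#'   `p_empirical`, and `null_mean` (mean null intersection size).
#' @export
permutation_overlap_p <- function(set_sizes, observed,
                                  universe_size = 20000,
                                  n_samplings = 100000,
                                  seed = 1) {
  set_sizes <- as.integer(set_sizes)
  stopifnot(length(set_sizes) >= 2, all(set_sizes >= 0))
  if (any(set_sizes > universe_size)) {
    stop("every set size must be <= universe_size")
  }
  if (observed < 0) stop("observed must be non-negative")
  k <- length(set_sizes)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_samplings), function(b) {
      inter <- sample.int(universe_size, set_sizes[1])
      for (j in 2:k) {
        s <- sample.int(universe_size, set_sizes[j])
        inter <- inter[match(inter, s, nomatch = 0L) > 0L]
        if (length(inter) == 0L) {
          # remaining sets still consumed so the stream length is
          # identical for every sampling
          for (jj in seq_len(k - j)) sample.int(universe_size, set_sizes[j + jj])
          break
        }
      }
      length(inter)
    }, integer(1))
  })
  count_ge <- sum(counts >= observed)
  structure(
    list(
      set_sizes = set_sizes,
      universe_size = as.integer(universe_size),
      observed = as.integer(observed),
      n_samplings = as.integer(n_samplings),
      count_ge = count_ge,
      p_empirical = (count_ge + 1) / (n_samplings + 1),
      null_mean = mean(counts)
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: observed %d-way overlap = %d (sets %s, universe %d)\n  %d/%d null samplings >= observed; empirical p = %.4g\n",
    length(x$set_sizes), x$observed,
    paste(x$set_sizes, collapse = "/"), x$universe_size,
    x$count_ge, x$n_samplings, x$p_empirical
  ))
  invisible(x)
}

#' Exact hypergeometric tail for a two-set overlap
#'
#' Analytic counterpart of [permutation_overlap_p()] for the two-set
#' case: the upper-tail probability `P(X >= observed)` where `X` is the
#' intersection size of two independent uniform subsets of sizes
#' `size_a` and `size_b` drawn from a universe of `universe_size` genes
#' (a hypergeometric variable).
#'
#' @param size_a,size_b Set sizes.
#' @param observed Observed intersection count.
#' @param universe_size Universe size.
#' @return The exact tail probability.
#' @export
hypergeometric_overlap_p <- function(size_a, size_b, observed, universe_size) {
  stopifnot(size_a <= universe_size, size_b <= universe_size)
  if (observed <= 0) return(1)
  stats::phyper(observed - 1, size_a, universe_size - size_a, size_b,
                lower.tail = FALSE)
}

#' Remove deletion-region genes from a gene set
#'
#' Set difference used for the "overlap excluding the deleted region"
#' variant of the cross-species comparison.
#'
#' @param s Character vector (gene set).
#' @param region Character vector of deletion-region gene ids.
#' @return `s` without the region genes.
#' @export
exclude_region_genes <- function(s, region) {
  setdiff(unique(as.character(s)), as.character(region))
}

#' Negative-control overlap from a split of the control samples
#'
#' Splits the control samples into two random halves (seeded,
#' deterministic), runs the differential-expression stand-in test
#' between the halves, selects "DEGs" at uncorrected p < `alpha`, and
#' tests their overlap with the supplied DEG sets by
#' [permutation_overlap_p()]. Under the null (controls are
#' exchangeable) the overlap should look like chance.
#'
#' If the two halves carry no variation (e.g. duplicated identical
#' samples) the test statistic is undefined for every gene; the control
#' DEG set is then empty and a warning is raised.
#'
#' @param controls A [count_matrix()] containing only control samples
#'   (at least 4; labels are ignored).
#' @param other_deg_sets List of gene-id sets (in the same id space as
#'   the control count matrix) to intersect with.
#' @param universe_size,n_samplings Passed to [permutation_overlap_p()].
#' @param alpha Raw-p threshold for the control split DEGs; default 0.05.
#' @param seed Integer seed controlling both the split and the sampling.
#' @return List with `control_degs` (character vector), `split`
#'   (assignment of samples to halves), `observed` (the k-way overlap
#'   count), and `overlap` (an `overlap_result`).
#' @export
control_split_overlap <- function(controls, other_deg_sets,
                                  universe_size = 20000,
                                  n_samplings = 100000,
                                  alpha = 0.05,
                                  seed = 1) {
  stopifnot(inherits(controls, "count_matrix"))
  n <- ncol(controls$counts)
  if (n < 4) stop("control_split_overlap needs at least 4 control samples")
  half <- floor(n / 2)
  idx <- withr::with_seed(seed, sample.int(n, half))
  grp <- rep("control", n)
  grp[idx] <- "case"
  split_m <- count_matrix(controls$counts, grp)
  deg_table <- differential_expression(split_m)
  if (all(is.na(deg_table$p_raw))) {
    warning("control split carries no variation; control DEG set is empty")
    control_degs <- character(0)
  } else {
    control_degs <- select_degs(deg_table, regime = "raw", alpha = alpha)
  }
  sets <- c(list(control_split = control_degs), other_deg_sets)
  observed <- overlap_sets(sets)$k_way
  overlap <- permutation_overlap_p(
    set_sizes = lengths(sets), observed = observed,
    universe_size = universe_size, n_samplings = n_samplings,
    seed = seed + 1L
  )
  list(
    control_degs = control_degs,
    split = data.frame(
      sample_id = colnames(controls$counts),
      half = ifelse(grp == "case", "half1", "half2"),
      stringsAsFactors = FALSE
    ),
    observed = observed,
    overlap = overlap
  )
}
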
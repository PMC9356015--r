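#' Configuration for the synthetic study generator
#'
#' Collects every knob of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: a gene universe of
#' 20,000 genes, a small human blood cohort (3 cases vs 4 controls)
#' and a larger mouse cortex cohort (10 vs 10), negative-binomial
#' counts with lognormal per-gene means, a planted set of
#' differentially expressed genes partially shared between the two
#' pseudo-species, eight deletion-region genes at halved dosage in
#' cases, a sparse background interaction network with planted
#' GO-coherent modules, and five named developmental stages.
#'
#' @param n_genes Gene universe size; default 20000.
#' @param n_case,n_control Named integer vectors (one entry per
#'   pseudo-species) of case/control sample counts.
#' @param nb_mean_log_mu,nb_mean_sdlog Meanlog/sdlog of the lognormal
#'   distribution of per-gene baseline means.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); shared across groups.
#' @param frac_de Fraction of genes with planted differential
#'   expression; default 0.05.
#' @param lfc_magnitude Planted |log2 fold change|; default 2.
#' @param n_deletion_genes Number of deletion-region genes (halved
#'   case dosage); default 8.
#' @param shared_fraction Fraction of planted human DEGs also planted
#'   in the second pseudo-species; default 0.5.
#' @param ppi_n_edges Background (random) interaction edges; default
#'   30000.
#' @param module_sizes Sizes of the planted GO-coherent modules; the
#'   first half are planted as activated (members up-shifted), the
#'   second half as inactivated; default `c(30, 30, 30, 30)`.
#' @param n_background_terms,background_term_size Background GO terms
#'   annotating random gene sets.
#' @param background_nonexp_fraction Fraction of background annotation
#'   rows carrying a non-experimental evidence code (IEA); default 0.3.
#' @param stage_names Ordered developmental stages, first must be the
#'   prenatal stage.
#' @param n_prenatal_max Planted prenatal-maximum genes (all of them
#'   brain-silent DEGs); default 30.
#' @param n_ndd_genes Size of the synthetic NDD gene list; default 500.
#' @param ndd_de_fraction Fraction of the NDD list drawn from planted
#'   DEGs (plants a real enrichment); default 0.2.
#' @param seed Integer seed; the same config yields byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000,
                       n_case = c(human = 3, mouse = 10),
                       n_control = c(human = 4, mouse = 10),
                       nb_mean_log_mu = 4,
                       nb_mean_sdlog = 1,
                       nb_dispersion = 0.1,
                       frac_de = 0.05,
                       lfc_magnitude = 2,
                       n_deletion_genes = 8,
                       shared_fraction = 0.5,
                       ppi_n_edges = 30000,
                       module_sizes = c(30, 30, 30, 30),
                       n_background_terms = 20,
                       background_term_size = 10,
                       background_nonexp_fraction = 0.3,
                       stage_names = c("prenatal", "infant", "child",
                                       "adolescent", "adult"),
                       n_prenatal_max = 30,
                       n_ndd_genes = 500,
                       ndd_de_fraction = 0.2,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_case = n_case, n_control = n_control,
    nb_mean_log_mu = nb_mean_log_mu, nb_mean_sdlog = nb_mean_sdlog,
    nb_dispersion = nb_dispersion, frac_de = frac_de,
    lfc_magnitude = lfc_magnitude,
    n_deletion_genes = as.integer(n_deletion_genes),
    shared_fraction = shared_fraction, ppi_n_edges = as.integer(ppi_n_edges),
    module_sizes = as.integer(module_sizes),
    n_background_terms = as.integer(n_background_terms),
    background_term_size = as.integer(background_term_size),
    background_nonexp_fraction = background_nonexp_fraction,
    stage_names = stage_names, n_prenatal_max = as.integer(n_prenatal_max),
    n_ndd_genes = as.integer(n_ndd_genes),
    ndd_de_fraction = ndd_de_fraction, seed = as.integer(seed)
  )
  if (cfg$n_genes < 10) stop("n_genes too small")
  if (length(cfg$n_case) != length(cfg$n_control)) {
    stop("n_case and n_control must describe the same species")
  }
  if (is.null(names(cfg$n_case)) || is.null(names(cfg$n_control))) {
    stop("n_case and n_control must be named by species")
  }
  if (any(cfg$n_case <= 0) || any(cfg$n_control <= 0)) {
    stop("sample counts must be positive")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  fr <- c(cfg$frac_de, cfg$shared_fraction, cfg$background_nonexp_fraction,
          cfg$ndd_de_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  max_edges <- cfg$n_genes * (cfg$n_genes - 1) / 2
  if (cfg$ppi_n_edges > max_edges) {
    stop("ppi_n_edges exceeds the maximum for a simple graph")
  }
  if (length(cfg$stage_names) < 2 || cfg$stage_names[1] != "prenatal") {
    stop("stage_names needs >= 2 stages, the first being 'prenatal'")
  }
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n, prefix = "g") sprintf("%s%05d", prefix, seq_len(n))

#' Generate a negative-binomial count matrix with planted effects
#'
#' Draws a gene-by-sample count matrix from a negative-binomial model
#' with lognormal per-gene baseline means shared by both groups. Genes
#' in `planted` get their case-group mean multiplied by
#' `2^log2_fold_change`; `deletion_genes` get their case-group mean
#' halved (heterozygous-dosage emulation).
#'
#' @param config A [sim_config()].
#' @param species_label One of `names(config$n_case)`.
#' @param planted Optional data frame with columns `gene_id`,
#'   `log2_fold_change`; NULL means no planted differential expression.
#' @param deletion_genes Character vector of gene ids dosage-halved in
#'   cases; default none.
#' @param gene_ids Gene universe; defaults to `g00001..`.
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `counts` (a [count_matrix()]) and `truth` (list
#'   with the planted table and deletion genes).
#' @export
generate_counts <- function(config, species_label, planted = NULL,
                            deletion_genes = character(0),
                            gene_ids = sim_gene_ids(config$n_genes),
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!species_label %in% names(config$n_case)) {
    stop(sprintf("unknown species '%s'", species_label))
  }
  n1 <- config$n_case[[species_label]]
  n0 <- config$n_control[[species_label]]
  ng <- length(gene_ids)
  lfc <- setNames(rep(0, ng), gene_ids)
  if (!is.null(planted) && nrow(planted) > 0) {
    if (!all(planted$gene_id %in% gene_ids)) {
      stop("planted genes must belong to the gene universe")
    }
    lfc[planted$gene_id] <- planted$log2_fold_change
  }
  dosage <- setNames(rep(1, ng), gene_ids)
  if (length(deletion_genes) > 0) {
    if (!all(deletion_genes %in% gene_ids)) {
      stop("deletion_genes must belong to the gene universe")
    }
    dosage[deletion_genes] <- 0.5
  }
  size <- 1 / config$nb_dispersion
  counts <- withr::with_seed(seed, {
    mu0 <- stats::rlnorm(ng, meanlog = config$nb_mean_log_mu,
                         sdlog = config$nb_mean_sdlog)
    mu_case <- mu0 * 2^lfc * dosage
    ctrl <- matrix(stats::rnbinom(ng * n0, size = size, mu = mu0),
                   nrow = ng)
    case <- matrix(stats::rnbinom(ng * n1, size = size, mu = mu_case),
                   nrow = ng)
    cbind(ctrl, case)
  })
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("%s_control_%d", species_label, seq_len(n0)),
                        sprintf("%s_case_%d", species_label, seq_len(n1)))
  group <- c(rep("control", n0), rep("case", n1))
  list(
    counts = count_matrix(counts, group),
    truth = list(
      species = species_label,
      planted = if (is.null(planted)) {
        data.frame(gene_id = character(0), log2_fold_change = numeric(0))
      } else planted,
      deletion_genes = deletion_genes
    )
  )
}

#' Generate a synthetic protein-interaction network
#'
#' Background edges are drawn uniformly at random among unordered gene
#' pairs (Erdos-Renyi by edge count). Each planted module is made
#' internally connected by a random path over its genes plus extra
#' random internal edges, so module recovery downstream cannot fail for
#' connectivity reasons.
#'
#' @param config A [sim_config()].
#' @param planted_modules List of gene-id vectors (one per planted
#'   module); default empty.
#' @param gene_ids Gene universe.
#' @param seed Seed; defaults to `config$seed`.
#' @return A [ppi_network()] containing all planted and background
#'   edges.
#' @export
generate_ppi <- function(config, planted_modules = list(),
                         gene_ids = sim_gene_ids(config$n_genes),
                         seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ng <- length(gene_ids)
  withr::with_seed(seed, {
    planted_edges <- lapply(planted_modules, function(genes) {
      stopifnot(all(genes %in% gene_ids), length(genes) >= 2)
      path <- sample(genes)
      extra_n <- length(genes)
      ii <- sample.int(length(genes), extra_n, replace = TRUE)
      jj <- sample.int(length(genes), extra_n, replace = TRUE)
      rbind(
        data.frame(a = path[-length(path)], b = path[-1],
                   stringsAsFactors = FALSE),
        data.frame(a = genes[ii], b = genes[jj], stringsAsFactors = FALSE)
      )
    })
    bg <- NULL
    need <- config$ppi_n_edges
    seen <- character(0)
    while (need > 0) {
      i <- sample.int(ng, need * 1.2 + 10, replace = TRUE)
      j <- sample.int(ng, need * 1.2 + 10, replace = TRUE)
      ok <- i != j
      lo <- pmin(i[ok], j[ok])
      hi <- pmax(i[ok], j[ok])
      key <- paste(lo, hi)
      fresh <- !duplicated(key) & !(key %in% seen)
      lo <- lo[fresh][seq_len(min(sum(fresh), need))]
      hi <- hi[fresh][seq_len(min(sum(fresh), need))]
      seen <- c(seen, paste(lo, hi))
      bg <- rbind(bg, data.frame(a = gene_ids[lo], b = gene_ids[hi],
                                 stringsAsFactors = FALSE))
      need <- config$ppi_n_edges - nrow(bg)
    }
    ppi_network(do.call(rbind, c(planted_edges, list(bg))),
                nodes = gene_ids)
  })
}

#' Generate GO biological-process annotations with planted modules
#'
#' Each planted module becomes one GO term annotating exactly its
#' genes with experimental evidence codes. Background terms annotate
#' random gene sets; a configurable fraction of background rows carry
#' the non-experimental IEA code and a small fraction are
#' molecular-function rows, so the evidence/aspect filter is
#' exercised.
#'
#' @param config A [sim_config()].
#' @param planted_modules Named list (term id -> gene-id vector).
#' @param gene_ids Gene universe.
#' @param seed Seed; defaults to `config$seed`.
#' @return Annotation data frame with columns `gene_id`, `term_id`,
#'   `evidence`, `aspect`.
#' @export
generate_go_annotations <- function(config, planted_modules = list(),
                                    gene_ids = sim_gene_ids(config$n_genes),
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    planted <- NULL
    if (length(planted_modules) > 0) {
      if (is.null(names(planted_modules))) {
        names(planted_modules) <- sprintf("GO:81%05d",
                                          seq_along(planted_modules))
      }
      planted <- do.call(rbind, lapply(names(planted_modules), function(tid) {
        genes <- planted_modules[[tid]]
        data.frame(
          gene_id = genes, term_id = tid,
          evidence = sample(EXPERIMENTAL_EVIDENCE_CODES, length(genes),
                            replace = TRUE),
          aspect = "P", stringsAsFactors = FALSE
        )
      }))
    }
    bg <- NULL
    if (config$n_background_terms > 0) {
      bg <- do.call(rbind, lapply(seq_len(config$n_background_terms),
                                  function(i) {
        genes <- sample(gene_ids, config$background_term_size)
        nonexp <- stats::runif(length(genes)) < config$background_nonexp_fraction
        data.frame(
          gene_id = genes,
          term_id = sprintf("GO:00%05d", i),
          evidence = ifelse(nonexp, "IEA",
                            sample(EXPERIMENTAL_EVIDENCE_CODES,
                                   length(genes), replace = TRUE)),
          aspect = ifelse(stats::runif(length(genes)) < 0.1, "F", "P"),
          stringsAsFactors = FALSE
        )
      }))
    }
    out <- rbind(planted, bg)
    if (is.null(out)) {
      out <- data.frame(gene_id = character(0), term_id = character(0),
                        evidence = character(0), aspect = character(0),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate developmental-stage expression with planted prenatal-max genes
#'
#' Planted genes get a strictly prenatal-maximum profile with a
#' prenatal RPKM above 1.5; all other genes get a strictly increasing
#' profile peaking in the last (adult) stage, so no non-planted gene
#' can satisfy the downstream prenatal-maximum rule.
#'
#' @param config A [sim_config()].
#' @param prenatal_max_genes Gene ids planted as prenatal-maximum.
#' @param gene_ids Gene universe.
#' @param seed Seed; defaults to `config$seed`.
#' @return Data frame: `gene_id` plus one RPKM column per stage.
#' @export
generate_stage_expression <- function(config, prenatal_max_genes = character(0),
                                      gene_ids = sim_gene_ids(config$n_genes),
                                      seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(prenatal_max_genes %in% gene_ids))
  ns <- length(config$stage_names)
  ng <- length(gene_ids)
  withr::with_seed(seed, {
    # baseline: strictly increasing toward the adult stage
    vals <- t(apply(matrix(stats::runif(ng * ns, 0.2, 20), ncol = ns), 1,
                    sort))
    planted <- gene_ids %in% prenatal_max_genes
    if (any(planted)) {
      pren <- stats::runif(sum(planted), 2, 20)
      rest <- pren * matrix(stats::runif(sum(planted) * (ns - 1), 0.1, 0.8),
                            ncol = ns - 1)
      vals[planted, ] <- cbind(pren, rest)
    }
    out <- data.frame(gene_id = gene_ids, vals, stringsAsFactors = FALSE)
    names(out) <- c("gene_id", config$stage_names)
    out
  })
}

#' Generate adult-tissue TPM with planted brain-silent genes
#'
#' Produces a tissue-expression table (brain cortex and blood TPM).
#' `brain_silent_genes` get cortex TPM strictly below 1.5;
#' `cortex_expressed_genes` are forced above 1.5 (used to plant the
#' deletion-region dosage pattern); everything else is drawn well
#' above the threshold.
#'
#' @param config A [sim_config()].
#' @param brain_silent_genes Gene ids planted with cortex TPM < 1.5.
#' @param cortex_expressed_genes Gene ids forced to cortex TPM > 1.5.
#' @param gene_ids Gene universe.
#' @param seed Seed; defaults to `config$seed`.
#' @return Data frame with columns `gene_id`, `brain_cortex`, `blood`.
#' @export
generate_tissue_expression <- function(config,
                                       brain_silent_genes = character(0),
                                       cortex_expressed_genes = character(0),
                                       gene_ids = sim_gene_ids(config$n_genes),
                                       seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (length(intersect(brain_silent_genes, cortex_expressed_genes)) > 0) {
    stop("a gene cannot be both brain-silent and cortex-expressed")
  }
  ng <- length(gene_ids)
  withr::with_seed(seed, {
    cortex <- stats::runif(ng, 2, 50)
    blood <- stats::runif(ng, 0, 50)
    cortex[gene_ids %in% brain_silent_genes] <-
      stats::runif(sum(gene_ids %in% brain_silent_genes), 0, 1.4)
    cortex[gene_ids %in% cortex_expressed_genes] <-
      stats::runif(sum(gene_ids %in% cortex_expressed_genes), 2, 50)
    data.frame(gene_id = gene_ids, brain_cortex = cortex, blood = blood,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Generates every input the pipeline consumes, with a coordinated
#' ground truth: count matrices for two pseudo-species sharing a
#' planted DEG subset through a 1:1 orthology table, deletion-region
#' genes at halved case dosage in both species, a PPI network with
#' planted GO-coherent modules whose members are shifted up (activated
#' truth) or down (inactivated truth) in the human planted DEG set, a
#' synthetic NDD gene list enriched for planted DEGs, and tissue/stage
#' expression tables planting the brain-silent prenatal-maximum chain.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study` with elements `config`, `counts`
#'   (named list per species of [count_matrix()]), `orthology` (data
#'   frame `human`, `mouse`), `ppi`, `annotations`, `tissue_expr`,
#'   `stage_expr`, `gene_sets` (list: `deletion`, `ndd`), and `truth`
#'   (planted DEG sets per species, shared set, activated/inactivated
#'   module term ids and gene lists, prenatal-max genes, brain-silent
#'   genes).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  species <- names(config$n_case)
  if (length(species) != 2) {
    stop("simulate_study expects exactly two pseudo-species")
  }
  human <- species[1]
  mouse <- species[2]
  gene_ids <- sim_gene_ids(config$n_genes)
  mouse_ids <- sim_gene_ids(config$n_genes, prefix = "m")
  orthology <- data.frame(human = gene_ids, mouse = mouse_ids,
                          stringsAsFactors = FALSE)
  names(orthology) <- c(human, mouse)
  to_mouse <- setNames(mouse_ids, gene_ids)

  n_de <- round(config$frac_de * config$n_genes)
  n_modules <- length(config$module_sizes)
  n_act <- ceiling(n_modules / 2)

  plan <- withr::with_seed(config$seed, {
    deletion <- gene_ids[seq_len(config$n_deletion_genes)]
    pool <- setdiff(gene_ids, deletion)
    module_genes <- list()
    for (i in seq_len(n_modules)) {
      g <- sample(pool, config$module_sizes[i])
      pool <- setdiff(pool, g)
      module_genes[[i]] <- sort(g)
    }
    names(module_genes) <- sprintf("GO:81%05d", seq_len(n_modules))
    act_terms <- names(module_genes)[seq_len(n_act)]
    inact_terms <- setdiff(names(module_genes), act_terms)
    forced <- unlist(module_genes, use.names = FALSE)
    if (length(forced) > n_de) {
      stop("module_sizes plant more DEGs than frac_de allows")
    }
    extra <- sample(pool, n_de - length(forced))
    de_genes <- c(forced, extra)
    signs <- c(
      rep(1, sum(lengths(module_genes[act_terms]))),
      rep(-1, sum(lengths(module_genes[inact_terms]))),
      sample(c(-1, 1), length(extra), replace = TRUE)
    )
    human_de <- data.frame(
      gene_id = de_genes,
      log2_fold_change = signs * config$lfc_magnitude,
      stringsAsFactors = FALSE
    )
    shared_idx <- sample.int(n_de, round(config$shared_fraction * n_de))
    shared <- human_de[shared_idx, , drop = FALSE]
    n_extra_mouse <- n_de - nrow(shared)
    mouse_specific <- sample(setdiff(gene_ids, de_genes), n_extra_mouse)
    mouse_de <- data.frame(
      gene_id = unname(to_mouse[c(shared$gene_id, mouse_specific)]),
      log2_fold_change = c(shared$log2_fold_change,
                           sample(c(-1, 1), n_extra_mouse, replace = TRUE) *
                             config$lfc_magnitude),
      stringsAsFactors = FALSE
    )
    pm_pool <- setdiff(extra, forced)
    prenatal_max <- sort(sample(pm_pool, config$n_prenatal_max))
    silent_only <- sort(sample(setdiff(pm_pool, prenatal_max),
                               config$n_prenatal_max))
    n_ndd_de <- round(config$ndd_de_fraction * config$n_ndd_genes)
    ndd <- sort(c(sample(de_genes, min(n_ndd_de, length(de_genes))),
                  sample(setdiff(gene_ids, de_genes),
                         config$n_ndd_genes - min(n_ndd_de, length(de_genes)))))
    list(deletion = deletion, module_genes = module_genes,
         act_terms = act_terms, inact_terms = inact_terms,
         human_de = human_de, mouse_de = mouse_de,
         shared = shared$gene_id, prenatal_max = prenatal_max,
         silent_only = silent_only, ndd = ndd)
  })

  hum <- generate_counts(config, human, planted = plan$human_de,
                         deletion_genes = plan$deletion,
                         gene_ids = gene_ids, seed = config$seed + 101L)
  mus <- generate_counts(config, mouse, planted = plan$mouse_de,
                         deletion_genes = unname(to_mouse[plan$deletion]),
                         gene_ids = mouse_ids, seed = config$seed + 202L)
  ppi <- generate_ppi(config, planted_modules = unname(plan$module_genes),
                      gene_ids = gene_ids, seed = config$seed + 303L)
  annotations <- generate_go_annotations(config,
                                         planted_modules = plan$module_genes,
                                         gene_ids = gene_ids,
                                         seed = config$seed + 404L)
  brain_silent <- c(plan$prenatal_max, plan$silent_only)
  tissue_expr <- generate_tissue_expression(
    config, brain_silent_genes = brain_silent,
    cortex_expressed_genes = plan$deletion[seq_len(min(4, length(plan$deletion)))],
    gene_ids = gene_ids, seed = config$seed + 505L
  )
  # remaining deletion genes planted below the cortex threshold
  if (length(plan$deletion) > 4) {
    low <- plan$deletion[-seq_len(4)]
    tissue_expr$brain_cortex[match(low, tissue_expr$gene_id)] <-
      withr::with_seed(config$seed + 606L, stats::runif(length(low), 0, 1.4))
  }
  stage_expr <- generate_stage_expression(
    config, prenatal_max_genes = plan$prenatal_max,
    gene_ids = gene_ids, seed = config$seed + 707L
  )

  truth <- list(
    true_deg_sets = setNames(
      list(plan$human_de$gene_id, plan$mouse_de$gene_id), c(human, mouse)),
    true_shared_set = plan$shared,
    planted_activated_modules = plan$act_terms,
    planted_inactivated_modules = plan$inact_terms,
    module_genes = plan$module_genes,
    true_prenatal_max_genes = plan$prenatal_max,
    brain_silent_genes = brain_silent,
    deletion_genes = plan$deletion
  )
  structure(
    list(config = config,
         counts = setNames(list(hum$counts, mus$counts), c(human, mouse)),
         orthology = orthology, ppi = ppi, annotations = annotations,
         tissue_expr = tissue_expr, stage_expr = stage_expr,
         gene_sets = list(deletion = plan$deletion, ndd = plan$ndd),
         truth = truth),
    class = "sim_study"
  )
}
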
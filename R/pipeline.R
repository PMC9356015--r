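#' Assemble a pipeline run configuration
#'
#' A run configuration names the input files and fixes every analysis
#' constant: the DEG thresholds (adjusted p < 0.05 for the first,
#' "human", dataset; raw p < 0.05 for the others), the low-count
#' filter (total < 10 reads excluded), the overlap null (100,000
#' samplings over a 20,000-gene universe), the module-activity
#' permutations (1000) and z threshold (2), and the tissue/stage
#' expression thresholds (1.5 TPM / 1.5 RPKM). The configuration is
#' echoed verbatim into the output bundle.
#'
#' @param datasets Named list; each element a list with either
#'   `counts` + `samples` paths or a precomputed `deg_table` path, and
#'   a `regime` ("adjusted" or "raw"). The first dataset is the
#'   reference species.
#' @param orthology,ppi,annotations,tissue_expr,stage_expr,gene_sets
#'   Input file paths (`gene_sets` a GMT with `deletion` and `ndd`
#'   sets); any may be NULL, in which case the stages needing them are
#'   skipped with a notice.
#' @param alpha,low_count,tpm_threshold,rpkm_threshold,z_threshold
#'   Analysis thresholds.
#' @param universe_size,n_samplings,n_perm Null-model sizes.
#' @param seed Integer seed for every stochastic stage.
#' @param outdir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(datasets,
                       orthology = NULL, ppi = NULL, annotations = NULL,
                       tissue_expr = NULL, stage_expr = NULL,
                       gene_sets = NULL,
                       alpha = 0.05, low_count = 10,
                       tpm_threshold = 1.5, rpkm_threshold = 1.5,
                       z_threshold = 2,
                       universe_size = 20000, n_samplings = 100000,
                       n_perm = 1000,
                       seed = 1, outdir = "degmods_run") {
  stopifnot(is.list(datasets), length(datasets) >= 1,
            !is.null(names(datasets)))
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    if (is.null(d$deg_table) && (is.null(d$counts) || is.null(d$samples))) {
      stop(sprintf("dataset '%s' needs counts+samples or a deg_table", nm))
    }
    if (is.null(d$regime)) {
      stop(sprintf("dataset '%s' must name its selection regime", nm))
    }
  }
  paths <- c(
    unlist(lapply(datasets, function(d) c(d$counts, d$samples, d$deg_table))),
    orthology, ppi, annotations, tissue_expr, stage_expr, gene_sets
  )
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  structure(
    list(datasets = datasets, orthology = orthology, ppi = ppi,
         annotations = annotations, tissue_expr = tissue_expr,
         stage_expr = stage_expr, gene_sets = gene_sets,
         alpha = alpha, low_count = low_count,
         tpm_threshold = tpm_threshold, rpkm_threshold = rpkm_threshold,
         z_threshold = z_threshold, universe_size = universe_size,
         n_samplings = n_samplings, n_perm = n_perm,
         seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The YAML mirrors the arguments of [run_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  y$datasets <- lapply(y$datasets, function(d) {
    d$counts <- fix(d$counts); d$samples <- fix(d$samples)
    d$deg_table <- fix(d$deg_table); d
  })
  for (k in c("orthology", "ppi", "annotations", "tissue_expr",
              "stage_expr", "gene_sets")) {
    y[[k]] <- fix(y[[k]])
  }
  do.call(run_config, y)
}

pipeline_log <- function(lines, msgs) {
  c(lines, paste(format(Sys.time(), "%H:%M:%S"), msgs))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-dataset count filtering, differential
#' expression (or loading of a precomputed DEG table) and DEG
#' selection; ortholog-mapped cross-species overlap with its
#' permutation null, the deletion-excluded variant, and the
#' control-split negative control; DEG-interacted network and
#' functional-module extraction; module-activity scoring and
#' classification; deletion-region dosage checks; the brain-silent /
#' prenatal-maximum developmental chain with the Tukey HSD stage
#' profile test; and NDD binomial enrichment. Stages whose inputs are
#' absent are skipped with an explicit notice. Per-stage tables, a
#' summary JSON, and a run log are written under `config$outdir`.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  log_lines <- character(0)
  note <- function(msg) {
    log_lines <<- pipeline_log(log_lines, msg)
    message(msg)
  }
  summary <- list(seed = config$seed,
                  thresholds = config[c("alpha", "low_count", "tpm_threshold",
                                        "rpkm_threshold", "z_threshold",
                                        "universe_size", "n_samplings",
                                        "n_perm")])

  # -- differential expression per dataset ------------------------------
  deg_tables <- list()
  deg_sets <- list()
  counts_kept <- list()
  for (nm in names(config$datasets)) {
    d <- config$datasets[[nm]]
    if (!is.null(d$deg_table)) {
      tab <- read_deg_table(d$deg_table)
      note(sprintf("dataset %s: loaded precomputed DEG table (%d genes)",
                   nm, nrow(tab)))
    } else {
      m <- read_count_matrix(d$counts, d$samples)
      m <- filter_low_counts(m, config$low_count)
      counts_kept[[nm]] <- m
      tab <- differential_expression(m)
      note(sprintf("dataset %s: %d genes after low-count filter", nm,
                   nrow(tab)))
    }
    deg_tables[[nm]] <- tab
    deg_sets[[nm]] <- select_degs(tab, regime = d$regime,
                                  alpha = config$alpha)
    note(sprintf("dataset %s: %d DEGs (%s regime, alpha=%g)",
                 nm, length(deg_sets[[nm]]), d$regime, config$alpha))
    write_deg_table(tab, out(sprintf("deg_table_%s.tsv", nm)))
  }
  summary$deg_counts <- lapply(deg_sets, length)
  ref <- names(config$datasets)[1]

  gene_sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
               else list()

  # -- cross-species overlap --------------------------------------------
  if (length(deg_sets) >= 2 && !is.null(config$orthology)) {
    ortho <- read_orthology(config$orthology)
    mapped <- deg_sets
    for (nm in setdiff(names(deg_sets), ref)) {
      mapped[[nm]] <- map_orthologs(deg_sets[[nm]], ortho[c(2, 1)])
    }
    ov <- overlap_sets(mapped)
    perm <- permutation_overlap_p(
      lengths(mapped), ov$k_way, universe_size = config$universe_size,
      n_samplings = config$n_samplings, seed = config$seed + 11L
    )
    summary$overlap <- list(
      set_sizes = unname(lengths(mapped)), k_way = ov$k_way,
      p_empirical = perm$p_empirical
    )
    note(sprintf("overlap: %d shared genes across %d sets, empirical p=%.4g",
                 ov$k_way, length(mapped), perm$p_empirical))
    write_gmt(list(shared_degs = ov$k_way_genes), out("shared_degs.gmt"))

    if (!is.null(gene_sets$deletion)) {
      shared_nodel <- exclude_region_genes(ov$k_way_genes, gene_sets$deletion)
      perm_nodel <- permutation_overlap_p(
        lengths(mapped), length(shared_nodel),
        universe_size = config$universe_size,
        n_samplings = config$n_samplings, seed = config$seed + 12L
      )
      summary$overlap_excluding_deletion <- list(
        k_way = length(shared_nodel), p_empirical = perm_nodel$p_empirical
      )
    }

    refd <- config$datasets[[ref]]
    if (!is.null(refd$counts)) {
      m <- read_count_matrix(refd$counts, refd$samples)
      ctrl <- count_matrix(
        m$counts[, m$group == "control", drop = FALSE],
        rep("control", sum(m$group == "control"))
      )
      if (ncol(ctrl$counts) >= 4) {
        ctrl <- filter_low_counts(ctrl, config$low_count)
        cso <- control_split_overlap(
          ctrl, mapped[setdiff(names(mapped), ref)],
          universe_size = config$universe_size,
          n_samplings = config$n_samplings, seed = config$seed + 13L
        )
        summary$control_split <- list(
          n_control_degs = length(cso$control_degs),
          observed = cso$observed,
          p_empirical = cso$overlap$p_empirical
        )
        note(sprintf("control split: %d DEGs, overlap %d, p=%.3g",
                     length(cso$control_degs), cso$observed,
                     cso$overlap$p_empirical))
      }
    }
  } else {
    note("overlap stage skipped (needs >= 2 datasets and an orthology table)")
  }

  # -- functional modules and activity ----------------------------------
  if (!is.null(config$ppi) && !is.null(config$annotations)) {
    pin <- read_edge_list(config$ppi)
    ann <- filter_experimental_annotations(read_annotations(config$annotations))
    degnet <- build_deg_network(deg_sets[[ref]], pin)
    modules <- extract_functional_modules(degnet, ann, deg_sets[[ref]])
    note(sprintf("modules: %d functional modules from %d annotated terms",
                 length(modules), length(unique(ann$term_id))))
    activity <- score_all_modules(
      deg_tables[[ref]], modules, n_perm = config$n_perm,
      seed = config$seed + 21L, z_threshold = config$z_threshold
    )
    write_tsv(activity, out("module_activity.tsv"))
    act <- activity$term_id[activity$status == "activated"]
    inact <- activity$term_id[activity$status == "inactivated"]
    if (length(modules) > 0) {
      mod_genes <- setNames(lapply(modules, `[[`, "genes"),
                            vapply(modules, `[[`, character(1), "term_id"))
      keep <- c(act, inact)
      if (length(keep) > 0) {
        write_gmt(mod_genes[keep], out("classified_modules.gmt"),
                  descriptions = c(rep("activated", length(act)),
                                   rep("inactivated", length(inact))))
      }
    }
    summary$modules <- list(
      n_modules = length(modules),
      activated = act, inactivated = inact
    )
    note(sprintf("activity: %d activated, %d inactivated",
                 length(act), length(inact)))
  } else {
    note("module stages skipped (needs ppi and annotations)")
  }

  # -- dosage check ------------------------------------------------------
  if (!is.null(config$tissue_expr) && !is.null(gene_sets$deletion)) {
    tis <- read_expression(config$tissue_expr)
    dc <- dosage_check(gene_sets$deletion, tis,
                       threshold = config$tpm_threshold)
    summary$dosage <- lapply(dc, function(x) {
      list(expressed = x$expressed, low = x$low, missing = x$missing)
    })
    note(sprintf("dosage: %d/%d deletion genes expressed in brain cortex",
                 length(dc[[1]]$expressed), length(gene_sets$deletion)))
  }

  # -- developmental-stage chain ----------------------------------------
  if (!is.null(config$tissue_expr) && !is.null(config$stage_expr)) {
    tis <- read_expression(config$tissue_expr)
    stg <- read_expression(config$stage_expr)
    silent <- select_brain_silent_degs(deg_sets[[ref]], tis,
                                       threshold = config$tpm_threshold)
    with_data <- intersect(silent, stg$gene_id)
    summary$developmental <- list(
      n_brain_silent = length(silent),
      n_no_data = length(attr(silent, "no_data")),
      n_with_stage_data = length(with_data)
    )
    if (length(with_data) >= 2) {
      hsd <- stage_profile_test(with_data, stg)
      write_tsv(hsd, out("stage_tukey_hsd.tsv"))
      adult_pren <- hsd$p_adj[(hsd$stage_a == "adult" &
                                 hsd$stage_b == "prenatal") |
                                (hsd$stage_a == "prenatal" &
                                   hsd$stage_b == "adult")]
      summary$developmental$tukey_adult_vs_prenatal_p <-
        if (length(adult_pren) == 1) adult_pren else NULL
    }
    pmax_genes <- select_prenatal_max(silent, stg,
                                      prenatal_threshold = config$rpkm_threshold)
    summary$developmental$n_prenatal_max <- length(pmax_genes)
    write_gmt(list(prenatal_max_degs = pmax_genes), out("prenatal_max.gmt"))
    note(sprintf("developmental: %d brain-silent DEGs, %d prenatal-maximum",
                 length(silent), length(pmax_genes)))
  } else {
    note("developmental stage skipped (needs tissue and stage expression)")
  }

  # -- NDD enrichment ----------------------------------------------------
  if (!is.null(gene_sets$ndd)) {
    universe <- deg_tables[[ref]]$gene_id
    ndd_in_universe <- intersect(gene_sets$ndd, universe)
    enr <- ndd_binomial_enrichment(deg_sets[[ref]], ndd_in_universe, universe)
    summary$ndd <- enr
    note(sprintf("NDD: %d/%d DEGs in the NDD list, binomial p=%.3g",
                 enr$overlap, enr$n_degs, enr$p_value))
  }

  summary$config <- config[setdiff(names(config), "datasets")]
  summary$config$datasets <- lapply(config$datasets, function(d) {
    d[!vapply(d, is.null, logical(1))]
  })
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  writeLines(log_lines, out("run.log"))
  invisible(summary)
}
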
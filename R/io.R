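#' @name io
#' @title Tab-separated and GMT input/output adapters
#' @description
#' All tables are UTF-8, tab-separated, with a header row. Counts are
#' written as a gene-by-sample table (first column `gene_id`) plus a
#' sample sheet (`sample_id`, `group`); DEG tables carry `gene_id`,
#' `log2_fold_change`, `p_raw`, `p_adj`; edge lists are two unordered
#' columns; annotations are GAF-like (`gene_id`, `term_id`,
#' `evidence`, `aspect`); gene sets use the standard GMT layout
#' (name, description, then members). Every writer/reader pair
#' round-trips.
NULL

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname io
#' @param m A [count_matrix()].
#' @param counts_path,samples_path Paths for the count table and the
#'   sample sheet.
#' @export
write_count_matrix <- function(m, counts_path, samples_path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(sample_id = colnames(m$counts),
                       group = as.character(m$group),
                       stringsAsFactors = FALSE), samples_path)
  invisible(counts_path)
}

#' @rdname io
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- read_tsv_checked(counts_path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate gene ids: %s", paste(unique(dup), collapse = ", ")))
  }
  samples <- read_tsv_checked(samples_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  if (!identical(sort(colnames(counts)), sort(samples$sample_id))) {
    stop("sample sheet does not match count columns")
  }
  group <- samples$group[match(colnames(counts), samples$sample_id)]
  count_matrix(counts, group)
}

#' @rdname io
#' @param t DEG table data frame.
#' @param path File path.
#' @export
write_deg_table <- function(t, path) {
  stopifnot(all(c("gene_id", "log2_fold_change", "p_raw", "p_adj") %in%
                  names(t)))
  write_tsv(t[, c("gene_id", "log2_fold_change", "p_raw", "p_adj")], path)
}

#' @rdname io
#' @export
read_deg_table <- function(path) {
  t <- read_tsv_checked(path)
  req <- c("gene_id", "log2_fold_change", "p_raw", "p_adj")
  if (!all(req %in% names(t))) {
    stop(sprintf("DEG table must have columns: %s", paste(req, collapse = ", ")))
  }
  dup <- t$gene_id[duplicated(t$gene_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate gene ids: %s", paste(unique(dup), collapse = ", ")))
  }
  for (col in c("p_raw", "p_adj")) {
    v <- t[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) {
      stop(sprintf("%s outside [0, 1] at line %d of %s",
                   col, bad[1] + 1L, path))
    }
  }
  t[req]
}

#' @rdname io
#' @param net A [ppi_network()].
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  write_tsv(net$edges, path)
}

#' @rdname io
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("edge list needs two columns")
  ppi_network(df)
}

#' @rdname io
#' @param annotations Annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  req <- c("gene_id", "term_id", "evidence", "aspect")
  stopifnot(all(req %in% names(annotations)))
  write_tsv(annotations[req], path)
}

#' @rdname io
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path)
  req <- c("gene_id", "term_id", "evidence", "aspect")
  if (!all(req %in% names(df))) {
    stop(sprintf("annotation table must have columns: %s",
                 paste(req, collapse = ", ")))
  }
  df[req]
}

#' @rdname io
#' @param sets Named list of character vectors (gene sets).
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) {
    if (length(p) < 2) stop("malformed GMT line (need name and description)")
    p[-(1:2)]
  })
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname io
#' @param table Two-column orthology data frame.
#' @export
write_orthology <- function(table, path) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  write_tsv(table[1:2], path)
}

#' @rdname io
#' @export
read_orthology <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("orthology table needs two columns")
  df[1:2]
}

#' @rdname io
#' @param expr Expression data frame (`gene_id` plus numeric columns).
#' @export
write_expression <- function(expr, path) {
  stopifnot("gene_id" %in% names(expr))
  write_tsv(expr, path)
}

#' @rdname io
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  if (!"gene_id" %in% names(df)) stop("expression table needs a gene_id column")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate gene ids: %s", paste(unique(dup), collapse = ", ")))
  }
  df
}

#' Write every table of a simulated study to a directory
#'
#' Materialises a [simulate_study()] bundle as the plain-text files the
#' pipeline reads back: per-species counts and sample sheets, the
#' orthology table, the PPI edge list, GO annotations, tissue and
#' stage expression, a GMT with the deletion-region and NDD gene sets,
#' and the planted truth as JSON.
#'
#' @param sim A `sim_study` from [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (sp in names(sim$counts)) {
    write_count_matrix(sim$counts[[sp]],
                       p(sprintf("counts_%s.tsv", sp)),
                       p(sprintf("samples_%s.tsv", sp)))
  }
  write_orthology(sim$orthology, p("orthology.tsv"))
  write_edge_list(sim$ppi, p("ppi_edges.tsv"))
  write_annotations(sim$annotations, p("go_annotations.tsv"))
  write_expression(sim$tissue_expr, p("tissue_expression.tsv"))
  write_expression(sim$stage_expr, p("stage_expression.tsv"))
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(outdir)
}
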
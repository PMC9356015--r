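#' Construct a protein-interaction network
#'
#' Normalises an edge list into a simple undirected graph: self-loops
#' are removed, each unordered pair is stored once (duplicates and
#' reversed duplicates collapse), and the node set is the union of edge
#' endpoints plus any explicitly supplied isolated nodes.
#'
#' @param edges Two-column data frame or matrix of gene-id pairs. May
#'   be empty.
#' @param nodes Optional character vector of additional node ids
#'   (isolated nodes are allowed).
#' @return An object of class `ppi_network`: list with `nodes`
#'   (character) and `edges` (data frame with columns `a`, `b`,
#'   `a < b` lexicographically).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    ed <- data.frame(a = character(0), b = character(0),
                     stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges[[1]])
    b <- as.character(edges[[2]])
    keep <- a != b
    lo <- pmin(a[keep], b[keep])
    hi <- pmax(a[keep], b[keep])
    ed <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
    rownames(ed) <- NULL
  }
  all_nodes <- sort(unique(c(ed$a, ed$b, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = ed), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a ppi_network to an igraph object
#'
#' @param x A [ppi_network()].
#' @return An undirected [igraph::graph] on the same nodes and edges.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "ppi_network"))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = x$nodes)
}

#' Build the DEG-interacted network
#'
#' The DEG-interacted network is the subgraph of the protein-interaction
#' network spanned by the DEGs and their first interaction neighbours:
#' its node set is `(degs` intersected with the network) plus every
#' direct neighbour of a DEG, and its edge set is the parent network's
#' edges induced on that node set. DEGs absent from the network are
#' dropped with a message.
#'
#' @param degs Character vector of DEG ids.
#' @param pin A [ppi_network()].
#' @return A `ppi_network` (DEGs with no interaction partner remain as
#'   isolated nodes).
#' @export
build_deg_network <- function(degs, pin) {
  stopifnot(inherits(pin, "ppi_network"))
  degs <- unique(as.character(degs))
  present <- intersect(degs, pin$nodes)
  if (length(present) < length(degs)) {
    message(sprintf("build_deg_network: %d DEG(s) absent from the network",
                    length(degs) - length(present)))
  }
  if (length(present) == 0) return(ppi_network())
  touch_a <- pin$edges$a %in% present
  touch_b <- pin$edges$b %in% present
  neighbours <- unique(c(pin$edges$b[touch_a], pin$edges$a[touch_b]))
  node_set <- union(present, neighbours)
  keep <- pin$edges$a %in% node_set & pin$edges$b %in% node_set
  ppi_network(pin$edges[keep, , drop = FALSE], nodes = node_set)
}

#' Experimental GO evidence codes
#'
#' The GO consortium's experimental-evidence branch, used by default to
#' restrict annotations to those supported by experiments.
#' @export
EXPERIMENTAL_EVIDENCE_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Filter GO annotations to experimentally supported biological process
#'
#' Keeps annotation rows whose evidence code belongs to the
#' experimental set and whose GO aspect is biological process (`"P"`).
#' Rows with an unknown evidence code are removed and counted in a
#' message.
#'
#' @param annotations Data frame with columns `gene_id`, `term_id`,
#'   `evidence`, `aspect` (aspect `"P"`/`"F"`/`"C"`).
#' @param codes Character vector of evidence codes treated as
#'   experimental; default [EXPERIMENTAL_EVIDENCE_CODES].
#' @return The filtered annotation data frame.
#' @export
filter_experimental_annotations <- function(annotations,
                                            codes = EXPERIMENTAL_EVIDENCE_CODES) {
  stopifnot(is.data.frame(annotations))
  req <- c("gene_id", "term_id", "evidence", "aspect")
  if (!all(req %in% names(annotations))) {
    stop("annotations must have columns gene_id, term_id, evidence, aspect")
  }
  known <- c(codes, "IEA", "ISS", "ISO", "ISA", "ISM", "IGC", "IBA", "IBD",
             "IKR", "IRD", "RCA", "TAS", "NAS", "IC", "ND", "HTP", "HDA",
             "HMP", "HGI", "HEP")
  unknown <- setdiff(unique(annotations$evidence), known)
  if (length(unknown) > 0) {
    message(sprintf("filter_experimental_annotations: %d unknown evidence code(s) removed: %s",
                    length(unknown), paste(unknown, collapse = ", ")))
  }
  keep <- annotations$evidence %in% codes & annotations$aspect == "P"
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract DEG-interacted functional modules
#'
#' A functional module is the subnetwork of the DEG-interacted network
#' formed by the genes annotated to one GO biological-process term. For
#' each term, the module genes are the annotated genes present in the
#' network, and the module edges are the network edges induced on those
#' genes. A module is retained only if it contains at least one DEG and
#' at least one interaction (edge); modules are not required to be
#' connected.
#'
#' @param net The DEG-interacted network (a [ppi_network()], typically
#'   from [build_deg_network()]).
#' @param annotations Annotation data frame, already filtered to
#'   experimental biological-process rows (see
#'   [filter_experimental_annotations()]).
#' @param degs Character vector of DEG ids.
#' @return A list of `functional_module` objects, each a list with
#'   `term_id`, `genes`, `edges` (data frame `a`,`b`), and
#'   `deg_members`. Ordered by term id.
#' @export
extract_functional_modules <- function(net, annotations, degs) {
  stopifnot(inherits(net, "ppi_network"), is.data.frame(annotations))
  degs <- unique(as.character(degs))
  if (nrow(annotations) == 0) return(list())
  by_term <- split(as.character(annotations$gene_id),
                   as.character(annotations$term_id))
  by_term <- by_term[sort(names(by_term))]
  out <- list()
  for (term in names(by_term)) {
    genes <- sort(intersect(unique(by_term[[term]]), net$nodes))
    if (length(genes) < 2) next
    keep <- net$edges$a %in% genes & net$edges$b %in% genes
    edges <- net$edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
    deg_members <- intersect(genes, degs)
    if (nrow(edges) >= 1 && length(deg_members) >= 1) {
      out[[term]] <- structure(
        list(term_id = term, genes = genes, edges = edges,
             deg_members = deg_members),
        class = "functional_module"
      )
    }
  }
  unname(out)
}

#' @export
print.functional_module <- function(x, ...) {
  cat(sprintf("functional_module %s: %d genes, %d edges, %d DEG(s)\n",
              x$term_id, length(x$genes), nrow(x$edges),
              length(x$deg_members)))
  invisible(x)
}
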
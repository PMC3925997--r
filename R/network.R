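# Thresholded gene networks with an undirected co-expression view and a
# derived directed regulation view: every co-expression edge incident to a
# TF becomes a TF -> gene edge; TF-TF edges are kept reciprocal (both
# directions), since one-way TF -> TF directionality is not inferred.

new_gene_network <- function(genes, from, to, score, tf_ids, threshold) {
  stopifnot(!anyDuplicated(genes))
  unknown_tf <- setdiff(tf_ids, genes)
  if (length(unknown_tf) > 0) {
    warning("ignoring ", length(unknown_tf),
            " TF id(s) not in the gene universe: ",
            paste(utils::head(unknown_tf, 3), collapse = ", "),
            if (length(unknown_tf) > 3) ", ...")
    tf_ids <- intersect(tf_ids, genes)
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]; score <- score[keep]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  dup <- duplicated(paste(from, to, sep = "\r"))
  from <- from[!dup]; to <- to[!dup]; score <- score[!dup]
  edges <- data.frame(from = from, to = to, score = score,
                      stringsAsFactors = FALSE)
  is_tf <- genes %in% tf_ids
  names(is_tf) <- genes
  # regulation view
  a_tf <- edges$from %in% tf_ids
  b_tf <- edges$to %in% tf_ids
  reg_from <- c(edges$from[a_tf], edges$to[b_tf])
  reg_to <- c(edges$to[a_tf], edges$from[b_tf])
  reg <- data.frame(from = reg_from, to = reg_to, stringsAsFactors = FALSE)
  connected <- genes %in% c(edges$from, edges$to)
  names(connected) <- genes
  structure(
    list(nodes = data.frame(gene = genes, tf = unname(is_tf),
                            connected = unname(connected),
                            stringsAsFactors = FALSE),
         edges = edges, reg_edges = reg, threshold = threshold),
    class = "gene_network"
  )
}

#' Build a thresholded gene network from a CLR score matrix
#'
#' An undirected co-expression edge links every gene pair with CLR score >=
#' `threshold` (inclusive; ties kept). The directed regulation view contains
#' a TF -> gene edge for every co-expression edge incident to a TF, with
#' TF-TF edges reciprocal both ways. Genes without edges are retained as
#' isolated nodes and flagged unconnected.
#'
#' @param clr a [score_matrix()] of kind `"CLR"`.
#' @param threshold positive CLR cutoff.
#' @param tf_ids transcription-factor gene ids; unknown ids produce a
#'   warning and are ignored.
#' @return A `gene_network`.
#' @export
build_network <- function(clr, threshold, tf_ids = character(0)) {
  stopifnot(inherits(clr, "score_matrix"))
  if (clr$kind != "CLR") stop("build_network expects a CLR score matrix")
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  S <- clr$scores
  genes <- rownames(S)
  ut <- which(upper.tri(S) & !is.na(S) & S >= threshold, arr.ind = TRUE)
  new_gene_network(genes,
                   from = genes[ut[, 1]], to = genes[ut[, 2]],
                   score = S[ut], tf_ids = tf_ids, threshold = threshold)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network (CLR threshold ", x$threshold, "): ",
      nrow(x$nodes), " nodes (", sum(x$nodes$tf), " TFs, ",
      sum(x$nodes$connected), " connected), ",
      nrow(x$edges), " co-expression edges, ",
      nrow(x$reg_edges), " regulation edges\n", sep = "")
  invisible(x)
}

#' Convert a gene network to an igraph object
#'
#' @param net a `gene_network`.
#' @param view `"coexpression"` (undirected) or `"regulation"` (directed).
#' @param connected_only drop isolated nodes.
#' @return An igraph graph with vertex attribute `tf`.
#' @export
as_igraph <- function(net, view = c("coexpression", "regulation"),
                      connected_only = FALSE) {
  view <- match.arg(view)
  nodes <- net$nodes
  if (view == "coexpression") {
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = FALSE, vertices = nodes$gene)
  } else {
    reg_nodes <- unique(c(net$reg_edges$from, net$reg_edges$to))
    verts <- if (connected_only) nodes$gene[nodes$gene %in% reg_nodes] else nodes$gene
    g <- igraph::graph_from_data_frame(net$reg_edges, directed = TRUE,
                                       vertices = verts)
  }
  if (connected_only && view == "coexpression") {
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  igraph::V(g)$tf <- nodes$tf[match(igraph::V(g)$name, nodes$gene)]
  g
}

# adjacency list (named list) of the undirected co-expression view
adjacency_list <- function(net) {
  e <- net$edges
  if (nrow(e) == 0) return(list())
  lapply(split(c(e$to, e$from), c(e$from, e$to)), unique)
}

#' Neighbourhood of a gene (undirected co-expression view)
#'
#' @param net a `gene_network`.
#' @param gene gene id.
#' @return Character vector of directly linked genes.
#' @export
neighbours <- function(net, gene) {
  e <- net$edges
  unique(c(e$to[e$from == gene], e$from[e$to == gene]))
}

#' Connected genes of a network
#' @param net a `gene_network`.
#' @return Character vector of genes with at least one neighbour.
#' @export
connected_genes <- function(net) net$nodes$gene[net$nodes$connected]
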
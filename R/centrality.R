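#' Gene centralities
#'
#' Degree, average nearest-neighbour (avnn) degree and betweenness per gene.
#' The co-expression view treats edges as undirected. In the regulation view
#' degree is out-degree for TFs and in-degree for non-TF genes; avnn averages
#' the rule-degree of a TF's out-neighbours and of a gene's in-neighbours;
#' betweenness uses the directed graph. Betweenness is unnormalized raw pair
#' counts. avnn is `NA` for isolated nodes.
#'
#' @param net a `gene_network`.
#' @param view `"coexpression"` or `"regulation"`.
#' @return A `data.frame` (gene, tf, connected, degree, avnn, betweenness).
#' @export
compute_centralities <- function(net, view = c("coexpression", "regulation")) {
  view <- match.arg(view)
  if (nrow(net$nodes) == 0) stop("empty network")
  genes <- net$nodes$gene
  is_tf <- net$nodes$tf
  if (view == "coexpression") {
    g <- as_igraph(net, "coexpression")
    deg <- igraph::degree(g)[genes]
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)[genes]
    adj <- adjacency_list(net)
    avnn <- vapply(genes, function(v) {
      nb <- adj[[v]]
      if (is.null(nb) || length(nb) == 0) return(NA_real_)
      mean(deg[nb])
    }, 0)
  } else {
    g <- as_igraph(net, "regulation")
    indeg <- igraph::degree(g, mode = "in")[genes]
    outdeg <- igraph::degree(g, mode = "out")[genes]
    deg <- ifelse(is_tf, outdeg, indeg)
    names(deg) <- genes
    btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)[genes]
    e <- net$reg_edges
    out_nb <- split(e$to, e$from)
    in_nb <- split(e$from, e$to)
    avnn <- vapply(seq_along(genes), function(i) {
      v <- genes[i]
      nb <- if (is_tf[i]) out_nb[[v]] else in_nb[[v]]
      nb <- unique(nb)
      if (is.null(nb) || length(nb) == 0) return(NA_real_)
      mean(deg[nb])
    }, 0)
  }
  data.frame(gene = genes, tf = is_tf,
             connected = net$nodes$connected,
             degree = as.numeric(deg), avnn = as.numeric(avnn),
             betweenness = as.numeric(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species conservation of gene centrality
#'
#' A gene is conserved if it ranks in the top (or bottom) `fraction` of the
#' chosen centrality among connected genes in the focal species (the first
#' table) and has at least one ortholog in the corresponding top/bottom set
#' of every other species. Significance is an empirical p-value from
#' randomized gene lists of the same sizes, p = (r + 1) / (n_rand + 1).
#'
#' @param tables named list (by species) of [compute_centralities()] tables;
#'   the first entry is the focal species.
#' @param map an [ortholog_map()].
#' @param measure `"degree"`, `"avnn"` or `"betweenness"`.
#' @param direction `"top"` or `"bottom"`.
#' @param fraction rank fraction in (0, 0.5].
#' @param n_rand number of randomized lists (>= 100 recommended).
#' @param seed RNG seed.
#' @return List with `conserved` (focal gene ids), `n_ranked` (size of the
#'   focal top set), `fraction_conserved`, and `p`.
#' @export
centrality_conservation <- function(tables, map, measure = "degree",
                                    direction = c("top", "bottom"),
                                    fraction = 0.10, n_rand = 1000L,
                                    seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  if (n_rand < 100) warning("n_rand < 100 gives coarse empirical p-values")
  species <- names(tables)
  ranked <- lapply(tables, function(tab) {
    tab <- tab[tab$connected, , drop = FALSE]
    top_fraction_ids(tab$gene, tab[[measure]], fraction, direction)
  })
  universes <- lapply(tables, function(tab) tab$gene[tab$connected])
  # ortholog lookup: focal gene -> orthologs in each other species
  focal_sp <- species[1]
  ortho <- lapply(species[-1], function(sp) ortholog_table(map, focal_sp, sp))
  names(ortho) <- species[-1]
  other_sets <- lapply(species[-1], function(sp) {
    list(top = ranked[[sp]], ortho = ortho[[sp]])
  })
  conserved <- Filter(function(g) {
    all(vapply(other_sets, function(o) {
      length(intersect(o$ortho[[g]] %||% character(0), o$top)) > 0
    }, TRUE))
  }, ranked[[1]])
  observed <- length(conserved)
  r <- 0L
  with_seed(seed, {
    sizes <- vapply(ranked, length, 0L)
    for (i in seq_len(n_rand)) {
      rand_focal <- sample(universes[[1]], sizes[1])
      rand_other <- lapply(seq_along(other_sets), function(j) {
        sample(universes[[j + 1]], min(sizes[j + 1], length(universes[[j + 1]])))
      })
      rc <- sum(vapply(rand_focal, function(g) {
        all(vapply(seq_along(other_sets), function(j) {
          length(intersect(other_sets[[j]]$ortho[[g]] %||% character(0),
                           rand_other[[j]])) > 0
        }, TRUE))
      }, TRUE))
      if (rc >= observed) r <- r + 1L
    }
  })
  list(conserved = conserved, n_ranked = length(ranked[[1]]),
       fraction_conserved = if (length(ranked[[1]])) observed / length(ranked[[1]]) else NA_real_,
       p = empirical_p(r, n_rand))
}
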
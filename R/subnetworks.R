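#' Gene Ontology subnetwork statistics
#'
#' For every GO term with between `min_genes` and `max_genes` connected
#' annotated genes, statistics of the induced subgraph: density (internal
#' links over possible links), connectivity (external-to-internal link ratio
#' on the undirected view), and ingoing/outgoing connectivity on the
#' regulation view (directed links entering/leaving the subnetwork over
#' internal directed links). Ratios with zero internal links are `NA` and
#' excluded from rankings.
#'
#' @param net a `gene_network`.
#' @param go data.frame with columns `gene`, `term`.
#' @param min_genes,max_genes eligibility bounds on connected annotated
#'   genes (defaults 10 and 1000).
#' @return data.frame (term, n_genes, density, connectivity,
#'   ingoing_connectivity, outgoing_connectivity).
#' @export
subnetwork_statistics <- function(net, go, min_genes = 10L, max_genes = 1000L) {
  stopifnot(nrow(go) > 0)
  conn <- connected_genes(net)
  go <- go[go$gene %in% conn, , drop = FALSE]
  genes_by_term <- split(go$gene, go$term)
  genes_by_term <- lapply(genes_by_term, unique)
  sizes <- lengths(genes_by_term)
  genes_by_term <- genes_by_term[sizes >= min_genes & sizes <= max_genes]
  e <- net$edges
  re <- net$reg_edges
  out <- lapply(names(genes_by_term), function(term) {
    gs <- genes_by_term[[term]]
    m <- length(gs)
    in_a <- e$from %in% gs
    in_b <- e$to %in% gs
    e_int <- sum(in_a & in_b)
    e_ext <- sum(xor(in_a, in_b))
    density <- e_int / (m * (m - 1) / 2)
    connectivity <- if (e_int > 0) e_ext / e_int else NA_real_
    r_in_a <- re$from %in% gs
    r_in_b <- re$to %in% gs
    r_int <- sum(r_in_a & r_in_b)
    ingoing <- if (r_int > 0) sum(!r_in_a & r_in_b) / r_int else NA_real_
    outgoing <- if (r_int > 0) sum(r_in_a & !r_in_b) / r_int else NA_real_
    data.frame(term = term, n_genes = m, density = density,
               connectivity = connectivity, ingoing_connectivity = ingoing,
               outgoing_connectivity = outgoing, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(term = character(0), n_genes = integer(0),
                      density = numeric(0), connectivity = numeric(0),
                      ingoing_connectivity = numeric(0),
                      outgoing_connectivity = numeric(0))
  }
  res[order(res$term), , drop = FALSE]
}

#' Cross-species conservation of a subnetwork statistic
#'
#' A GO term is conserved if it ranks in the top (or bottom) `fraction` of
#' the chosen statistic in every species. GO term ids are shared across
#' species, so no ortholog map is needed. Significance is an empirical
#' p-value from randomized term lists of the same sizes. With no eligible
#' terms the p-value is `NA`.
#'
#' @param stats_list named list (by species) of [subnetwork_statistics()]
#'   tables.
#' @param statistic column name to rank on.
#' @param direction `"top"` or `"bottom"`.
#' @param fraction rank fraction in (0, 0.5].
#' @param n_rand randomized lists.
#' @param seed RNG seed.
#' @return List with `conserved` (term ids), `n_ranked`, `p`.
#' @export
statistic_conservation <- function(stats_list, statistic = "density",
                                   direction = c("top", "bottom"),
                                   fraction = 0.10, n_rand = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(stats_list) >= 2)
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  if (n_rand < 100) warning("n_rand < 100 gives coarse empirical p-values")
  eligible <- lapply(stats_list, function(s) {
    s[!is.na(s[[statistic]]), c("term", statistic)]
  })
  tops <- lapply(eligible, function(s) {
    top_fraction_ids(s$term, s[[statistic]], fraction, direction)
  })
  conserved <- Reduce(intersect, tops)
  if (all(vapply(tops, length, 0L) == 0)) {
    return(list(conserved = character(0), n_ranked = 0L, p = NA_real_))
  }
  observed <- length(conserved)
  r <- 0L
  with_seed(seed, {
    for (i in seq_len(n_rand)) {
      rand_sets <- lapply(eligible, function(s) {
        sample(s$term, min(ceiling(fraction * nrow(s)), nrow(s)))
      })
      if (length(Reduce(intersect, rand_sets)) >= observed) r <- r + 1L
    }
  })
  list(conserved = conserved, n_ranked = length(tops[[1]]),
       p = empirical_p(r, n_rand))
}

#' Tau tissue-specificity scores
#'
#' tau = sum_i (1 - x_i / x_max) / (n_tissues - 1) over per-tissue mean
#' expression, with means floored at 0 before computing. tau is 0 for a
#' uniform profile and 1 for single-tissue expression. Genes whose floored
#' profile is all zero get `NA`.
#'
#' @param expr an [expression_matrix()].
#' @param tissue character vector mapping each sample (column) to a tissue.
#' @return data.frame (gene, tau).
#' @export
tau_scores <- function(expr, tissue) {
  stopifnot(length(tissue) == ncol(expr))
  tissues <- unique(tissue)
  if (length(tissues) < 2) stop("need at least 2 tissues")
  means <- vapply(tissues, function(t) {
    rowMeans(expr[, tissue == t, drop = FALSE])
  }, numeric(nrow(expr)))
  means <- matrix(pmax(means, 0), nrow = nrow(expr),
                  dimnames = list(rownames(expr), tissues))
  xmax <- apply(means, 1, max)
  tau <- ifelse(xmax > 0,
                rowSums(1 - means / xmax) / (length(tissues) - 1),
                NA_real_)
  data.frame(gene = rownames(expr), tau = as.numeric(tau),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' GO term enrichment of a gene set
#'
#' Upper-tail hypergeometric test per GO term against a gene universe, with
#' Bonferroni or Benjamini-Hochberg correction.
#'
#' @param genes gene set (must be a subset of `universe`).
#' @param universe background gene ids.
#' @param go data.frame with columns `gene`, `term`.
#' @param correction `"bonferroni"` or `"bh"`.
#' @return data.frame (term, n_term, n_overlap, p, p_adjusted), sorted by p.
#' @export
go_enrichment <- function(genes, universe, go,
                          correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  if (length(genes) == 0) stop("empty gene set")
  if (!all(genes %in% universe)) stop("gene set must be a subset of the universe")
  go <- go[go$gene %in% universe, , drop = FALSE]
  by_term <- lapply(split(go$gene, go$term), unique)
  N <- length(unique(universe))
  s <- length(unique(genes))
  rows <- lapply(names(by_term), function(term) {
    k <- length(by_term[[term]])
    x <- length(intersect(by_term[[term]], genes))
    p <- stats::phyper(x - 1, k, N - k, s, lower.tail = FALSE)
    data.frame(term = term, n_term = k, n_overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, res$p * nrow(res))
  } else {
    stats::p.adjust(res$p, method = "BH")
  }
  res[order(res$p, res$term), , drop = FALSE]
}
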
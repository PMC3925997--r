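# Cross-species conservation of links and network neighbourhoods.
#
# Comparing species S1 to S2: statistics are reported relative to the genes
# that are connected in S1 and have at least one connected predicted
# ortholog in S2. A link A-B is conserved if any ortholog of A is linked to
# any ortholog of B in S2. A neighbourhood is conserved/diverged per the
# hypergeometric test Hypergeometric(N, k, n) at overlap x, where N is the
# S1 gene universe, n the neighbourhood size of A, k the number of distinct
# S1 orthologs of the neighbours of A', and x the overlap; upper tail for
# conservation, lower tail for divergence, each family FDR-corrected
# separately (Benjamini-Hochberg).

#' Eligible genes for a directed species comparison
#'
#' Genes connected in the S1 network that have at least one predicted
#' ortholog connected in the S2 network.
#'
#' @param net1,net2 `gene_network`s of the two species.
#' @param map an [ortholog_map()].
#' @param from,to species labels of `net1` and `net2` in the map.
#' @return Character vector of S1 gene ids.
#' @export
eligible_genes <- function(net1, net2, map, from, to) {
  conn1 <- connected_genes(net1)
  conn2 <- connected_genes(net2)
  ortho <- ortholog_table(map, from, to)
  keep <- vapply(conn1, function(g) {
    o <- ortho[[g]]
    !is.null(o) && any(o %in% conn2)
  }, TRUE)
  conn1[keep]
}

#' Link conservation between two networks
#'
#' Fraction of S1 co-expression links among eligible genes for which some
#' ortholog of one endpoint is linked to some ortholog of the other endpoint
#' in S2. The two networks may be built at different thresholds. `NA` when
#' there are no eligible links.
#'
#' @inheritParams eligible_genes
#' @return List with `fraction`, `n_links`, `n_conserved`, and `links`
#'   (data.frame from, to, conserved).
#' @export
link_conservation <- function(net1, net2, map, from, to) {
  elig <- eligible_genes(net1, net2, map, from, to)
  e <- net1$edges
  e <- e[e$from %in% elig & e$to %in% elig, , drop = FALSE]
  if (nrow(e) == 0) {
    return(list(fraction = NA_real_, n_links = 0L, n_conserved = 0L,
                links = data.frame(from = character(0), to = character(0),
                                   conserved = logical(0))))
  }
  e2 <- net2$edges
  edge_env <- new.env(parent = emptyenv())
  if (nrow(e2) > 0) {
    keys <- edge_key(e2$from, e2$to)
    for (k in keys) assign(k, TRUE, edge_env)
  }
  ortho <- ortholog_table(map, from, to)
  conserved <- vapply(seq_len(nrow(e)), function(i) {
    oa <- ortho[[e$from[i]]]
    ob <- ortho[[e$to[i]]]
    if (is.null(oa) || is.null(ob)) return(FALSE)
    for (a in oa) {
      for (b in ob) {
        if (a != b && !is.null(edge_env[[edge_key(a, b)]])) return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  list(fraction = mean(conserved), n_links = nrow(e),
       n_conserved = sum(conserved),
       links = data.frame(from = e$from, to = e$to, conserved = conserved,
                          stringsAsFactors = FALSE))
}

#' Null distribution of link conservation from name-shuffled networks
#'
#' Permutes the gene labels of the S1 network (topology intact) and
#' recomputes the conserved-link fraction, `n_rand` times.
#'
#' @inheritParams eligible_genes
#' @param n_rand number of randomizations (>= 10).
#' @param seed RNG seed.
#' @return Numeric vector of null fractions (may contain `NA` for
#'   degenerate shuffles with no eligible links).
#' @export
randomized_link_conservation <- function(net1, net2, map, from, to,
                                         n_rand = 100L, seed = 1L) {
  if (n_rand < 10) stop("n_rand must be >= 10")
  genes <- net1$nodes$gene
  tf_ids <- genes[net1$nodes$tf]
  with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      relabel <- stats::setNames(sample(genes), genes)
      rnet <- new_gene_network(genes,
                               from = unname(relabel[net1$edges$from]),
                               to = unname(relabel[net1$edges$to]),
                               score = net1$edges$score,
                               tf_ids = tf_ids, threshold = net1$threshold)
      link_conservation(rnet, net2, map, from, to)$fraction
    }, 0)
  })
}

hyper_tails <- function(N, n, k, x) {
  # Hypergeometric(N, k, n): draw n genes from a universe of N containing k
  # marked genes; x marked among the drawn.
  p_cons <- stats::phyper(x - 1, k, N - k, n, lower.tail = FALSE)
  p_div <- stats::phyper(x, k, N - k, n)
  c(p_conserved = p_cons, p_diverged = p_div)
}

#' Neighbourhood-overlap test for one ortholog pair
#'
#' @param gene eligible S1 gene A.
#' @param ortholog connected S2 ortholog A'.
#' @inheritParams eligible_genes
#' @param universe_size N; defaults to the number of genes in the S1
#'   network's node universe.
#' @return One-row data.frame (gene, ortholog, N, n, k, x, p_conserved,
#'   p_diverged, bitscore).
#' @export
neighbourhood_test <- function(gene, ortholog, net1, net2, map, from, to,
                               universe_size = NULL) {
  if (!ortholog %in% orthologs(map, gene, species = to)) {
    stop("'", ortholog, "' is not a predicted ortholog of '", gene, "'")
  }
  adj1 <- adjacency_list(net1)
  adj2 <- adjacency_list(net2)
  back <- ortholog_table(map, to, from)
  neighbourhood_test_impl(gene, ortholog, adj1, adj2, back,
                          universe_size %||% nrow(net1$nodes),
                          bitscore(map, gene, ortholog))
}

neighbourhood_test_impl <- function(gene, ortholog, adj1, adj2, back, N, bs) {
  nb1 <- adj1[[gene]] %||% character(0)
  nb2 <- adj2[[ortholog]] %||% character(0)
  mapped <- unique(unlist(back[nb2], use.names = FALSE)) %||% character(0)
  n <- length(nb1)
  k <- length(mapped)
  x <- length(intersect(nb1, mapped))
  p <- hyper_tails(N, n, k, x)
  data.frame(gene = gene, ortholog = ortholog, N = N, n = n, k = k, x = x,
             p_conserved = unname(p["p_conserved"]),
             p_diverged = unname(p["p_diverged"]),
             bitscore = bs, stringsAsFactors = FALSE)
}

#' All neighbourhood tests for a directed species comparison
#'
#' One hypergeometric test per (eligible S1 gene, connected S2 ortholog)
#' pair.
#'
#' @inheritParams eligible_genes
#' @param universe_size N for every test; defaults to the S1 node universe.
#' @return data.frame of tests with attributes `from`, `to`.
#' @export
neighbourhood_tests <- function(net1, net2, map, from, to,
                                universe_size = NULL) {
  elig <- eligible_genes(net1, net2, map, from, to)
  adj1 <- adjacency_list(net1)
  adj2 <- adjacency_list(net2)
  ortho <- ortholog_table(map, from, to)
  back <- ortholog_table(map, to, from)
  conn2 <- connected_genes(net2)
  N <- universe_size %||% nrow(net1$nodes)
  rows <- list()
  for (g in elig) {
    for (o in intersect(ortho[[g]], conn2)) {
      rows[[length(rows) + 1L]] <-
        neighbourhood_test_impl(g, o, adj1, adj2, back, N,
                                bitscore(map, g, o))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(0), ortholog = character(0), N = integer(0),
               n = integer(0), k = integer(0), x = integer(0),
               p_conserved = numeric(0), p_diverged = numeric(0),
               bitscore = numeric(0))
  }
  attr(out, "from") <- from
  attr(out, "to") <- to
  out
}

#' Classify genes by neighbourhood conservation
#'
#' Benjamini-Hochberg FDR is applied separately to the conserved-tail and
#' diverged-tail p-value families across all ortholog pairs of the
#' comparison. A gene is Conserved if it has at least one significantly
#' conserved ortholog-neighbourhood and no diverged one,
#' Conserved-and-Diverged if it has both (possibly through different
#' orthologs), Diverged if only diverged, and None otherwise.
#'
#' @param tests data.frame from [neighbourhood_tests()].
#' @param fdr FDR level (default 0.05).
#' @return A `conservation_report`: list with `tests` (q-values and
#'   significance flags added), `genes` (gene, category), `fdr`, `counts`.
#' @export
classify_genes <- function(tests, fdr = 0.05) {
  if (nrow(tests) == 0) stop("empty test set")
  tests$q_conserved <- stats::p.adjust(tests$p_conserved, method = "BH")
  tests$q_diverged <- stats::p.adjust(tests$p_diverged, method = "BH")
  tests$sig_conserved <- tests$q_conserved <= fdr
  tests$sig_diverged <- tests$q_diverged <= fdr
  by_gene <- split(tests, tests$gene)
  category <- vapply(by_gene, function(tt) {
    has_c <- any(tt$sig_conserved)
    has_d <- any(tt$sig_diverged)
    if (has_c && has_d) "Conserved-and-Diverged"
    else if (has_c) "Conserved"
    else if (has_d) "Diverged"
    else "None"
  }, "")
  genes <- data.frame(gene = names(by_gene), category = unname(category),
                      stringsAsFactors = FALSE)
  counts <- table(factor(genes$category,
                         levels = c("Conserved", "Conserved-and-Diverged",
                                    "Diverged", "None")))
  structure(list(tests = tests, genes = genes, fdr = fdr, counts = counts,
                 from = attr(tests, "from"), to = attr(tests, "to")),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("Neighbourhood conservation report")
  if (!is.null(x$from)) cat(" (", x$from, " -> ", x$to, ")", sep = "")
  cat(": ", nrow(x$genes), " eligible genes, FDR ", x$fdr, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

# deterministic "most significant" ordering for conserved (or diverged) tests
order_most_significant <- function(tt, tail = c("conserved", "diverged")) {
  tail <- match.arg(tail)
  bs <- ifelse(is.na(tt$bitscore), -Inf, tt$bitscore)
  if (tail == "conserved") {
    order(tt$p_conserved, -tt$x, -bs, tt$ortholog)
  } else {
    order(tt$p_diverged, tt$x, -bs, tt$ortholog)
  }
}

#' Reciprocal neighbourhood classification
#'
#' A gene A in S1 is reciprocally conserved if its most significant
#' conserved ortholog A' (ties broken by p, then overlap x, then bit-score,
#' then id) has A as its own most significant conserved ortholog in the
#' reverse comparison, and both tests pass FDR; correspondingly for
#' divergence. For paralog pairs that both best-match the same gene, at most
#' one can be reciprocal.
#'
#' @param tests12 tests for S1 -> S2 from [neighbourhood_tests()].
#' @param tests21 tests for S2 -> S1.
#' @param fdr FDR level.
#' @return A `conservation_report` for S1 genes with categories Conserved,
#'   Conserved-and-Diverged, Diverged, None (reciprocal semantics).
#' @export
reciprocal_classify <- function(tests12, tests21, fdr = 0.05) {
  r12 <- classify_genes(tests12, fdr)
  r21 <- classify_genes(tests21, fdr)
  best_of <- function(tests, tail) {
    picks <- lapply(split(tests, tests$gene), function(tt) {
      tt[order_most_significant(tt, tail)[1], c("gene", "ortholog",
                                                if (tail == "conserved") "sig_conserved" else "sig_diverged")]
    })
    do.call(rbind, picks)
  }
  bc12 <- best_of(r12$tests, "conserved"); bd12 <- best_of(r12$tests, "diverged")
  bc21 <- best_of(r21$tests, "conserved"); bd21 <- best_of(r21$tests, "diverged")
  recip <- function(b12, b21, flag) {
    back <- stats::setNames(b21$ortholog, b21$gene)
    ok12 <- stats::setNames(b12[[flag]], b12$gene)
    ok21 <- stats::setNames(b21[[flag]], b21$gene)
    vapply(seq_len(nrow(b12)), function(i) {
      a <- b12$gene[i]; ap <- b12$ortholog[i]
      isTRUE(ok12[[a]]) && identical(unname(back[ap]), a) && isTRUE(ok21[[ap]])
    }, TRUE)
  }
  cons <- stats::setNames(recip(bc12, bc21, "sig_conserved"), bc12$gene)
  divg <- stats::setNames(recip(bd12, bd21, "sig_diverged"), bd12$gene)
  genes <- data.frame(gene = bc12$gene, stringsAsFactors = FALSE)
  genes$category <- ifelse(cons[genes$gene] & divg[genes$gene], "Conserved-and-Diverged",
                    ifelse(cons[genes$gene], "Conserved",
                    ifelse(divg[genes$gene], "Diverged", "None")))
  counts <- table(factor(genes$category,
                         levels = c("Conserved", "Conserved-and-Diverged",
                                    "Diverged", "None")))
  structure(list(tests = r12$tests, genes = genes, fdr = fdr, counts = counts,
                 from = attr(tests12, "from"), to = attr(tests12, "to"),
                 reciprocal = TRUE),
            class = "conservation_report")
}

#' Multi-ortholog conservation categories
#'
#' For genes with at least two predicted orthologs in the target species:
#' Uniquely conserved (every connected ortholog-neighbourhood significantly
#' conserved) takes precedence over Conserved-and-Diverged, then Conserved,
#' Diverged, None.
#'
#' @param report a `conservation_report` from [classify_genes()].
#' @param map an [ortholog_map()].
#' @return data.frame (gene, n_orthologs, category).
#' @export
multi_ortholog_summary <- function(report, map) {
  tests <- report$tests
  ortho <- ortholog_table(map, report$from, report$to)
  n_ortho <- lengths(ortho[report$genes$gene])
  keep <- report$genes$gene[n_ortho >= 2]
  by_gene <- split(tests, tests$gene)
  rows <- lapply(keep, function(g) {
    tt <- by_gene[[g]]
    has_c <- any(tt$sig_conserved)
    has_d <- any(tt$sig_diverged)
    all_c <- nrow(tt) == length(ortho[[g]]) && all(tt$sig_conserved)
    cat <- if (all_c) "Uniquely conserved"
      else if (has_c && has_d) "Conserved-and-Diverged"
      else if (has_c) "Conserved"
      else if (has_d) "Diverged"
      else "None"
    data.frame(gene = g, n_orthologs = length(ortho[[g]]), category = cat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_orthologs = integer(0),
                      category = character(0))
  }
  out
}

#' Sequence similarity versus regulatory conservation
#'
#' For genes with at least two predicted orthologs, at least one
#' significantly conserved and at least one significantly diverged
#' ortholog-neighbourhood: does the most sequence-similar ortholog (highest
#' BLAST bit-score) coincide with the most conserved one (smallest
#' conserved-tail p; ties by larger overlap, higher bit-score, id), the most
#' diverged one, or neither? Genes lacking bit-scores for any ortholog are
#' excluded and counted.
#'
#' @param report a `conservation_report` from [classify_genes()].
#' @param map an [ortholog_map()] with bit-scores.
#' @return List with `fractions` (most_similar_most_conserved,
#'   most_similar_most_diverged, not_agreeing), `n_applicable`,
#'   `n_excluded`, `most_conserved` (per-gene best conserved ortholog for
#'   all genes with a significant conserved test), and `ranks` (rank of the
#'   most conserved ortholog under the bit-score ordering).
#' @export
sequence_vs_regulation <- function(report, map) {
  tests <- report$tests
  by_gene <- split(tests, tests$gene)
  # best conserved ortholog for every gene with >= 1 significant conserved test
  mc_rows <- lapply(by_gene, function(tt) {
    if (!any(tt$sig_conserved)) return(NULL)
    tt[order_most_significant(tt, "conserved")[1], c("gene", "ortholog")]
  })
  most_conserved <- do.call(rbind, mc_rows[!vapply(mc_rows, is.null, TRUE)])
  applicable <- names(by_gene)[vapply(by_gene, function(tt) {
    nrow(tt) >= 2 && any(tt$sig_conserved) && any(tt$sig_diverged)
  }, TRUE)]
  n_excluded <- 0L
  agree <- character(0)
  ranks <- integer(0)
  for (g in applicable) {
    tt <- by_gene[[g]]
    if (any(is.na(tt$bitscore))) {
      n_excluded <- n_excluded + 1L
      next
    }
    most_similar <- tt$ortholog[order(-tt$bitscore, tt$ortholog)][1]
    mc <- tt$ortholog[order_most_significant(tt, "conserved")[1]]
    md <- tt$ortholog[order_most_significant(tt, "diverged")[1]]
    cls <- if (most_similar == mc) "most_similar_most_conserved"
      else if (most_similar == md) "most_similar_most_diverged"
      else "not_agreeing"
    agree <- c(agree, cls)
    ranks <- c(ranks, match(mc, tt$ortholog[order(-tt$bitscore, tt$ortholog)]))
  }
  lv <- c("most_similar_most_conserved", "most_similar_most_diverged",
          "not_agreeing")
  fr <- if (length(agree)) table(factor(agree, levels = lv)) / length(agree) else {
    stats::setNames(rep(NA_real_, 3), lv)
  }
  list(fractions = fr, n_applicable = length(agree), n_excluded = n_excluded,
       most_conserved = most_conserved, ranks = ranks)
}

#' Neighbourhood conservation fraction for a directed comparison
#'
#' Convenience wrapper: runs all neighbourhood tests, classifies genes, and
#' returns the fraction of eligible genes with at least one significantly
#' conserved ortholog-neighbourhood (categories Conserved or
#' Conserved-and-Diverged). At thresholds so stringent that no gene remains
#' eligible, no gene has a conserved neighbourhood and the fraction is
#' reported as 0 (with `n_eligible = 0`).
#'
#' @inheritParams eligible_genes
#' @param fdr FDR level.
#' @return List with `fraction`, `n_eligible`, `n_conserved`,
#'   `n_diverged`.
#' @export
neighbourhood_conservation_fraction <- function(net1, net2, map, from, to,
                                                fdr = 0.05) {
  tst <- neighbourhood_tests(net1, net2, map, from, to)
  if (nrow(tst) == 0) {
    return(list(fraction = 0, n_eligible = 0L, n_conserved = 0L,
                n_diverged = 0L))
  }
  rep_ <- classify_genes(tst, fdr)
  n_cons <- sum(rep_$genes$category %in% c("Conserved", "Conserved-and-Diverged"))
  n_div <- sum(rep_$genes$category %in% c("Diverged", "Conserved-and-Diverged"))
  list(fraction = n_cons / nrow(rep_$genes), n_eligible = nrow(rep_$genes),
       n_conserved = n_cons, n_diverged = n_div)
}

#' Core conservation across a species trio
#'
#' For each species X with directed reports against both other species, a
#' gene is core-conserved if it has at least one significantly conserved
#' ortholog-neighbourhood in both, core-diverged correspondingly, and
#' core-both if both hold.
#'
#' @param reports named list of `conservation_report`s, names `"X->Y"`,
#'   covering all ordered pairs of at least three species.
#' @return data.frame (species, n_eligible, n_conserved, n_diverged, n_both)
#'   with attribute `core_sets`.
#' @export
core_conservation <- function(reports) {
  froms <- vapply(reports, function(r) r$from, "")
  tos <- vapply(reports, function(r) r$to, "")
  species <- unique(c(froms, tos))
  if (length(species) < 3) stop("core conservation needs at least 3 species")
  sets <- list()
  rows <- lapply(species, function(sp) {
    idx <- which(froms == sp)
    if (length(idx) < 2) return(NULL)
    per <- lapply(idx, function(i) {
      r <- reports[[i]]
      list(cons = r$genes$gene[r$genes$category %in%
                                 c("Conserved", "Conserved-and-Diverged")],
           div = r$genes$gene[r$genes$category %in%
                                c("Diverged", "Conserved-and-Diverged")],
           elig = r$genes$gene)
    })
    cons <- Reduce(intersect, lapply(per, `[[`, "cons"))
    div <- Reduce(intersect, lapply(per, `[[`, "div"))
    elig <- Reduce(intersect, lapply(per, `[[`, "elig"))
    sets[[sp]] <<- list(conserved = cons, diverged = div,
                        both = intersect(cons, div))
    data.frame(species = sp, n_eligible = length(elig),
               n_conserved = length(cons), n_diverged = length(div),
               n_both = length(intersect(cons, div)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "core_sets") <- sets
  out
}
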
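# Typed network motifs in regulation networks. Node types are TF and gene;
# permitted links are reciprocal TF-TF pairs and directed TF -> gene edges;
# genes emit no edges. Motif classes are connected typed digraphs up to
# type-preserving isomorphism, with a canonical code defined as the minimal
# adjacency bit-string over all type-preserving node permutations (TFs
# first). Counting is by connected *induced* subgraphs, each node set
# counted once, so class counts sum to the total number of connected induced
# subgraphs of that size.

# canonical code of a typed digraph: types TRUE = TF; A directed adjacency
canonical_code <- function(is_tf, A) {
  k <- length(is_tf)
  tf_idx <- which(is_tf)
  gene_idx <- which(!is_tf)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  for (pt in perms(tf_idx)) {
    for (pg in perms(gene_idx)) {
      ord <- c(pt, pg)
      code <- paste(c(length(tf_idx), A[ord, ord, drop = FALSE]), collapse = "")
      if (is.null(best) || code < best) best <- code
    }
  }
  best
}

enumerate_classes_internal <- function(size) {
  classes <- list()
  seen <- character(0)
  for (t in seq_len(size)) {
    g <- size - t
    tt_pairs <- if (t >= 2) utils::combn(t, 2) else matrix(0, 2, 0)
    n_tt <- ncol(tt_pairs)
    n_tg <- t * g
    for (mask_tt in seq_len(2^n_tt) - 1L) {
      for (mask_tg in seq_len(2^n_tg) - 1L) {
        A <- matrix(0L, size, size)
        if (n_tt > 0) {
          on <- which(bitwAnd(mask_tt, 2^(seq_len(n_tt) - 1L)) > 0)
          for (e in on) {
            A[tt_pairs[1, e], tt_pairs[2, e]] <- 1L
            A[tt_pairs[2, e], tt_pairs[1, e]] <- 1L
          }
        }
        if (n_tg > 0) {
          on <- which(bitwAnd(mask_tg, 2^(seq_len(n_tg) - 1L)) > 0)
          for (e in on) {
            tf_i <- (e - 1L) %% t + 1L
            gene_j <- t + (e - 1L) %/% t + 1L
            A[tf_i, gene_j] <- 1L
          }
        }
        und <- (A + t(A)) > 0
        gr <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
        if (!igraph::is_connected(gr)) next
        is_tf <- c(rep(TRUE, t), rep(FALSE, g))
        code <- canonical_code(is_tf, A)
        if (!code %in% seen) {
          seen <- c(seen, code)
          classes[[length(classes) + 1L]] <- list(is_tf = is_tf, adj = A,
                                                  code = code)
        }
      }
    }
  }
  ord <- order(vapply(classes, `[[`, "", "code"))
  classes <- classes[ord]
  structure(list(size = size, classes = classes,
                 codes = vapply(classes, `[[`, "", "code")),
            class = "motif_catalog")
}

#' Enumerate typed motif classes
#'
#' Exhaustively generates all connected typed directed graphs of the given
#' size over TF/gene node types under the regulation-network link semantics
#' (TF-TF reciprocal, TF -> gene directed, genes emit nothing), reduced to
#' canonical representatives under type-preserving isomorphism. Size 3
#' yields 6 classes, among them the feed-forward-loop pattern (two connected
#' TFs regulating the same gene) and, at size 4, the bi-fan.
#'
#' @param size motif size, 3 or 4.
#' @return A `motif_catalog` with elements `size`, `classes` (each with
#'   `is_tf`, `adj`, `code`) and `codes`.
#' @export
enumerate_motif_classes <- function(size) {
  if (!size %in% c(3L, 4L)) stop("motif size must be 3 or 4")
  enumerate_classes_internal(as.integer(size))
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat("Motif catalog: size", x$size, "-", length(x$classes), "classes\n")
  invisible(x)
}

# index of the FFL pattern (TF<->TF, both -> same gene) in a size-3 catalog
#' Locate a named motif pattern in a catalog
#' @param catalog a `motif_catalog`.
#' @param pattern `"ffl"` (two connected TFs regulating the same gene,
#'   size 3) or `"bifan"` (two unconnected TFs regulating the same two
#'   genes, size 4).
#' @return Integer class index.
#' @export
motif_class_index <- function(catalog, pattern = c("ffl", "bifan")) {
  pattern <- match.arg(pattern)
  if (pattern == "ffl") {
    stopifnot(catalog$size == 3)
    A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- 1L; A[1, 3] <- A[2, 3] <- 1L
    code <- canonical_code(c(TRUE, TRUE, FALSE), A)
  } else {
    stopifnot(catalog$size == 4)
    A <- matrix(0L, 4, 4); A[1, 3] <- A[1, 4] <- A[2, 3] <- A[2, 4] <- 1L
    code <- canonical_code(c(TRUE, TRUE, FALSE, FALSE), A)
  }
  match(code, catalog$codes)
}

# ESU enumeration of connected induced subgraphs of size k.
# adj: list of integer neighbour vectors (undirected skeleton), 1..n.
esu_subgraphs <- function(adj, n, k, callback) {
  extend <- function(sub, ext, v) {
    if (length(sub) == k) {
      callback(sub)
      return(invisible(NULL))
    }
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      excl <- unique(unlist(adj[sub], use.names = FALSE))
      new_ext <- setdiff(adj[[w]], c(excl, sub))
      new_ext <- new_ext[new_ext > v]
      extend(c(sub, w), unique(c(ext, new_ext)), v)
    }
  }
  for (v in seq_len(n)) {
    ext0 <- adj[[v]][adj[[v]] > v]
    if (length(ext0) > 0 || k == 1) extend(v, ext0, v)
  }
  invisible(NULL)
}

#' Count motif occurrences in a regulation network
#'
#' Counts connected induced typed subgraphs of the catalog's size in the
#' regulation view (optionally restricted to the induced subnetwork on a
#' node subset). Each node set is counted exactly once, in the class its
#' induced typed subgraph belongs to.
#'
#' @param net a `gene_network`.
#' @param catalog a `motif_catalog` from [enumerate_motif_classes()].
#' @param nodes optional node subset; all must be present in the network.
#' @return Named integer vector of counts per class code.
#' @export
count_motifs <- function(net, catalog, nodes = NULL) {
  re <- net$reg_edges
  verts <- net$nodes$gene
  if (!is.null(nodes)) {
    if (!all(nodes %in% verts)) stop("node subset contains unknown genes")
    keep <- re$from %in% nodes & re$to %in% nodes
    re <- re[keep, , drop = FALSE]
    verts <- nodes
  }
  counts <- stats::setNames(integer(length(catalog$codes)), catalog$codes)
  if (nrow(re) == 0) return(counts)
  idx <- stats::setNames(seq_along(verts), verts)
  fi <- idx[re$from]; ti <- idx[re$to]
  n <- length(verts)
  # undirected skeleton adjacency + directed adjacency set
  und <- unique(data.frame(a = pmin(fi, ti), b = pmax(fi, ti)))
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  sp <- split(c(und$b, und$a), c(und$a, und$b))
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  dir_env <- new.env(parent = emptyenv())
  for (e in seq_along(fi)) assign(paste(fi[e], ti[e]), TRUE, dir_env)
  is_tf_all <- stats::setNames(net$nodes$tf, net$nodes$gene)[verts]
  k <- catalog$size
  esu_subgraphs(adj, n, k, function(sub) {
    A <- matrix(0L, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j && !is.null(dir_env[[paste(sub[i], sub[j])]])) A[i, j] <- 1L
      }
    }
    code <- canonical_code(unname(is_tf_all[sub]), A)
    pos <- match(code, catalog$codes)
    if (is.na(pos)) stop("unclassifiable induced subgraph; catalog incomplete")
    counts[pos] <<- counts[pos] + 1L
  })
  counts
}

#' Degree-preserving randomization of a regulation network
#'
#' Rewires the TF -> gene stratum with bipartite double-edge swaps
#' (preserving every TF's out-degree and every gene's in-degree) and the
#' TF-TF stratum as an undirected graph (preserving TF-TF degrees),
#' avoiding self-loops and multi-edges. 10 x |E| swap attempts per stratum.
#' Strata with fewer than 2 edges are returned unchanged with a warning.
#' Degree preservation is asserted on every draw.
#'
#' @param net a `gene_network`.
#' @param seed RNG seed.
#' @param swap_factor swap attempts per edge (default 10).
#' @return A `gene_network` whose regulation view is rewired; its undirected
#'   edge set is the skeleton of the rewired regulation edges.
#' @export
randomize_regulation_network <- function(net, seed = 1L, swap_factor = 10L) {
  is_tf <- stats::setNames(net$nodes$tf, net$nodes$gene)
  re <- net$reg_edges
  tt <- re[is_tf[re$from] & is_tf[re$to], , drop = FALSE]
  tg <- re[is_tf[re$from] & !is_tf[re$to], , drop = FALSE]
  # undirected TF-TF pairs
  if (nrow(tt) > 0) {
    ttu <- unique(data.frame(a = pmin(tt$from, tt$to),
                             b = pmax(tt$from, tt$to),
                             stringsAsFactors = FALSE))
  } else {
    ttu <- data.frame(a = character(0), b = character(0))
  }
  with_seed(seed, {
    # bipartite stratum
    if (nrow(tg) >= 2) {
      from <- tg$from; to <- tg$to
      exists <- new.env(parent = emptyenv())
      for (i in seq_len(nrow(tg))) assign(paste(from[i], to[i]), TRUE, exists)
      n_att <- swap_factor * nrow(tg)
      for (s in seq_len(n_att)) {
        ij <- sample.int(nrow(tg), 2)
        i <- ij[1]; j <- ij[2]
        if (from[i] == from[j] || to[i] == to[j]) next
        k1 <- paste(from[i], to[j]); k2 <- paste(from[j], to[i])
        if (!is.null(exists[[k1]]) || !is.null(exists[[k2]])) next
        rm(list = c(paste(from[i], to[i]), paste(from[j], to[j])), envir = exists)
        tmp <- to[i]; to[i] <- to[j]; to[j] <- tmp
        assign(paste(from[i], to[i]), TRUE, exists)
        assign(paste(from[j], to[j]), TRUE, exists)
      }
      tg_new <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    } else {
      if (nrow(tg) > 0) warning("TF->gene stratum too small to rewire; returned unchanged")
      tg_new <- tg
    }
    # TF-TF stratum (undirected)
    if (nrow(ttu) >= 2) {
      a <- ttu$a; b <- ttu$b
      exists <- new.env(parent = emptyenv())
      for (i in seq_len(nrow(ttu))) assign(edge_key(a[i], b[i]), TRUE, exists)
      n_att <- swap_factor * nrow(ttu)
      for (s in seq_len(n_att)) {
        ij <- sample.int(nrow(ttu), 2)
        i <- ij[1]; j <- ij[2]
        if (stats::runif(1) < 0.5) { tmp <- a[j]; a[j] <- b[j]; b[j] <- tmp }
        # propose (a_i, b_j), (a_j, b_i)
        if (a[i] == b[j] || a[j] == b[i]) next
        k1 <- edge_key(a[i], b[j]); k2 <- edge_key(a[j], b[i])
        if (!is.null(exists[[k1]]) || !is.null(exists[[k2]])) next
        rm(list = c(edge_key(a[i], b[i]), edge_key(a[j], b[j])), envir = exists)
        tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
        assign(edge_key(a[i], b[i]), TRUE, exists)
        assign(edge_key(a[j], b[j]), TRUE, exists)
      }
      tt_new <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
    } else {
      if (nrow(ttu) > 0) warning("TF-TF stratum too small to rewire; returned unchanged")
      tt_new <- ttu
    }
    out <- new_gene_network(net$nodes$gene,
                            from = c(tg_new$from, tt_new$a),
                            to = c(tg_new$to, tt_new$b),
                            score = rep(NA_real_, nrow(tg_new) + nrow(tt_new)),
                            tf_ids = net$nodes$gene[net$nodes$tf],
                            threshold = net$threshold)
    # degree preservation assertions (per draw)
    deg_tab <- function(e) {
      list(out = table(factor(e$from, levels = net$nodes$gene)),
           inn = table(factor(e$to, levels = net$nodes$gene)))
    }
    d0 <- deg_tab(net$reg_edges); d1 <- deg_tab(out$reg_edges)
    stopifnot(identical(as.vector(d0$out), as.vector(d1$out)),
              identical(as.vector(d0$inn), as.vector(d1$inn)))
    out
  })
}

#' Motif enrichment Z-scores in GO subnetworks
#'
#' For every eligible GO term (10-1000 connected annotated genes) and every
#' motif class, the observed induced-subgraph count is compared with counts
#' on the induced subgraph of the same gene set in `n_rand` degree-preserving
#' randomized networks: Z = (obs - mean_rand) / sd_rand, `NA` when sd_rand
#' is 0. With `go = NULL` a single global census is scored instead.
#'
#' @param net a `gene_network`.
#' @param go data.frame (gene, term) or `NULL` for the global mode.
#' @param catalog a `motif_catalog`.
#' @param n_rand number of randomized networks (default 100).
#' @param seed RNG seed.
#' @param min_genes,max_genes GO eligibility bounds.
#' @return data.frame (term, class_code, observed, rand_mean, rand_sd, z).
#' @export
motif_zscores <- function(net, go, catalog, n_rand = 100L, seed = 1L,
                          min_genes = 10L, max_genes = 1000L) {
  if (is.null(go)) {
    gene_sets <- list(global = NULL)
  } else {
    conn <- connected_genes(net)
    go <- go[go$gene %in% conn, , drop = FALSE]
    gene_sets <- lapply(split(go$gene, go$term), unique)
    gene_sets <- gene_sets[lengths(gene_sets) >= min_genes &
                             lengths(gene_sets) <= max_genes]
  }
  ncls <- length(catalog$codes)
  obs <- vapply(gene_sets, function(gs) count_motifs(net, catalog, gs),
                integer(ncls))
  obs <- matrix(obs, nrow = ncls,
                dimnames = list(catalog$codes, names(gene_sets)))
  sum1 <- matrix(0, ncls, length(gene_sets))
  sum2 <- matrix(0, ncls, length(gene_sets))
  for (r in seq_len(n_rand)) {
    rnet <- suppressWarnings(
      randomize_regulation_network(net, seed = child_seed(seed, paste0("rw", r))))
    cc <- vapply(gene_sets, function(gs) count_motifs(rnet, catalog, gs),
                 integer(ncls))
    cc <- matrix(cc, nrow = ncls)
    sum1 <- sum1 + cc
    sum2 <- sum2 + cc^2
  }
  mu <- sum1 / n_rand
  vr <- pmax(0, sum2 / n_rand - mu^2) * n_rand / max(1, n_rand - 1)
  sdv <- sqrt(vr)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  data.frame(
    term = rep(colnames(obs), each = ncls),
    class_code = rep(catalog$codes, times = ncol(obs)),
    observed = as.vector(obs), rand_mean = as.vector(mu),
    rand_sd = as.vector(sdv), z = as.vector(z),
    stringsAsFactors = FALSE
  )
}

#' Cross-species conserved motifs
#'
#' A GO term is conserved for a motif class if its enrichment Z-score ranks
#' in the top `top_fraction` of eligible terms in every species. Empirical
#' significance by randomized term lists, as for subnetwork statistics.
#'
#' @param stats_list named list (by species) of [motif_zscores()] tables with
#'   a shared GO vocabulary.
#' @param top_fraction rank fraction (default 0.20).
#' @param n_rand randomized lists.
#' @param seed RNG seed.
#' @return data.frame (class_code, n_conserved, p) plus attribute
#'   `conserved_terms` (named list per class).
#' @export
conserved_motifs <- function(stats_list, top_fraction = 0.20, n_rand = 1000L,
                             seed = 1L) {
  if (length(stats_list) < 2) stop("need motif statistics for >= 2 species")
  codes <- sort(unique(stats_list[[1]]$class_code))
  res <- list()
  terms_by_class <- list()
  for (ci in seq_along(codes)) {
    cls <- codes[ci]
    per_sp <- lapply(stats_list, function(s) {
      s <- s[s$class_code == cls & !is.na(s$z), , drop = FALSE]
      s
    })
    tops <- lapply(per_sp, function(s) {
      top_fraction_ids(s$term, s$z, top_fraction, "top")
    })
    conserved <- Reduce(intersect, tops)
    observed <- length(conserved)
    if (all(vapply(tops, length, 0L) == 0)) {
      p <- NA_real_
    } else {
      r <- 0L
      with_seed(child_seed(seed, cls), {
        for (i in seq_len(n_rand)) {
          rand_sets <- lapply(per_sp, function(s) {
            if (nrow(s) == 0) return(character(0))
            sample(s$term, min(ceiling(top_fraction * nrow(s)), nrow(s)))
          })
          if (length(Reduce(intersect, rand_sets)) >= observed) r <- r + 1L
        }
      })
      p <- empirical_p(r, n_rand)
    }
    res[[ci]] <- data.frame(class_code = cls, n_conserved = observed, p = p,
                            stringsAsFactors = FALSE)
    terms_by_class[[cls]] <- conserved
  }
  out <- do.call(rbind, res)
  attr(out, "conserved_terms") <- terms_by_class
  out
}
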
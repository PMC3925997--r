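# Independent oracle implementations used to validate the package's
# estimators. These deliberately share no code with the implementation
# paths they check.

# Hard-binned histogram plugin MI, normalized by the minimum marginal
# entropy. Equal-width bins on rank-scaled values, matching the B-spline
# estimator's rank scaling so that spline_order = 1 must agree exactly.
hist_mi_oracle <- function(x, y, n_bins) {
  bin_of <- function(v) {
    r <- rank(v, ties.method = "average")
    if (max(r) == min(r)) return(rep(1L, length(v)))
    z <- (r - 1) / (length(v) - 1) * n_bins
    pmin(floor(pmin(z, n_bins - 1e-9)) + 1L, n_bins)
  }
  bx <- bin_of(x); by <- bin_of(y)
  joint <- table(factor(bx, levels = 1:n_bins), factor(by, levels = 1:n_bins))
  p <- joint / length(x)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- ent(rowSums(p)); hy <- ent(colSums(p))
  if (min(hx, hy) < 1e-12) return(0)
  mi <- hx + hy - ent(p)
  min(1, max(0, mi / min(hx, hy)))
}

# Exact hypergeometric tails by direct combinatorial summation.
hyper_oracle <- function(N, n, k, x) {
  support <- 0:min(n, k)
  pmf <- choose(k, support) * choose(N - k, n - support) / choose(N, n)
  if (min(n, k) == 0 || sum(pmf) == 0) pmf <- c(1, rep(0, length(support) - 1))
  c(upper = sum(pmf[support >= x]), lower = sum(pmf[support <= x]))
}

# Brute-force betweenness on a small undirected graph given as an edge
# data.frame (from, to) over vertices 1..n: BFS distances, shortest-path
# counts by dynamic programming, pair-dependency summation.
betweenness_oracle <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dist <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d + 1) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- unique(nxt); d <- d + 1
    }
  }
  bt <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bt
}

# Exhaustive induced-subgraph motif census: every k-subset of nodes, keep
# weakly connected induced regulation subgraphs, classify by canonical code.
motif_census_oracle <- function(net, catalog) {
  verts <- net$nodes$gene
  is_tf <- stats::setNames(net$nodes$tf, verts)
  re <- net$reg_edges
  dir_env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(re))) assign(paste(re$from[i], re$to[i]), TRUE, dir_env)
  k <- catalog$size
  counts <- stats::setNames(integer(length(catalog$codes)), catalog$codes)
  for (sub in utils::combn(verts, k, simplify = FALSE)) {
    A <- matrix(0L, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j && !is.null(dir_env[[paste(sub[i], sub[j])]])) A[i, j] <- 1L
    }
    und <- (A + t(A)) > 0
    # connectivity by reachability expansion
    reach <- 1L
    repeat {
      new <- unique(c(reach, which(colSums(und[reach, , drop = FALSE]) > 0)))
      if (length(new) == length(reach)) break
      reach <- new
    }
    if (length(reach) < k) next
    code <- comparex:::canonical_code(unname(is_tf[sub]), A)
    counts[code] <- counts[code] + 1L
  }
  counts
}

# Random valid regulation network for motif tests: TFs and genes, random
# reciprocal TF-TF pairs and TF->gene edges.
random_regulation_network <- function(n_nodes, n_tf, p_tt, p_tg, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_nodes))
  tfs <- genes[seq_len(n_tf)]
  others <- setdiff(genes, tfs)
  from <- character(0); to <- character(0)
  if (n_tf >= 2) {
    prs <- utils::combn(tfs, 2)
    keep <- stats::runif(ncol(prs)) < p_tt
    from <- c(from, prs[1, keep]); to <- c(to, prs[2, keep])
  }
  for (tf in tfs) {
    keep <- others[stats::runif(length(others)) < p_tg]
    from <- c(from, rep(tf, length(keep))); to <- c(to, keep)
  }
  comparex:::new_gene_network(genes, from, to, rep(1, length(from)),
                              tf_ids = tfs, threshold = 1)
}

# Shared expensive fixtures, built lazily and memoized for the test run.
.fixture_env <- new.env()

recovery_fixture <- function() {
  if (is.null(.fixture_env$recovery)) {
    spec <- scenario_spec(species_names = c("ath", "pop"), seed = 11)
    study <- simulate_study(spec)
    clrs <- lapply(study$expression, function(e) clr_transform(mi_matrix(e)))
    nets2 <- lapply(names(clrs), function(sp) {
      build_network(clrs[[sp]], 2, study$tfs[[sp]])
    })
    names(nets2) <- names(clrs)
    .fixture_env$recovery <- list(spec = spec, study = study, clrs = clrs,
                                  nets2 = nets2)
  }
  .fixture_env$recovery
}

toy_study <- function(seed = 3, species = c("ath", "pop")) {
  key <- paste0("toy", seed, paste(species, collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    spec <- scenario_spec(species_names = species, n_genes = 80,
                          n_samples = 50, n_modules = 2,
                          module_size_range = c(15, 25), seed = seed)
    .fixture_env[[key]] <- list(spec = spec, study = simulate_study(spec))
  }
  .fixture_env[[key]]
}
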
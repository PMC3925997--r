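test_that("degree fits separate preferential-attachment from Erdos-Renyi graphs", {
  set.seed(31)
  d_pa <- igraph::degree(igraph::sample_pa(2000, m = 2, directed = FALSE))
  fit_pa <- fit_degree_distribution(d_pa)
  expect_identical(fit_pa$classification, "scale_free")
  expect_gt(fit_pa$alpha, 1.5)

  d_er <- igraph::degree(igraph::sample_gnp(2000, 0.005))
  fit_er <- fit_degree_distribution(d_er)
  expect_identical(fit_er$classification, "random")
  expect_equal(fit_er$lambda, mean(d_er[d_er > 0]))

  d_ring <- igraph::degree(igraph::make_ring(100))
  expect_identical(fit_degree_distribution(d_ring)$classification,
                   "indeterminate")
  expect_error(fit_degree_distribution(rep(3, 10)), "at least 50")
})

test_that("power-law exponent agrees with igraph's independent MLE", {
  set.seed(32)
  d <- igraph::degree(igraph::sample_pa(3000, m = 3, directed = FALSE))
  ours <- fit_degree_distribution(d)
  theirs <- igraph::fit_power_law(d[d >= ours$xmin], xmin = ours$xmin,
                                  implementation = "plfit")
  expect_equal(ours$alpha, theirs$alpha, tolerance = 0.05)
})

test_that("centralities on toy graphs match known values", {
  net <- comparex:::new_gene_network(c("A", "B", "C"),
                                    from = c("A", "B"), to = c("B", "C"),
                                    score = c(1, 1), tf_ids = character(0),
                                    threshold = 1)
  ct <- compute_centralities(net)
  row <- function(g) ct[ct$gene == g, ]
  expect_identical(ct$degree, c(1, 2, 1))
  expect_equal(row("B")$avnn, 1)
  expect_equal(row("A")$avnn, 2)
  expect_gt(row("B")$betweenness, row("A")$betweenness)
  expect_equal(row("A")$betweenness, 0)

  leaves <- paste0("L", 1:5)
  star <- comparex:::new_gene_network(c("h", leaves),
                                     from = rep("h", 5), to = leaves,
                                     score = rep(1, 5),
                                     tf_ids = character(0), threshold = 1)
  cs <- compute_centralities(star)
  expect_equal(cs$avnn[cs$gene == "h"], 1)
  expect_true(all(cs$avnn[cs$gene != "h"] == 5))
})

test_that("betweenness equals all-pairs brute force on random graphs", {
  for (s in 1:5) {
    set.seed(40 + s)
    n <- 12
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < 0.25
    edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep])
    genes <- sprintf("v%02d", 1:n)
    net <- comparex:::new_gene_network(genes, genes[edges$from],
                                      genes[edges$to],
                                      rep(1, nrow(edges)),
                                      character(0), 1)
    ct <- compute_centralities(net)
    oracle <- betweenness_oracle(edges, n)
    expect_equal(ct$betweenness[match(genes, ct$gene)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("regulation-view centralities use in/out degree by node role", {
  # T1 <-> T2, T1 -> G1, T1 -> G2, T2 -> G1
  net <- comparex:::new_gene_network(
    c("T1", "T2", "G1", "G2"),
    from = c("T1", "T1", "T1", "T2"),
    to = c("T2", "G1", "G2", "G1"),
    score = rep(1, 4), tf_ids = c("T1", "T2"), threshold = 1)
  ct <- compute_centralities(net, view = "regulation")
  row <- function(g) ct[ct$gene == g, ]
  expect_equal(row("T1")$degree, 3)  # out: T2, G1, G2
  expect_equal(row("T2")$degree, 2)  # out: T1, G1
  expect_equal(row("G1")$degree, 2)  # in: T1, T2
  expect_equal(row("G2")$degree, 1)
  # avnn of G1 averages rule-degree of its in-neighbours T1 (3) and T2 (2)
  expect_equal(row("G1")$avnn, 2.5)
  # avnn of T1 averages out-neighbours T2 (2), G1 (2), G2 (1)
  expect_equal(row("T1")$avnn, 5 / 3)
})

test_that("centrality conservation is exact on identical networks and null on shuffled maps", {
  st <- toy_study(seed = 12)$study
  clr <- clr_transform(mi_matrix(st$expression$ath))
  net <- build_network(clr, 1.5, st$tfs$ath)
  ct <- compute_centralities(net)
  genes <- ct$gene
  members <- data.frame(group = paste0("G", seq_along(genes)),
                        species = "s1", gene = genes)
  members2 <- members; members2$species <- "s2"
  idmap <- ortholog_map(rbind(members, members2))
  res <- centrality_conservation(list(s1 = ct, s2 = ct), idmap,
                                 measure = "degree", n_rand = 200, seed = 1)
  expect_equal(res$fraction_conserved, 1.0)
  expect_lt(res$p, 0.05)

  # shuffled ortholog map destroys the signal
  set.seed(99)
  members2$gene <- sample(members2$gene)
  shufmap <- ortholog_map(rbind(members, members2))
  res2 <- centrality_conservation(list(s1 = ct, s2 = ct), shufmap,
                                  measure = "degree", n_rand = 200, seed = 1)
  expect_gt(res2$p, 0.05)

  # a top gene with no ortholog is never conserved
  members3 <- members2[members2$gene != res$conserved[1], ]
  partmap <- ortholog_map(rbind(members, members3))
  res3 <- centrality_conservation(list(s1 = ct, s2 = ct), partmap,
                                  measure = "degree", n_rand = 100, seed = 1)
  expect_false(res$conserved[1] %in% res3$conserved)
})

test_that("subnetwork statistics implement the density and connectivity ratios", {
  tri <- comparex:::new_gene_network(
    c("a", "b", "c", "d"), from = c("a", "a", "b"), to = c("b", "c", "c"),
    score = rep(1, 3), tf_ids = character(0), threshold = 1)
  go <- data.frame(gene = c("a", "b", "c"), term = rep("GO:1", 3))
  s <- subnetwork_statistics(tri, go, min_genes = 3)
  expect_equal(s$density, 1.0)
  expect_equal(s$connectivity, 0)

  pair <- comparex:::new_gene_network(
    c("A", "B", "C"), from = c("A", "A"), to = c("B", "C"),
    score = c(1, 1), tf_ids = character(0), threshold = 1)
  go2 <- data.frame(gene = c("A", "B"), term = rep("GO:2", 2))
  s2 <- subnetwork_statistics(pair, go2, min_genes = 2)
  expect_equal(s2$density, 1.0)
  expect_equal(s2$connectivity, 1.0)

  # 10-gene term with 18 internal links: density 18/45
  set.seed(5)
  genes <- sprintf("g%02d", 1:12)
  prs <- utils::combn(genes[1:10], 2)
  sel <- sample(ncol(prs), 18)
  netd <- comparex:::new_gene_network(genes, prs[1, sel], prs[2, sel],
                                     rep(1, 18), character(0), 1)
  go3 <- data.frame(gene = genes[1:10], term = "GO:3")
  s3 <- subnetwork_statistics(netd, go3)
  expect_equal(s3$density, 18 / 45)

  # terms outside the connected-gene bounds are excluded
  s4 <- subnetwork_statistics(netd, go3, min_genes = 11)
  expect_identical(nrow(s4), 0L)
})

test_that("statistic conservation: identity, independence, and relabeling invariance", {
  terms <- sprintf("GO:%03d", 1:100)
  tab <- data.frame(term = terms, n_genes = 50, density = seq(1, 0.01, length.out = 100),
                    connectivity = 1, ingoing_connectivity = 1,
                    outgoing_connectivity = 1)
  res <- statistic_conservation(list(a = tab, b = tab, c = tab),
                                "density", n_rand = 200, seed = 2)
  expect_identical(sort(res$conserved),
                   sort(top_fraction_ids <- tab$term[order(-tab$density, tab$term)][1:10]))
  expect_lt(res$p, 0.05)

  # independently permuted rankings: expected conserved ~ f^3 * N = 0.1
  set.seed(77)
  counts <- replicate(40, {
    tabs <- lapply(1:3, function(i) {
      t2 <- tab; t2$density <- sample(t2$density); t2
    })
    names(tabs) <- c("a", "b", "c")
    length(statistic_conservation(tabs, "density", n_rand = 0 + 100,
                                  seed = 3)$conserved)
  })
  expect_lt(mean(counts), 1.0)

  # empty eligible set reports NA
  empty <- tab[0, ]
  expect_true(is.na(statistic_conservation(list(a = empty, b = empty),
                                           "density", n_rand = 100,
                                           seed = 1)$p))

  # invariance to term relabeling (consistent across species)
  perm <- sample(terms)
  relab <- stats::setNames(perm, terms)
  tabs_r <- lapply(list(a = tab, b = tab, c = tab), function(t2) {
    t2$term <- unname(relab[t2$term]); t2
  })
  res_r <- statistic_conservation(tabs_r, "density", n_rand = 200, seed = 2)
  expect_setequal(res_r$conserved, unname(relab[res$conserved]))
})

test_that("tau scores follow the tissue-specificity formula", {
  m <- rbind(spec1 = c(0, 0, 0, 5),
             flat = c(3, 3, 3, 3),
             mid = c(1, 0.5, 0, 0),
             zero = c(0, 0, 0, 0),
             neg = c(-1, -2, 4, 4))
  colnames(m) <- paste0("s", 1:4)
  em <- expression_matrix(m, "x")
  tau <- tau_scores(em, tissue = paste0("t", 1:4))
  val <- function(g) tau$tau[tau$gene == g]
  expect_equal(val("spec1"), 1.0)
  expect_equal(val("flat"), 0.0)
  expect_equal(val("mid"), (0 + 0.5 + 1 + 1) / 3)
  expect_true(is.na(val("zero")))
  expect_equal(val("neg"), (1 + 1 + 0 + 0) / 3)  # negatives floored at 0
  expect_error(tau_scores(em, tissue = rep("t1", 4)), "2 tissues")
  # (1, 0.5, 0) over three tissues
  m2 <- rbind(g = c(1, 0.5, 0)); colnames(m2) <- paste0("s", 1:3)
  expect_equal(tau_scores(expression_matrix(m2), paste0("t", 1:3))$tau, 0.75)
})

test_that("GO enrichment matches the exact hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  go <- data.frame(gene = universe[1:5], term = "GO:A")
  res <- go_enrichment(universe[1:5], universe, go, correction = "bonferroni")
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_adjusted, min(1, res$p * nrow(res)))

  go2 <- rbind(go, data.frame(gene = universe[6:10], term = "GO:B"))
  res2 <- go_enrichment(universe[1:5], universe, go2, correction = "bh")
  expect_equal(res2$p[res2$term == "GO:B"], 1)
  expect_error(go_enrichment(character(0), universe, go), "empty")
  expect_error(go_enrichment(c("zz"), universe, go), "subset")
})
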
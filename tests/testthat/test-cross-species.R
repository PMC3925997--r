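# small helpers to build networks and maps from literal edge lists
mknet <- function(genes, from, to, tfs = character(0)) {
  comparex:::new_gene_network(genes, from, to, rep(1, length(from)), tfs, 1)
}
mkmap <- function(...) {
  # mkmap("A1" = c("P1","P2"), ...): species "s1" genes mapping to "s2" genes
  pairs <- list(...)
  members <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    rbind(data.frame(group = paste0("G", i), species = "s1",
                     gene = names(pairs)[i]),
          data.frame(group = paste0("G", i), species = "s2",
                     gene = pairs[[i]]))
  }))
  ortholog_map(members)
}

test_that("hypergeometric tails match exact enumeration on small universes", {
  for (N in c(5, 9, 12)) {
    for (n in 0:N) {
      for (k in 0:N) {
        for (x in 0:min(n, k)) {
          o <- hyper_oracle(N, n, k, x)
          p <- comparex:::hyper_tails(N, n, k, x)
          expect_equal(unname(p["p_conserved"]), unname(o["upper"]),
                       tolerance = 1e-12)
          expect_equal(unname(p["p_diverged"]), unname(o["lower"]),
                       tolerance = 1e-12)
          expect_gte(sum(p), 1)   # tails share the point mass at x
        }
      }
    }
  }
})

test_that("neighbourhood test reproduces the worked tail values", {
  genes1 <- c("A", paste0("n", 1:5), paste0("f", 1:14))   # N = 20
  genes2 <- c("Ap", paste0("m", 1:5), paste0("h", 1:14))
  members <- rbind(
    data.frame(group = "G0", species = "s1", gene = "A"),
    data.frame(group = "G0", species = "s2", gene = "Ap"),
    data.frame(group = paste0("K", 1:5), species = "s1", gene = paste0("n", 1:5)),
    data.frame(group = paste0("K", 1:5), species = "s2", gene = paste0("m", 1:5)))
  map <- ortholog_map(members)
  # full overlap: A's 5 neighbours are exactly the mapped neighbours of Ap
  net1 <- mknet(genes1, rep("A", 5), paste0("n", 1:5))
  net2 <- mknet(genes2, rep("Ap", 5), paste0("m", 1:5))
  t1 <- neighbourhood_test("A", "Ap", net1, net2, map, "s1", "s2")
  expect_identical(c(t1$N, t1$n, t1$k, t1$x), c(20L, 5L, 5L, 5L))
  expect_equal(t1$p_conserved, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap: neighbours of A are f-genes with no orthologs
  net1b <- mknet(genes1, rep("A", 5), paste0("f", 1:5))
  t2 <- neighbourhood_test("A", "Ap", net1b, net2, map, "s1", "s2")
  expect_identical(t2$x, 0L)
  expect_equal(t2$p_conserved, 1)
  expect_equal(t2$p_diverged, choose(15, 5) / choose(20, 5), tolerance = 1e-12)

  # no mappable neighbours: k = 0 degenerate distribution
  net2b <- mknet(genes2, rep("Ap", 3), paste0("h", 1:3))
  t3 <- neighbourhood_test("A", "Ap", net1b, net2b, map, "s1", "s2")
  expect_identical(t3$k, 0L)
  expect_equal(t3$p_conserved, 1)
  expect_equal(t3$p_diverged, 1)

  expect_error(neighbourhood_test("A", "m1", net1, net2, map, "s1", "s2"),
               "not a predicted ortholog")
})

test_that("eligibility requires connectivity on both sides of the map", {
  map <- mkmap(A = "Ap", B = "Bp", C = "Cp")
  net1 <- mknet(c("A", "B", "C", "D"), c("A", "B"), c("B", "D"))
  net2 <- mknet(c("Ap", "Bp", "Cp"), "Ap", "Bp")
  elig <- eligible_genes(net1, net2, map, "s1", "s2")
  expect_setequal(elig, c("A", "B"))   # C isolated in s1, D unmapped
  # ortholog isolated in s2 -> excluded
  net2b <- mknet(c("Ap", "Bp", "Cp"), "Bp", "Cp")
  expect_setequal(eligible_genes(net1, net2b, map, "s1", "s2"), "B")
  # identity comparison: all connected genes eligible
  expect_setequal(eligible_genes(net1, net1,
                                 mkmap(A = "A", B = "B", C = "C", D = "D"),
                                 "s1", "s2"),
                  c("A", "B", "D"))
})

test_that("link conservation follows the any-ortholog-pair rule", {
  idmap <- mkmap(A = "A", B = "B", C = "C")
  net <- mknet(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  expect_equal(link_conservation(net, net, idmap, "s1", "s2")$fraction, 1.0)

  # A-B conserved through the second ortholog of A only
  map2 <- mkmap(A = c("A1p", "A2p"), B = "Bp")
  net1 <- mknet(c("A", "B"), "A", "B")
  net2 <- mknet(c("A1p", "A2p", "Bp"), "A2p", "Bp")
  lc <- link_conservation(net1, net2, map2, "s1", "s2")
  expect_equal(lc$fraction, 1.0)

  # disjoint edge sets among mutually eligible genes
  net1c <- mknet(c("A", "B", "C", "D"), c("A", "C"), c("B", "D"))
  net2c <- mknet(c("A", "B", "C", "D"), c("A", "B"), c("C", "D"))
  map4 <- mkmap(A = "A", B = "B", C = "C", D = "D")
  expect_equal(link_conservation(net1c, net2c, map4, "s1", "s2")$fraction, 0)

  # no eligible links -> NA
  net_iso <- mknet(c("A", "B"), character(0), character(0))
  expect_true(is.na(link_conservation(net_iso, net, idmap, "s1", "s2")$fraction))
})

test_that("name-shuffled null fractions are valid and reproducible", {
  st <- toy_study(seed = 21)$study
  clrs <- lapply(st$expression, function(e) clr_transform(mi_matrix(e)))
  n1 <- build_network(clrs$ath, 1.5, st$tfs$ath)
  n2 <- build_network(clrs$pop, 1.5, st$tfs$pop)
  nulls <- randomized_link_conservation(n1, n2, st$orthologs, "ath", "pop",
                                        n_rand = 15, seed = 9)
  expect_length(nulls, 15)
  expect_true(all(nulls[!is.na(nulls)] >= 0 & nulls[!is.na(nulls)] <= 1))
  nulls2 <- randomized_link_conservation(n1, n2, st$orthologs, "ath", "pop",
                                         n_rand = 15, seed = 9)
  expect_identical(nulls, nulls2)
  expect_error(randomized_link_conservation(n1, n2, st$orthologs, "ath",
                                            "pop", n_rand = 5), ">= 10")
})

# construct a test table directly to exercise the classification rules
fake_tests <- function(df) {
  df$N <- 100L; df$n <- 10L; df$k <- 10L
  df$x <- 0L
  df$bitscore <- df$bitscore %||% NA_real_
  attr(df, "from") <- "s1"; attr(df, "to") <- "s2"
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene categories follow the two-family FDR rules", {
  tests <- fake_tests(data.frame(
    gene = c("g1", "g2", "g2", "g3", "g4"),
    ortholog = c("o1", "o2a", "o2b", "o3", "o4"),
    p_conserved = c(1e-8, 1e-8, 1, 1, 0.9),
    p_diverged = c(1, 1, 1e-8, 1e-8, 0.8)))
  rep_ <- classify_genes(tests, fdr = 0.05)
  cat_of <- stats::setNames(rep_$genes$category, rep_$genes$gene)
  expect_identical(unname(cat_of["g1"]), "Conserved")
  expect_identical(unname(cat_of["g2"]), "Conserved-and-Diverged")
  expect_identical(unname(cat_of["g3"]), "Diverged")
  expect_identical(unname(cat_of["g4"]), "None")
  expect_error(classify_genes(tests[0, ]), "empty")
  # categories are exclusive and exhaustive
  expect_identical(sum(rep_$counts), nrow(rep_$genes))
})

test_that("reciprocal classification keeps only mutual best pairs", {
  # 1:1 significant mutual best: reciprocal equals plain classification
  t12 <- fake_tests(data.frame(gene = "A", ortholog = "P",
                               p_conserved = 1e-9, p_diverged = 1))
  t21 <- fake_tests(data.frame(gene = "P", ortholog = "A",
                               p_conserved = 1e-9, p_diverged = 1))
  r <- reciprocal_classify(t12, t21, fdr = 0.05)
  expect_identical(r$genes$category, "Conserved")

  # two paralogs both best-matching the same gene: at most one reciprocal
  t12b <- fake_tests(data.frame(
    gene = c("Pa", "Pb"), ortholog = c("A", "A"),
    p_conserved = c(1e-9, 1e-7), p_diverged = c(1, 1)))
  t21b <- fake_tests(data.frame(
    gene = c("A", "A"), ortholog = c("Pa", "Pb"),
    p_conserved = c(1e-9, 1e-7), p_diverged = c(1, 1)))
  rb <- reciprocal_classify(t12b, t21b, fdr = 0.05)
  expect_identical(sum(rb$genes$category == "Conserved"), 1L)
  expect_identical(rb$genes$category[rb$genes$gene == "Pb"], "None")

  # reciprocal conserved count never exceeds the plain count
  st <- recovery_fixture()
  t_ap <- neighbourhood_tests(st$nets2$ath, st$nets2$pop, st$study$orthologs,
                              "ath", "pop")
  t_pa <- neighbourhood_tests(st$nets2$pop, st$nets2$ath, st$study$orthologs,
                              "pop", "ath")
  plain <- classify_genes(t_ap, 0.05)
  recip <- reciprocal_classify(t_ap, t_pa, 0.05)
  n_plain <- sum(plain$counts[c("Conserved", "Conserved-and-Diverged")])
  n_recip <- sum(recip$counts[c("Conserved", "Conserved-and-Diverged")])
  expect_lte(n_recip, n_plain)
  expect_gt(n_recip, 0)
})

test_that("multi-ortholog categories apply the stated precedence", {
  map <- mkmap(g1 = c("a1", "b1"), g2 = c("a2", "b2"), g3 = c("a3", "b3"),
               g4 = "a4")
  tests <- fake_tests(data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    ortholog = c("a1", "b1", "a2", "b2", "a3", "b3", "a4"),
    p_conserved = c(1e-8, 1e-8, 1e-8, 1, 1e-8, 0.5, 1e-8),
    p_diverged = c(1, 1, 1, 1e-8, 1, 0.5, 1)))
  rep_ <- classify_genes(tests, fdr = 0.05)
  ms <- multi_ortholog_summary(rep_, map)
  cat_of <- stats::setNames(ms$category, ms$gene)
  expect_identical(unname(cat_of["g1"]), "Uniquely conserved")
  expect_identical(unname(cat_of["g2"]), "Conserved-and-Diverged")
  expect_identical(unname(cat_of["g3"]), "Conserved")
  expect_false("g4" %in% ms$gene)   # single ortholog: out of scope
})

test_that("sequence similarity versus regulatory conservation bookkeeping", {
  mk <- function(bs_a, bs_b) {
    tests <- fake_tests(data.frame(
      gene = c("g", "g"), ortholog = c("oa", "ob"),
      p_conserved = c(1e-9, 1), p_diverged = c(1, 1e-9),
      bitscore = c(bs_a, bs_b)))
    classify_genes(tests, fdr = 0.05)
  }
  members <- rbind(
    data.frame(group = "G1", species = "s1", gene = "g"),
    data.frame(group = "G1", species = "s2", gene = c("oa", "ob")))
  map <- ortholog_map(members)
  # conserved ortholog has the lower bit-score
  res <- sequence_vs_regulation(mk(80, 100), map)
  expect_equal(unname(res$fractions["most_similar_most_diverged"]), 1)
  expect_identical(res$most_conserved$ortholog, "oa")
  expect_identical(res$ranks, 2L)
  # conserved ortholog has the higher bit-score
  res2 <- sequence_vs_regulation(mk(100, 80), map)
  expect_equal(unname(res2$fractions["most_similar_most_conserved"]), 1)
  expect_identical(res2$ranks, 1L)
  # missing bit-scores exclude the gene but count it
  res3 <- sequence_vs_regulation(mk(NA, 80), map)
  expect_identical(res3$n_excluded, 1L)
  expect_identical(res3$n_applicable, 0L)
})

test_that("the planted bit-score coin is recovered at about one half", {
  spec <- scenario_spec(species_names = c("ath", "pop"), duplication_rate = 0.4,
                        fraction_conserved = 0.55, fraction_diverged = 0.05,
                        fraction_unrelated = 0.4, seed = 31)
  st <- simulate_study(spec)
  clrs <- lapply(st$expression, function(e) clr_transform(mi_matrix(e)))
  nets <- lapply(names(clrs), function(sp) build_network(clrs[[sp]], 2, st$tfs[[sp]]))
  names(nets) <- names(clrs)
  tst <- neighbourhood_tests(nets$ath, nets$pop, st$orthologs, "ath", "pop")
  rep_ <- classify_genes(tst, 0.05)
  res <- sequence_vs_regulation(rep_, st$orthologs)
  expect_gt(res$n_applicable, 40)
  frac <- unname(res$fractions["most_similar_most_conserved"])
  # the generator flips a fair coin for which copy scores higher; allow 3.5
  # binomial standard errors around 0.5
  half_width <- 3.5 * sqrt(0.25 / res$n_applicable)
  expect_gt(frac, 0.5 - half_width)
  expect_lt(frac, 0.5 + half_width)
})

test_that("core conservation intersects directional reports over a trio", {
  mkrep <- function(from, to, cats) {
    structure(list(genes = data.frame(gene = names(cats), category = unname(cats)),
                   from = from, to = to,
                   counts = table(factor(cats, levels = c(
                     "Conserved", "Conserved-and-Diverged", "Diverged", "None")))),
              class = "conservation_report")
  }
  r_ab <- mkrep("a", "b", c(g1 = "Conserved", g2 = "Conserved", g3 = "None",
                            g4 = "Conserved-and-Diverged"))
  r_ac <- mkrep("a", "c", c(g1 = "Conserved", g2 = "None", g3 = "Conserved",
                            g4 = "Diverged"))
  r_ba <- mkrep("b", "a", c(h1 = "Conserved"))
  r_bc <- mkrep("b", "c", c(h1 = "Conserved"))
  r_ca <- mkrep("c", "a", c(k1 = "None"))
  r_cb <- mkrep("c", "b", c(k1 = "Diverged"))
  cc <- core_conservation(list(r_ab, r_ac, r_ba, r_bc, r_ca, r_cb))
  a_row <- cc[cc$species == "a", ]
  # g1 conserved vs both; g2 conserved vs one only; g4 conserved vs b and
  # diverged vs c
  sets <- attr(cc, "core_sets")
  expect_setequal(sets$a$conserved, "g1")
  expect_setequal(sets$a$diverged, "g4")
  expect_identical(a_row$n_conserved, 1L)
  expect_identical(cc[cc$species == "b", ]$n_conserved, 1L)
  expect_identical(cc[cc$species == "c", ]$n_conserved, 0L)
  expect_error(core_conservation(list(r_ab, r_ba)), "3 species")

  # identical triplicated networks under identity maps: every eligible gene
  # is in the conserved core
  st <- toy_study(seed = 33, species = c("x", "y", "z"))$study
  clrs <- lapply(st$expression, function(e) clr_transform(mi_matrix(e)))
  nets <- lapply(names(clrs), function(sp) build_network(clrs[[sp]], 1.5, st$tfs[[sp]]))
  names(nets) <- names(clrs)
  reps <- list()
  for (s1 in names(nets)) for (s2 in setdiff(names(nets), s1)) {
    tst <- neighbourhood_tests(nets[[s1]], nets[[s2]], st$orthologs, s1, s2)
    if (nrow(tst) > 0) reps[[paste(s1, s2)]] <- classify_genes(tst, 0.05)
  }
  cc2 <- core_conservation(reps)
  expect_true(all(cc2$n_conserved <= cc2$n_eligible))
})

test_that("conservation fraction drops as the threshold rises", {
  st <- recovery_fixture()
  fr <- vapply(c(2, 3.5), function(th) {
    n1 <- build_network(st$clrs$ath, th, st$study$tfs$ath)
    n2 <- build_network(st$clrs$pop, th, st$study$tfs$pop)
    neighbourhood_conservation_fraction(n1, n2, st$study$orthologs,
                                        "ath", "pop")$fraction
  }, 0)
  expect_gte(fr[1], fr[2])
  expect_gt(fr[1], 0.5)
})
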
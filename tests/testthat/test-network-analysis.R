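# helper: build a DiseaseNetwork from a plain edge list
net_from_pairs <- function(pairs, nodes = NULL) {
  df <- data.frame(disease_a = pairs[, 1], disease_b = pairs[, 2],
                   rho = 0.5, p = 0.01, q = 0.02)
  if (is.null(nodes)) nodes <- sort(unique(c(pairs[, 1], pairs[, 2])))
  disease_network(nodes, df)
}

test_that("within-network distance matches hand-computed shortest paths", {
  # path graph A-B-C: distances 1, 1, 2 over k = 2 internal links
  path3 <- net_from_pairs(rbind(c("A", "B"), c("B", "C")))
  wd <- within_network_distance(path3, c("A", "B", "C"))
  expect_equal(wd$wd, 2)
  expect_identical(wd$k, 2L)
  expect_false(wd$disconnected)

  # members spanning disconnected components have infinite, flagged WD
  split_net <- net_from_pairs(rbind(c("A", "B"), c("C", "D")))
  wd2 <- within_network_distance(split_net, c("A", "B", "C", "D"))
  expect_true(is.infinite(wd2$wd))
  expect_true(wd2$disconnected)

  # no internal link leaves the statistic undefined
  expect_error(within_network_distance(split_net, c("A", "C")), "undefined")
  expect_error(within_network_distance(path3, "A"), ">= 2")
})

test_that("WD is non-increasing under within-category edge addition", {
  set.seed(6)
  nodes <- sprintf("n%02d", 1:10)
  for (rep in 1:10) {
    all_pairs <- t(combn(nodes, 2))
    picked <- all_pairs[sample(nrow(all_pairs), 14), , drop = FALSE]
    g <- igraph::graph_from_edgelist(picked, directed = FALSE)
    if (igraph::components(g)$no > 1) next
    members <- sample(nodes, 5)
    net <- net_from_pairs(picked, nodes)
    inside <- picked[, 1] %in% members & picked[, 2] %in% members
    if (!any(inside)) next
    wd_before <- within_network_distance(net, members)$wd
    # add one new edge inside the member set
    candidates <- t(combn(members, 2))
    key <- paste(pmin(picked[, 1], picked[, 2]), pmax(picked[, 1], picked[, 2]))
    cand_key <- paste(pmin(candidates[, 1], candidates[, 2]),
                      pmax(candidates[, 1], candidates[, 2]))
    free <- candidates[!(cand_key %in% key), , drop = FALSE]
    if (!nrow(free)) next
    net2 <- net_from_pairs(rbind(picked, free[1, ]), nodes)
    expect_lte(within_network_distance(net2, members)$wd, wd_before)
  }
})

test_that("category WD tables flag categories looser than the whole network", {
  # clique category inside a sparse background
  pairs <- rbind(c("A", "B"), c("A", "C"), c("B", "C"),  # clique {A,B,C}
                 c("C", "D"), c("D", "E"), c("E", "F"))
  net <- net_from_pairs(pairs)
  ann <- category_annotation(list(A = "clique", B = "clique", C = "clique",
                                  D = "chain", E = "chain", F = "chain",
                                  X = "unknown-disease", E2 = character(0)),
                             taxonomy = "toy")
  expect_warning(tab <- category_wd_table(net, ann), "not in network")
  clique_row <- tab[tab$category == "clique", ]
  whole_row <- tab[tab$category == "whole network", ]
  expect_equal(clique_row$wd, 1)
  expect_false(clique_row$above_whole_network)
  expect_gt(whole_row$wd, 1)
  chain_row <- tab[tab$category == "chain", ]
  expect_true(chain_row$above_whole_network == (chain_row$wd > whole_row$wd))

  # categories with fewer than two connected diseases are omitted
  ann2 <- category_annotation(list(A = "solo", B = "chain", C = "chain"))
  expect_warning(tab2 <- category_wd_table(net, ann2), "omitted")
  expect_false("solo" %in% tab2$category)
})

test_that("tissue permutation finds planted compact tissues and keeps counts", {
  # tissue t1 = clique of 4; remaining diseases sparsely connected
  nodes <- c(sprintf("c%d", 1:4), sprintf("x%d", 1:8))
  clique <- t(combn(sprintf("c%d", 1:4), 2))
  chain <- cbind(c(sprintf("x%d", 1:7), "c1"), c(sprintf("x%d", 2:8), "x1"))
  net <- net_from_pairs(rbind(clique, chain), nodes)
  tissue_map <- stats::setNames(rep(c("t1", "t2", "t3"), each = 4), nodes)
  expect_error(tissue_wd_permutation(net, tissue_map, reps = 50), ">= 100")
  res <- tissue_wd_permutation(net, tissue_map, reps = 200, seed = 2)
  expect_setequal(res$tissue, c("t1", "t2", "t3"))
  expect_true(all(res$n_diseases == 4))
  t1 <- res[res$tissue == "t1", ]
  expect_equal(t1$wd, 1)
  expect_lt(t1$p_wilcoxon, 0.05)
  expect_lt(t1$p_empirical, 0.1)
  # deterministic under a fixed seed
  res2 <- tissue_wd_permutation(net, tissue_map, reps = 200, seed = 2)
  expect_identical(res, res2)
})

test_that("average-linkage clustering recovers separable blocks and oracle heights", {
  diseases <- sprintf("d%d", 1:6)
  rho <- matrix(0, 6, 6, dimnames = list(diseases, diseases))
  rho[1:3, 1:3] <- 1; rho[4:6, 4:6] <- 1
  sim <- structure(list(diseases = diseases, rho = rho,
                        covariate_mode = "none"), class = "SimilarityMatrix")
  pairs <- t(combn(diseases, 2))
  ps <- data.frame(disease_a = pairs[, 1], disease_b = pairs[, 2],
                   p = 0.001)
  groups <- hierarchical_cluster(sim, ps, k = 2)
  expect_length(unique(groups[1:3]), 1)
  expect_length(unique(groups[4:6]), 1)
  expect_false(groups[1] == groups[4])
  expect_error(hierarchical_cluster(sim, ps, k = 7), "exceed")

  # merge heights agree with a brute-force average-linkage oracle
  set.seed(12)
  r <- matrix(runif(36, -0.5, 0.9), 6, 6, dimnames = list(diseases, diseases))
  r <- (r + t(r)) / 2; diag(r) <- 1
  sim2 <- structure(list(diseases = diseases, rho = r,
                         covariate_mode = "none"), class = "SimilarityMatrix")
  groups2 <- hierarchical_cluster(sim2, ps, k = 2)
  tree <- attr(groups2, "tree")
  expect_equal(tree$height,
               oracle_average_linkage_heights(stats::as.dist(1 - r)),
               tolerance = 1e-12)

  # zeroing non-significant coefficients changes the metric
  ps0 <- ps; ps0$p <- 0.9
  groups3 <- hierarchical_cluster(sim2, ps0, k = 2)
  tree3 <- attr(groups3, "tree")
  expect_true(all(abs(tree3$height - 1) < 1e-12))
})

test_that("pair sharing uses the upper-tail hypergeometric and is symmetric", {
  assoc <- association_table(
    list(a = sprintf("i%d", 1:5), b = sprintf("i%d", 1:5),
         c = sprintf("i%d", 6:10), d = character(0)),
    kind = "gene", universe = sprintf("i%d", 1:10))
  full <- pair_sharing_test(assoc, "a", "b")
  expect_equal(full$p, 1 / choose(10, 5), tolerance = 1e-12)
  none <- pair_sharing_test(assoc, "a", "c")
  expect_equal(none$p, 1)
  expect_equal(pair_sharing_test(assoc, "c", "a")$p, none$p)
  expect_error(pair_sharing_test(assoc, "a", "zz"), "absent")
})

test_that("the DDL sharing Fisher test matches enumeration on small tables", {
  set.seed(13)
  for (rep in 1:30) {
    tab <- matrix(sample(0:15, 4, replace = TRUE) + 1, 2, 2)
    expect_equal(ddl_vs_nonddl_fisher(tab)$p, oracle_fisher_greater(tab),
                 tolerance = 1e-10)
  }
  # identical row proportions carry no enrichment signal
  flat <- matrix(c(10, 20, 5, 10), 2, 2)
  expect_gte(ddl_vs_nonddl_fisher(flat)$p, 0.5)
  expect_error(ddl_vs_nonddl_fisher(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("sharing contingency classifies pairs by link status and overlap", {
  nodes <- c("a", "b", "c", "d")
  net <- net_from_pairs(rbind(c("a", "b"), c("c", "d")), nodes)
  assoc <- association_table(
    list(a = c("x", "y", "z"), b = c("x", "y", "w"),
         c = c("q", "r"), d = c("s", "t")),
    kind = "drug", universe = c("x", "y", "z", "w", "q", "r", "s", "t"))
  tab <- sharing_contingency(net, assoc, alpha = 0.2)
  expect_identical(sum(tab), 6L)                  # all covered pairs
  expect_identical(sum(tab["DDL", ]), 2L)         # two edges
  # the a-b pair shares 2 of 3 items from a universe of 8
  p_ab <- pair_sharing_test(assoc, "a", "b")$p
  expect_identical(tab["DDL", "significant"] >= 1, p_ab < 0.2)
})

test_that("degree histograms cover configurable bins", {
  path4 <- net_from_pairs(cbind(c("a", "b", "c"), c("b", "c", "d")))
  h <- degree_distribution(path4, list(c(1, 1)))
  expect_equal(h$fraction, 0.5)
  expect_identical(attr(h, "outside"), 2L)
  h2 <- degree_distribution(path4, list(c(1, 1), c(2, 5)))
  expect_equal(sum(h2$fraction), 1)
  expect_error(degree_distribution(path4, list(c(1, 2), c(2, 3))), "overlap")
  clique <- net_from_pairs(t(combn(letters[1:5], 2)))
  h3 <- degree_distribution(clique, list(c(0, 3), c(4, 4)))
  expect_equal(h3$fraction, c(0, 1))
})

test_that("common-DCG enrichment ranks the matching pathway first", {
  universe <- sprintf("g%03d", 1:80)
  pc <- pathway_collection(list(hit = universe[1:10],
                                other1 = universe[31:40],
                                other2 = universe[41:55]))
  res <- common_dcg_enrichment(universe[1:10], pc, universe,
                               reps = 200, seed = 3)
  expect_identical(res$per_pathway$pathway[which.min(res$per_pathway$p)],
                   "hit")
  # the per-pathway kernel is the same upper-tail hypergeometric
  expect_equal(res$per_pathway$p[1],
               oracle_hyper_upper(10, 10, 80, 10), tolerance = 1e-12)
  expect_true(res$proportion_p >= 1 / 201 && res$proportion_p <= 1)
  expect_error(common_dcg_enrichment(universe[1:10], pc, universe, reps = 10),
               ">= 100")
  expect_error(common_dcg_enrichment(c("zzz"), pc, universe, reps = 200),
               "subset")
})
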
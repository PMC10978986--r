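test_that("quality classes follow the completeness/contamination thresholds", {
  # boundary and interior cases for each class
  expect_identical(classify_quality(0.95, 0.02), "HQ")
  expect_identical(classify_quality(0.90, 0.05), "HQ")   # inclusive bounds
  expect_identical(classify_quality(0.80, 0.08), "MHQ")
  expect_identical(classify_quality(0.89, 0.06), "MHQ")
  expect_identical(classify_quality(0.60, 0.20), "MQ")
  expect_identical(classify_quality(0.49, 0.01), "LQ")
  expect_identical(classify_quality(0.95, 0.30), "LQ")   # contamination alone
  expect_error(classify_quality(1.2, 0))
  # nesting: every HQ genome satisfies the MHQ and MQ filters
  set.seed(1)
  comp <- runif(200); cont <- runif(200, 0, 0.3)
  q <- classify_quality(comp, cont)
  expect_true(all(comp[q == "HQ"] >= 0.75 & cont[q == "HQ"] <= 0.10))
  expect_true(all(comp[q %in% c("HQ", "MHQ")] >= 0.50 &
                    cont[q %in% c("HQ", "MHQ")] <= 0.25))
})

test_that("completeness correction divides by completeness", {
  expect_equal(completeness_corrected(2e6, 0.8), 2.5e6)
  expect_equal(completeness_corrected(1234, 1.0), 1234)
  # monotone decreasing in completeness at fixed value
  v <- completeness_corrected(1e6, c(0.5, 0.7, 0.9))
  expect_true(all(diff(v) < 0))
  expect_error(completeness_corrected(1, 0))
})

test_that("dereplication recovers a planted partition and picks representatives", {
  plan <- list(c("gA", "gB", "gC"), c("gD", "gE", "gF"))
  fix <- gen_ani_matrix(plan, seed = 4)
  genomes <- data.frame(genome_id = unlist(plan),
                        completeness = c(0.9, 0.7, 0.8, 0.95, 0.6, 0.85),
                        contamination = c(0.01, 0.01, 0.1, 0.02, 0.0, 0.02),
                        genome_length = c(3e6, 2e6, 4e6, 2e6, 3e6, 5e6))
  cl <- dereplicate(fix$ani, fix$cov, genomes)
  got <- unname(split(cl$genome_id, cl$cluster_id))
  expect_equal(lapply(got, sort), lapply(plan, sort))
  # representative maximizes completeness - 5 * contamination
  reps <- unique(cl$representative_id[cl$genome_id %in% plan[[1]]])
  expect_identical(reps, "gA")
})

test_that("coverage condition separates high-ANI pairs and clusters partition the input", {
  ids <- c("x", "y", "z")
  ani <- matrix(1, 3, 3, dimnames = list(ids, ids))
  ani["x", "y"] <- ani["y", "x"] <- 0.96
  ani["x", "z"] <- ani["z", "x"] <- 0.80
  ani["y", "z"] <- ani["z", "y"] <- 0.80
  cov <- matrix(0.9, 3, 3, dimnames = list(ids, ids))
  cov["x", "y"] <- cov["y", "x"] <- 0.50  # high ANI but low coverage
  genomes <- data.frame(genome_id = ids, completeness = 0.9,
                        contamination = 0.01, genome_length = 3e6)
  cl <- dereplicate(ani, cov, genomes)
  expect_equal(length(unique(cl$cluster_id)), 3)  # all singletons
  expect_setequal(cl$genome_id, ids)
  # all within-threshold: one cluster
  cov[] <- 0.9; ani[] <- 1
  cl2 <- dereplicate(ani, cov, genomes)
  expect_equal(length(unique(cl2$cluster_id)), 1)
})

test_that("domain trees join through a 0.122 bridge without disturbing intra-domain distances", {
  set.seed(2)
  bact <- ape::rtree(6, tip.label = paste0("B", 1:6))
  arch <- ape::rtree(4, tip.label = paste0("A", 1:4))
  joined <- join_domain_trees(bact, arch)
  d_b <- ape::cophenetic.phylo(bact)
  d_j <- ape::cophenetic.phylo(joined)
  expect_equal(d_j[rownames(d_b), colnames(d_b)], d_b, tolerance = 1e-12)
  # inter-domain distance = depths to the two subtree roots + 0.122
  depth <- function(tr, tip) {
    dn <- ape::dist.nodes(tr)
    dn[match(tip, tr$tip.label), length(tr$tip.label) + 1]
  }
  expect_equal(d_j["B2", "A3"], depth(bact, "B2") + depth(arch, "A3") + 0.122,
               tolerance = 1e-12)
  # two single-leaf trees with zero stems: leaf-leaf distance is the bridge
  js <- join_domain_trees(coactomics:::single_tip_tree("B1"),
                          coactomics:::single_tip_tree("A1"))
  expect_equal(ape::cophenetic.phylo(js)["B1", "A1"], 0.122)
  # round-trips through Newick
  rt <- ape::read.tree(text = ape::write.tree(joined))
  expect_setequal(rt$tip.label, joined$tip.label)
  expect_error(join_domain_trees(bact, bact))
})

test_that("patristic distance matches brute-force path search", {
  cherry <- ape::read.tree(text = "(a:0.2,b:0.3);")
  expect_equal(patristic_distance(cherry, "a", "b"), 0.5)
  expect_equal(patristic_distance(cherry, "a", "a"), 0)
  expect_error(patristic_distance(cherry, "a", "nope"))
  set.seed(3)
  tr <- ape::rtree(12)
  # oracle: shortest path on the tree's edge graph with branch lengths
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$edge[, 1], to = tr$edge[, 2]), directed = FALSE)
  igraph::E(g)$weight <- tr$edge.length
  tips <- tr$tip.label
  for (pair in list(c(1, 5), c(2, 12), c(7, 8))) {
    want <- igraph::distances(g, v = as.character(pair[1]),
                              to = as.character(pair[2]))[1, 1]
    expect_equal(patristic_distance(tr, tips[pair[1]], tips[pair[2]]),
                 want, tolerance = 1e-10)
  }
  # metric sanity: triangle inequality over a few triples
  dm <- ape::cophenetic.phylo(tr)
  for (tri in list(c(1, 2, 3), c(4, 8, 11))) {
    d <- dm[tips[tri], tips[tri]]
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-12)
  }
})

test_that("mean community phylogenetic distance averages all unordered pairs", {
  # star tree, all branches 1: every pairwise distance is 2
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(mean_community_pd(star, c("a", "b", "c", "d")), 2)
  # three leaves with pairwise distances 1, 2, 3 -> mean 2
  dm <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  expect_equal(mean_community_pd(NULL, c("p", "q", "r"), dist_matrix = dm), 2)
  # equals brute-force pair enumeration on a random tree
  set.seed(5)
  tr <- ape::rtree(10)
  mem <- tr$tip.label[c(1, 4, 6, 9)]
  dmat <- ape::cophenetic.phylo(tr)
  acc <- 0; np <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    acc <- acc + dmat[mem[i], mem[j]]; np <- np + 1
  }
  expect_equal(mean_community_pd(tr, mem), acc / np)
  expect_error(mean_community_pd(tr, "one"))
})
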
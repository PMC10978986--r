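test_that("random community sampling respects the pool and is deterministic", {
  pool <- sprintf("g%03d", 1:50)
  comms <- sample_random_communities(pool, sizes = c(2, 3, 4), n = 110,
                                     seed = 5)
  expect_length(comms, 110)
  expect_true(all(unlist(comms) %in% pool))
  expect_true(all(vapply(comms, anyDuplicated, integer(1)) == 0))
  expect_true(all(lengths(comms) %in% c(2, 3, 4)))
  expect_identical(comms,
                   sample_random_communities(pool, c(2, 3, 4), 110, seed = 5))
  expect_error(sample_random_communities(pool[1:3], sizes = 5, n = 1))
  # mean PD of random communities approximates the pool mean pairwise PD
  set.seed(6)
  tr <- ape::rtree(50, tip.label = pool)
  dm <- ape::cophenetic.phylo(tr)
  pool_mean <- mean(dm[upper.tri(dm)])
  null_pd <- vapply(comms, function(m) mean_community_pd(tr, m, dm),
                    numeric(1))
  expect_lt(abs(mean(null_pd) - pool_mean) / pool_mean, 0.1)
})

test_that("community classification uses the null quantile quadrants", {
  thr <- structure(list(pd_q05 = 1.0, score_q95 = 0.5, n_random = 100),
                   class = "null_thresholds")
  expect_equal(classify_community(0.5, 0.9, thr), "LPD-HCP")
  expect_equal(classify_community(1.5, 0.2, thr), "HPD-LCP")
  expect_equal(classify_community(0.5, 0.2, thr), "LPD-LCP")
  expect_equal(classify_community(1.5, 0.9, thr), "HPD-HCP")
  # boundaries: at the thresholds the community is HPD / LCP
  expect_equal(classify_community(1.0, 0.5, thr), "HPD-LCP")
  expect_error(null_thresholds(1:10, 1:10))  # fewer than 30 nulls
})

test_that("functional Gini matches its closed forms and stays in [0, 1]", {
  expect_equal(functional_gini(c(4, 4, 4))$gini, 0)
  expect_equal(functional_gini(c(0, 0, 10))$gini, 1)
  expect_equal(functional_gini(c(2, 4))$gini, 1 / 3)
  # KO-set interface: capitals are counts of occurring KOs
  sets <- list(g1 = c("K1", "K2"), g2 = c("K2", "K3", "K4"), g3 = "K1")
  fg <- functional_gini(sets)
  expect_equal(unname(fg$capitals), c(2, 3, 1))
  # scale invariance and bounds on random capitals
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(sample(2:8, 1), 5) + 1
    g <- functional_gini(x)$gini
    expect_gte(g, 0); expect_lte(g, 1)
    expect_equal(functional_gini(x * 13)$gini, g, tolerance = 1e-12)
    # naive double-loop oracle
    n <- length(x)
    want <- sum(abs(outer(x, x, "-"))) / (2 * n * (n - 1) * mean(x))
    expect_equal(g, want)
  }
  expect_error(functional_gini(c(0, 0)))
})

test_that("functional Jaccard distance handles plain and expressed modes", {
  expect_equal(functional_jaccard(c("k1", "k2"), c("k1", "k2")), 0)
  expect_equal(functional_jaccard(c("k1"), c("k2")), 1)
  expect_equal(functional_jaccard(c("k1", "k2", "k3"),
                                  c("k2", "k3", "k4")), 0.5)
  det <- data.frame(ko = c("k1", "k2", "k3", "k4"),
                    n_samples_detected = c(15, 9, 12, 30))
  # k2 drops out in expressed mode (detected in < 10 samples)
  expect_equal(functional_jaccard(c("k1", "k2"), c("k1", "k3"),
                                  expressed_mode = TRUE,
                                  expression_detection = det),
               1 - 1 / 2)
  expect_error(functional_jaccard(character(0), character(0)))
})

test_that("exchange category profiles partition the community sum scores", {
  recs <- data.frame(community_id = c("c1", "c1", "c2", "c2"),
                     metabolite = c("aa1_e", "thb_e", "aa2_e", "odd"),
                     smetana = c(0.8, 0.3, 0.5, 0.2))
  cmap <- data.frame(metabolite = c("aa1_e", "aa2_e", "thb_e"),
                     category = c("amino acids", "amino acids", "B vitamins"))
  prof <- exchange_category_profile(recs, cmap)
  expect_equal(prof["c1", "amino acids"], 0.8)
  expect_equal(prof["c1", "B vitamins"], 0.3)
  expect_equal(prof["c2", "uncategorized"], 0.2)
  # row sums = community sum scores
  expect_equal(as.numeric(rowSums(prof)),
               as.numeric(tapply(recs$smetana, recs$community_id, sum)))
})

test_that("per-metabolite tests star planted differences and pass ties through", {
  set.seed(8)
  comms_a <- sprintf("a%02d", 1:8); comms_b <- sprintf("b%02d", 1:8)
  recs <- rbind(
    data.frame(community_id = rep(c(comms_a, comms_b), each = 1),
               metabolite = "aa1_e",
               smetana = c(runif(8, 0.8, 1.0), runif(8, 0.0, 0.2))),
    data.frame(community_id = rep(c(comms_a, comms_b), each = 1),
               metabolite = "thb_e", smetana = runif(16, 0.4, 0.6)))
  out <- per_metabolite_tests(recs, list(A = comms_a, B = comms_b))
  expect_true(out$p_bh[out$metabolite == "aa1_e"] <= 0.05)
  expect_true(out$p_bh[out$metabolite == "thb_e"] > 0.05)
  # star convention
  expect_equal(p_stars(c(5e-5, 5e-4, 5e-3, 0.03, 0.2)),
               c("****", "***", "**", "*", "ns"))
  # identical distributions: tied scores reported as ns
  tied <- data.frame(community_id = c(comms_a, comms_b),
                     metabolite = "flat", smetana = 0.5)
  out2 <- per_metabolite_tests(tied, list(A = comms_a, B = comms_b))
  expect_identical(out2$stars, "ns")
})

test_that("NMDS embeds duplicated communities at coincident points", {
  set.seed(9)
  prof <- matrix(runif(24, 0.1, 1), 6, 4,
                 dimnames = list(sprintf("c%d", 1:6), sprintf("cat%d", 1:4)))
  prof[2, ] <- prof[1, ]  # duplicate
  # near-zero stress on a tiny fixture triggers vegan's informative warning
  fit <- suppressWarnings(nmds_ordination(prof, seed = 4))
  spread <- max(dist(fit$points))
  expect_lt(sqrt(sum((fit$points[1, ] - fit$points[2, ])^2)), 0.02 * spread)
  expect_gte(fit$stress, 0)
  expect_error(nmds_ordination(prof[1:3, ], seed = 1))
})

test_that("donor summaries compare centrality and corrected size with both p values", {
  nodes <- sprintf("n%02d", 1:10)
  # hub-donor construction: n01 is the star centre and the only donor
  ed <- data.frame(g1 = "n01", g2 = nodes[-1], weight = 0.5, cond_set = "",
                   n_obs = 20)
  net <- structure(list(nodes = nodes, edges = ed, alpha = 0.01, max_k = 3),
                   class = "assoc_network")
  recs <- data.frame(donor = "n01", receiver = "n02", metabolite = "aa1_e",
                     smetana = 1)
  genomes <- data.frame(genome_id = nodes,
                        genome_length = seq(2e6, 4e6, length.out = 10),
                        completeness = 0.9)
  out <- donor_summaries(net, recs, genomes)
  expect_setequal(out$metric, c("closeness_centrality",
                                "corrected_genome_size"))
  expect_true(all(c("p_value", "p_bh") %in% names(out)))
  cc_row <- out[out$metric == "closeness_centrality", ]
  expect_gt(cc_row$median_donor, cc_row$median_non_donor)
  # all genomes donors: skipped with a message
  all_d <- data.frame(donor = nodes, receiver = "x", metabolite = "aa1_e",
                      smetana = 1)
  expect_message(res <- donor_summaries(net, all_d, genomes))
  expect_null(res)
})
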
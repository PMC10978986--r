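test_that("Fisher z test matches its closed form and is monotone in |r|", {
  # r = 0.5, n = 50, k = 0: z = atanh(0.5) * sqrt(47) = 3.7659, p = 1.662e-4
  ft <- fisher_z_test(0.5, 50, 0, alpha = 0.01)
  expect_equal(ft$z, 3.76589, tolerance = 1e-4)
  expect_equal(ft$p, 1.662e-4, tolerance = 1e-3)
  expect_true(ft$significant)
  expect_equal(fisher_z_test(0, 30)$p, 1)
  ps <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r)
    fisher_z_test(r, 40, 1)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(fisher_z_test(0.5, 5, 3))  # n - k - 3 <= 0
})

test_that("partial correlation agrees with the regression-residual oracle", {
  set.seed(12)
  X <- matrix(rnorm(500 * 5), 500, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  X[, 2] <- X[, 1] + 0.5 * rnorm(500)
  X[, 3] <- X[, 2] + 0.5 * rnorm(500)
  # empty set equals plain correlation
  expect_equal(partial_correlation(X, 1, 3)$r, cor(X[, 1], X[, 3]))
  for (S in list(2L, c(2L, 4L), c(2L, 4L, 5L))) {
    got <- partial_correlation(X, 1, 3, S)$r
    expect_equal(got, oracle_partial_cor(X, 1, 3, S), tolerance = 1e-10)
  }
  # chain: X and Z conditionally independent given Y
  expect_lt(abs(partial_correlation(X, 1, 3, 2L)$r), 0.1)
  expect_error(partial_correlation(cbind(X, X[, 2]), 1, 3, c(2L, 6L)))
})

test_that("network inference matches the exhaustive-conditioning oracle on dense fixtures", {
  for (s in 1:6) {
    X <- t(make_block_data(150, seed = 700 + s))  # obs x vars
    net <- infer_network(t(X), alpha = 0.01, max_k = 3,
                         conditioning = "exhaustive")
    got <- edge_keys(net)
    want <- oracle_network_edges(X, alpha = 0.01, max_k = 3)
    expect_identical(got, want)
  }
  # the default neighbourhood-restricted procedure can only keep a
  # superset of the exhaustive-oracle edges (fewer removing tests)
  X <- t(make_block_data(150, seed = 699))
  nb_edges <- edge_keys(infer_network(t(X), alpha = 0.01, max_k = 3))
  expect_true(all(oracle_network_edges(X, alpha = 0.01, max_k = 3)
                  %in% nb_edges))
})

test_that("indirect chain associations are removed, direct ones kept", {
  removed_xz <- 0; kept_direct <- 0
  for (s in 1:40) {
    mat <- make_chain_data(500, seed = 800 + s)
    net <- infer_network(mat, alpha = 0.01, max_k = 3)
    keys <- edge_keys(net)
    removed_xz <- removed_xz + !("X|Z" %in% keys)
    kept_direct <- kept_direct + all(c("X|Y", "Y|Z") %in% keys)
  }
  expect_gte(removed_xz / 40, 0.95)
  expect_gte(kept_direct / 40, 0.95)
  # every removal is certified by a recorded non-significant test
  mat <- make_chain_data(500, seed = 801)
  net <- infer_network(mat, alpha = 0.01, max_k = 3)
  if (!"X|Z" %in% edge_keys(net)) {
    expect_true(any(net$audit$g1 == "X" & net$audit$g2 == "Z" &
                      net$audit$p >= 0.01))
  }
})

test_that("duplicated variables stay connected with weight near one", {
  set.seed(13)
  v <- rnorm(40)
  mat <- rbind(a = v, b = v, c = rnorm(40))
  colnames(mat) <- sprintf("S%02d", 1:40)
  net <- infer_network(mat, alpha = 0.01, max_k = 3)
  expect_true("a|b" %in% edge_keys(net))
  w <- net$edges$weight[net$edges$g1 %in% c("a", "b") &
                          net$edges$g2 %in% c("a", "b")]
  expect_gt(abs(w), 0.99)
})

test_that("network inference is permutation-equivariant", {
  mat <- t(make_block_data(120, seed = 900))
  mat <- t(mat)  # genomes x samples
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  net1 <- infer_network(mat, alpha = 0.01, max_k = 3)
  net2 <- infer_network(mat[perm, ], alpha = 0.01, max_k = 3)
  expect_identical(edge_keys(net1), edge_keys(net2))
})

test_that("closeness centrality matches hand values and brute force", {
  star_edges <- data.frame(g1 = "hub", g2 = paste0("leaf", 1:5),
                           weight = 1, cond_set = "", n_obs = 20)
  star <- structure(list(nodes = c("hub", paste0("leaf", 1:5)),
                         edges = star_edges, alpha = 0.01, max_k = 3),
                    class = "assoc_network")
  cc <- closeness_centrality(star)
  expect_equal(unname(cc["hub"]), 1.0)
  # path P3 end node: 2 / (1 + 2)
  p3 <- structure(list(nodes = c("a", "b", "c"),
                       edges = data.frame(g1 = c("a", "b"), g2 = c("b", "c"),
                                          weight = 1, cond_set = "",
                                          n_obs = 20),
                       alpha = 0.01, max_k = 3), class = "assoc_network")
  expect_equal(unname(closeness_centrality(p3)["a"]), 2 / 3)
  # isolated node gets 0
  iso <- structure(list(nodes = c("a", "b", "z"),
                        edges = data.frame(g1 = "a", g2 = "b", weight = 1,
                                           cond_set = "", n_obs = 20),
                        alpha = 0.01, max_k = 3), class = "assoc_network")
  expect_equal(unname(closeness_centrality(iso)["z"]), 0)
  # brute force on a random graph
  set.seed(14)
  n <- 20
  adj <- matrix(runif(n * n) < 0.15, n, n); adj[lower.tri(adj)] <- FALSE
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  nodes <- sprintf("n%02d", 1:n)
  ed <- data.frame(g1 = nodes[idx[, 1]], g2 = nodes[idx[, 2]], weight = 1,
                   cond_set = "", n_obs = 20)
  net <- structure(list(nodes = nodes, edges = ed, alpha = 0.01, max_k = 3),
                   class = "assoc_network")
  cc <- closeness_centrality(net)
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE,
                                     vertices = nodes)
  d <- igraph::distances(g)
  for (v in nodes) {
    dv <- d[v, setdiff(nodes, v)]
    reach <- is.finite(dv)
    want <- if (!any(reach)) 0 else sum(reach) / sum(dv[reach])
    expect_equal(unname(cc[v]), want, tolerance = 1e-12)
  }
})
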
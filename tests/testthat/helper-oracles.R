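# Independent oracles used across the suite. These deliberately use
# different algorithms / code paths than the package implementation.

# Partial correlation via regression residuals (the package inverts the
# covariance matrix instead).
oracle_partial_cor <- function(X, i, j, S = integer(0)) {
  sub <- X[, c(i, j, S), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  if (length(S) == 0) return(stats::cor(sub[, 1], sub[, 2]))
  d <- as.data.frame(sub)
  names(d) <- c("yi", "yj", paste0("s", seq_along(S)))
  f <- stats::as.formula(paste("~", paste(names(d)[-(1:2)], collapse = "+")))
  ri <- stats::residuals(stats::lm(stats::update(f, yi ~ .), data = d))
  rj <- stats::residuals(stats::lm(stats::update(f, yj ~ .), data = d))
  stats::cor(ri, rj)
}

# Exhaustive-conditioning network oracle: an edge i-j exists iff the
# marginal and every partial correlation given ANY subset of the other
# variables up to size max_k is significant under the Fisher z test.
oracle_network_edges <- function(X, alpha = 0.01, max_k = 3,
                                 n_obs_min = 10) {
  p <- ncol(X)
  edges <- character(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(seq_len(p), c(i, j))
    keep <- TRUE
    for (k in 0:max_k) {
      sets <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      for (S in sets) {
        sub <- X[, c(i, j, S), drop = FALSE]
        n <- sum(stats::complete.cases(sub))
        if (n < n_obs_min || n - k - 3 <= 0) next
        r <- oracle_partial_cor(X, i, j, S)
        if (abs(r) >= 1) next
        z <- atanh(r) * sqrt(n - k - 3)
        if (2 * stats::pnorm(-abs(z)) >= alpha) { keep <- FALSE; break }
      }
      if (!keep) break
    }
    if (keep) {
      r0 <- oracle_partial_cor(X, i, j)
      n0 <- sum(stats::complete.cases(X[, c(i, j)]))
      z0 <- atanh(min(max(r0, -1 + 1e-12), 1 - 1e-12)) * sqrt(n0 - 3)
      if (2 * stats::pnorm(-abs(z0)) < alpha || abs(r0) >= 1)
        edges <- c(edges, paste(colnames(X)[c(i, j)], collapse = "|"))
    }
  }
  sort(edges)
}

edge_keys <- function(net) {
  e <- net$edges
  if (nrow(e) == 0) return(character(0))
  sort(vapply(seq_len(nrow(e)), function(r)
    paste(sort(c(e$g1[r], e$g2[r])), collapse = "|"), character(1)))
}

# Reference MCL through numpy (independent runtime and numerics).
oracle_mcl_python <- function(A, inflation = 1.5) {
  f_in <- tempfile(fileext = ".csv")
  f_py <- tempfile(fileext = ".py")
  utils::write.table(A, f_in, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  writeLines(c(
    "import sys",
    "import numpy as np",
    "A = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "infl = float(sys.argv[2])",
    "np.fill_diagonal(A, 0.0)",
    "loops = A.max(axis=0)",
    "loops[loops == 0] = 1.0",
    "np.fill_diagonal(A, loops)",
    "M = A / A.sum(axis=0)",
    "for _ in range(200):",
    "    Mp = M.copy()",
    "    M = M @ M",
    "    M = M ** infl",
    "    M[M < 1e-5] = 0.0",
    "    M = M / M.sum(axis=0)",
    "    if np.abs(M - Mp).max() < 1e-8:",
    "        break",
    "supp = (M > 1e-6) | (M > 1e-6).T",
    "n = A.shape[0]",
    "lab = [-1] * n",
    "c = 0",
    "for s in range(n):",
    "    if lab[s] >= 0:",
    "        continue",
    "    stack = [s]",
    "    lab[s] = c",
    "    while stack:",
    "        v = stack.pop()",
    "        for w in range(n):",
    "            if supp[v, w] and lab[w] < 0:",
    "                lab[w] = c",
    "                stack.append(w)",
    "    c += 1",
    "print(' '.join(map(str, lab)))"), f_py)
  out <- system2("python", c(f_py, f_in, as.character(inflation)),
                 stdout = TRUE)
  as.integer(strsplit(out[length(out)], " ")[[1]])
}

# All inclusion-minimal subsets by filtering the full lattice (no
# pruning shortcuts; independent of the package's incremental search).
oracle_minimal_sets <- function(candidates, feasible) {
  all_sets <- list()
  for (k in 0:length(candidates)) {
    sets <- if (k == 0) list(candidates[0]) else
      utils::combn(candidates, k, simplify = FALSE)
    all_sets <- c(all_sets, sets)
  }
  feas <- all_sets[vapply(all_sets, feasible, logical(1))]
  is_min <- vapply(seq_along(feas), function(i) {
    !any(vapply(seq_along(feas), function(j) {
      j != i && length(feas[[j]]) < length(feas[[i]]) &&
        all(feas[[j]] %in% feas[[i]])
    }, logical(1)))
  }, logical(1))
  feas[is_min]
}

# Naive all-subsets cross-feeding score oracle (shares only the LP growth
# primitive with the implementation).
oracle_detailed_scores <- function(models, medium, g_min = 1e-4) {
  members <- names(models)
  organics <- organic_exchange_metabolites(models)
  grows_set <- function(mem) {
    if (length(mem) == 1)
      check_growth(models[[mem]], medium, g_min = g_min)$grows
    else check_growth(community_model(models[mem], "shared"), medium,
                      g_min = g_min)$grows
  }
  scs <- function(d, r) {
    if (grows_set(r)) return(0)
    dsets <- oracle_minimal_sets(setdiff(members, r),
                                 function(s) grows_set(c(r, s)))
    if (length(dsets) == 0) return(0)
    mean(vapply(dsets, function(s) d %in% s, logical(1)))
  }
  mps <- function(d, m) as.numeric(max_secretion(models[[d]], m, medium) > 1e-6)
  mus <- function(r, m) {
    secretable <- organics[vapply(organics, function(mm)
      any(vapply(setdiff(members, r), function(d) mps(d, mm) > 0,
                 logical(1))), logical(1))]
    cand <- sort(intersect(union(medium, secretable),
                           organic_exchange_metabolites(models[[r]])))
    usets <- oracle_minimal_sets(cand, function(s)
      check_growth(models[[r]], s, g_min = g_min)$grows)
    if (length(usets) == 0 || !m %in% cand) return(0)
    mean(vapply(usets, function(s) m %in% s, logical(1)))
  }
  recs <- list()
  for (d in members) for (r in setdiff(members, d)) for (m in organics) {
    v <- scs(d, r) * mus(r, m) * mps(d, m)
    if (v > 0)
      recs[[length(recs) + 1L]] <- data.frame(donor = d, receiver = r,
                                              metabolite = m, smetana = v,
                                              stringsAsFactors = FALSE)
  }
  if (length(recs)) do.call(rbind, recs) else
    data.frame(donor = character(0), receiver = character(0),
               metabolite = character(0), smetana = numeric(0))
}

# X -> Y -> Z chain data (latent causal chain).
make_chain_data <- function(n, seed, noise = 0.5) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- x + noise * stats::rnorm(n)
  z <- y + noise * stats::rnorm(n)
  m <- cbind(X = x, Y = y, Z = z)
  t(m)  # genomes x samples orientation
}

# Two correlated blocks of four variables (dense marginal graph).
make_block_data <- function(n, seed) {
  set.seed(seed)
  f0 <- stats::rnorm(n)
  f1 <- f0 + 0.8 * stats::rnorm(n)
  f2 <- f0 + 0.8 * stats::rnorm(n)
  m <- sapply(1:8, function(i)
    (if (i <= 4) f1 else f2) + 0.6 * stats::rnorm(n))
  colnames(m) <- paste0("v", 1:8)
  t(m)
}

# Calibration pool for community typing: prototrophic helper donors and
# auxotrophic dependent receivers, some with alternative precursor routes
# (splits minimal uptake sets, diversifying the score lattice).
make_typing_pool <- function() {
  models <- list()
  secs <- list(c("aa1_e", "aa2_e", "rib_e"), c("aa2_e", "aa3_e"),
               c("aa4_e", "rib_e"), c("aa5_e", "aa1_e", "aa3_e"),
               c("aa4_e", "aa5_e", "rib_e"))
  for (i in seq_along(secs))
    models[[sprintf("h%02d", i)]] <-
      build_toy_model(sprintf("h%02d", i), secretes = secs[[i]])
  auxes <- list("aa1_e", "aa2_e", c("aa3_e", "aa4_e"), "aa5_e",
                c("aa1_e", "aa3_e"), c("aa2_e", "aa5_e"))
  alt <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  for (i in seq_along(auxes)) {
    gid <- sprintf("d%02d", i)
    models[[gid]] <- build_toy_model(
      gid, aux_requirements = auxes[[i]],
      alt_routes = if (alt[i])
        stats::setNames("rib_e", auxes[[i]][1]) else NULL)
  }
  models
}

# Memoized normalized community score over a fixed model pool.
make_score_fn <- function(models, medium = "glc_e") {
  cache <- new.env(parent = emptyenv())
  function(members) {
    key <- paste(sort(members), collapse = "|")
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    recs <- detailed_scores(models[members], medium = medium)
    v <- community_scores(recs, length(members))$normalized_score
    cache[[key]] <- v
    v
  }
}
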
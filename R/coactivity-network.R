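# Direct-association network inference on CLR-transformed omics matrices:
# significant marginal correlations pruned by conditional-independence
# tests (PC-stable style, neighbourhood-restricted conditioning sets).

#' Fisher z test of a (partial) correlation
#'
#' Tests `r = 0` via the Fisher transformation:
#' `z = atanh(r) * sqrt(n - k - 3)` with `k` the conditioning-set size,
#' two-sided normal p value.
#'
#' @param r Correlation in (-1, 1).
#' @param n Number of observations.
#' @param k Conditioning-set size.
#' @param alpha Significance level.
#' @return List with `significant`, `p`, `z`.
#' @export
fisher_z_test <- function(r, n, k = 0, alpha = 0.01) {
  stop_if_not(abs(r) < 1, "|r| must be < 1")
  stop_if_not(n - k - 3 > 0, "insufficient observations for Fisher z test")
  z <- atanh(r) * sqrt(n - k - 3)
  p <- 2 * stats::pnorm(-abs(z))
  list(significant = p < alpha, p = p, z = z)
}

#' Partial correlation given a conditioning set
#'
#' `r_{ij.S}`: the correlation of variables i and j after removing the
#' linear effects of the variables in S, computed by inverting the
#' covariance matrix of `{i, j} u S` over pairwise-complete observations.
#' With empty S this is the plain Pearson correlation.
#'
#' @param X Observations x variables numeric matrix (NA = missing).
#' @param i,j Column indices or names.
#' @param S Conditioning set (indices or names), `length(S) <= ncol - 2`.
#' @return List with `r` and `n` (complete observations used).
#' @export
partial_correlation <- function(X, i, j, S = integer(0)) {
  cols <- c(i, j, S)
  sub <- X[, cols, drop = FALSE]
  ok <- stats::complete.cases(sub)
  n <- sum(ok)
  if (length(S) == 0) {
    r <- stats::cor(sub[ok, 1], sub[ok, 2])
    return(list(r = r, n = n))
  }
  V <- stats::cov(sub[ok, , drop = FALSE])
  P <- tryCatch(solve(V), error = function(e)
    stop("singular conditioning (collinear S)", call. = FALSE))
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  list(r = r, n = n)
}

#' Infer a direct-association network from an omics matrix
#'
#' PC-stable-style constraint-based inference. Stage 0 keeps every genome
#' pair whose marginal correlation is significant under the Fisher z test
#' at `alpha` (pairwise-complete observations, at least `n_obs_min`). For
#' `k = 1 .. max_k`, each surviving edge is tested against all
#' conditioning subsets of size `k` drawn from the current neighbourhoods
#' of its two endpoints (snapshot per level); one non-significant test
#' removes the edge and is recorded in the audit trail. Surviving edges
#' are weighted by the partial correlation given the largest conditioning
#' set that certified them. Deterministic given input order.
#'
#' @param mat Genomes x samples matrix (CLR-transformed, NA = unobserved).
#' @param alpha Test significance level.
#' @param max_k Maximal conditioning-set size.
#' @param n_obs_min Minimum shared observations per test.
#' @param conditioning `"neighbourhood"` (default: PC-stable, conditioning
#'   sets drawn from the endpoints' current neighbourhoods) or
#'   `"exhaustive"` (all subsets of all other variables up to `max_k`;
#'   the small-instance surface on which the procedure provably equals an
#'   exhaustive conditioning oracle).
#' @return An `assoc_network`: list with `nodes`, `edges` (g1, g2, weight,
#'   cond_set, n_obs), and `audit` (the removing tests).
#' @export
infer_network <- function(mat, alpha = 0.01, max_k = 3, n_obs_min = 10,
                          conditioning = c("neighbourhood", "exhaustive")) {
  conditioning <- match.arg(conditioning)
  stop_if_not(nrow(mat) >= 2, "need >= 2 genomes")
  X <- t(mat)  # observations x variables
  vars <- colnames(X)
  nv <- length(vars)
  edge_key <- function(i, j) paste0(min(i, j), "_", max(i, j))

  edges <- list()  # key -> list(i, j, weight, cond, k, n)
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    pc <- partial_correlation(X, i, j)
    if (pc$n < n_obs_min || pc$n - 3 <= 0) next
    if (abs(pc$r) >= 1) { # duplicated variable: certainly associated
      edges[[edge_key(i, j)]] <- list(i = i, j = j, weight = pc$r,
                                      cond = integer(0), n = pc$n)
      next
    }
    ft <- fisher_z_test(pc$r, pc$n, 0, alpha)
    if (ft$significant)
      edges[[edge_key(i, j)]] <- list(i = i, j = j, weight = pc$r,
                                      cond = integer(0), n = pc$n)
  }

  audit <- list()
  for (k in seq_len(max_k)) {
    if (length(edges) == 0) break
    nb <- vector("list", nv)   # snapshot neighbourhoods at this level
    for (e in edges) {
      nb[[e$i]] <- c(nb[[e$i]], e$j)
      nb[[e$j]] <- c(nb[[e$j]], e$i)
    }
    for (key in names(edges)) {
      e <- edges[[key]]
      cand <- if (conditioning == "exhaustive")
        subsets_of(setdiff(seq_len(nv), c(e$i, e$j)), k)
      else unique(c(subsets_of(sort(setdiff(nb[[e$i]], e$j)), k),
                    subsets_of(sort(setdiff(nb[[e$j]], e$i)), k)))
      for (S in cand) {
        pc <- tryCatch(partial_correlation(X, e$i, e$j, S),
                       error = function(err) NULL)
        if (is.null(pc)) next                       # collinear S: skip
        if (pc$n < n_obs_min || pc$n - k - 3 <= 0) next
        if (abs(pc$r) >= 1) next                    # degenerate
        ft <- fisher_z_test(pc$r, pc$n, k, alpha)
        if (!ft$significant) {
          audit[[length(audit) + 1L]] <- data.frame(
            g1 = vars[e$i], g2 = vars[e$j],
            cond_set = paste(vars[S], collapse = ","),
            r = pc$r, p = ft$p, n_obs = pc$n, stringsAsFactors = FALSE)
          edges[[key]] <- NULL
          break
        }
        # still certified: track largest conditioning set
        if (length(S) >= length(e$cond)) {
          e$weight <- pc$r; e$cond <- S; e$n <- pc$n
          edges[[key]] <- e
        }
      }
    }
  }

  edf <- if (length(edges)) do.call(rbind, lapply(edges, function(e)
    data.frame(g1 = vars[e$i], g2 = vars[e$j], weight = e$weight,
               cond_set = paste(vars[e$cond], collapse = ","),
               n_obs = e$n, stringsAsFactors = FALSE)))
  else data.frame(g1 = character(0), g2 = character(0), weight = numeric(0),
                  cond_set = character(0), n_obs = numeric(0))
  rownames(edf) <- NULL
  structure(list(nodes = vars, edges = edf,
                 audit = if (length(audit)) do.call(rbind, audit) else NULL,
                 alpha = alpha, max_k = max_k, n_obs_min = n_obs_min),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d nodes, %d edges (%d positive, %d negative); alpha = %g, max_k = %d\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight > 0),
              sum(x$edges$weight < 0), x$alpha, x$max_k))
  invisible(x)
}

as_igraph <- function(net, weights = c("signed", "positive", "absolute")) {
  weights <- match.arg(weights)
  e <- net$edges
  if (weights == "positive") e <- e[e$weight > 0, , drop = FALSE]
  if (weights == "absolute") e$weight <- abs(e$weight)
  g <- igraph::graph_from_data_frame(e[, c("g1", "g2", "weight")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Closeness centrality of network nodes
#'
#' `(n_c - 1) / sum(d(v, u))` over the other members u of v's connected
#' component (component normalization), with unit edge lengths. Isolated
#' nodes get 0.
#'
#' @param net An `assoc_network` (all edges used, unweighted paths).
#' @param nodes Node names (default all).
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(net, nodes = NULL) {
  g <- as_igraph(net, "signed")
  nodes <- nodes %||% net$nodes
  stop_if_not(all(nodes %in% net$nodes), "unknown node")
  d <- igraph::distances(g, v = nodes, weights = NA)
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    dv <- d[v, ]
    reach <- is.finite(dv) & names(dv) != v
    out[v] <- if (!any(reach)) 0 else sum(reach) / sum(dv[reach])
  }
  out
}
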
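# Markov clustering of association graphs.

#' Markov clustering (MCL) of an association network
#'
#' Classic MCL flow simulation on the positive-weight subgraph (flow
#' interpretation needs non-negative similarities; negative edges are kept
#' in the network itself but dropped here, or folded in by absolute value
#' with `negative = "absolute"`). Each node receives a self-loop equal to
#' its maximum incident weight (regularization). The column-stochastic
#' matrix is alternately expanded (matrix power `expansion`), inflated
#' (elementwise power `inflation`, renormalized) and pruned (entries below
#' `prune_threshold` zeroed) until the matrix is stable. Clusters are the
#' connected components of the converged flow's support; genomes in no
#' cluster of size >= 2 are reported as singletons.
#'
#' @param net An `assoc_network`, or a symmetric non-negative adjacency
#'   matrix with dimnames.
#' @param inflation Inflation exponent (> 1), default 1.5.
#' @param expansion Expansion power, default 2.
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap; non-convergence is an error with
#'   diagnostics.
#' @param tol Convergence tolerance on the max entry change.
#' @param negative `"drop"` (default) or `"absolute"`.
#' @return List of class `mcl_communities`: `communities` (list of member
#'   vectors, size >= 2), `singletons`, `membership` (named vector),
#'   `iterations`.
#' @export
mcl_cluster <- function(net, inflation = 1.5, expansion = 2,
                        prune_threshold = 1e-5, max_iter = 200,
                        tol = 1e-8, negative = c("drop", "absolute")) {
  negative <- match.arg(negative)
  stop_if_not(inflation > 1, "inflation must be > 1")
  if (inherits(net, "assoc_network")) {
    nodes <- net$nodes
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    e <- net$edges
    w <- if (negative == "absolute") abs(e$weight) else pmax(e$weight, 0)
    for (r in seq_len(nrow(e))) {
      A[e$g1[r], e$g2[r]] <- A[e$g1[r], e$g2[r]] + w[r]
      A[e$g2[r], e$g1[r]] <- A[e$g2[r], e$g1[r]] + w[r]
    }
  } else {
    A <- as.matrix(net)
    stop_if_not(nrow(A) == ncol(A) && !is.null(rownames(A)),
                "adjacency must be square with dimnames")
    stop_if_not(all(A >= 0), "adjacency must be non-negative")
    nodes <- rownames(A)
  }
  stop_if_not(length(nodes) > 0, "empty graph")
  # self-loops: maximum incident weight (1 for isolated nodes)
  diag(A) <- 0
  self <- apply(A, 1, max)
  self[self == 0] <- 1
  diag(A) <- self
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_prev <- M
    M2 <- M
    for (p in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2[M2 < prune_threshold] <- 0
    M <- normalize(M2)
    if (max(abs(M - M_prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("MCL did not converge in %d iterations (last delta %.3g)",
                 max_iter, max(abs(M - M_prev))), call. = FALSE)
  supp <- (M > 1e-6) | t(M > 1e-6)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  mem <- igraph::components(g)$membership
  clusters <- split(nodes, mem)
  sizes <- lengths(clusters)
  communities <- unname(clusters[sizes >= 2])
  communities <- communities[order(vapply(communities,
                                          function(x) sort(x)[1],
                                          character(1)))]
  membership <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (i in seq_along(communities)) membership[communities[[i]]] <- i
  structure(list(communities = communities,
                 singletons = unlist(unname(clusters[sizes == 1])),
                 membership = membership, iterations = it),
            class = "mcl_communities")
}

#' @export
print.mcl_communities <- function(x, ...) {
  cat(sprintf("<mcl_communities> %d communities (sizes %s), %d singletons, %d iterations\n",
              length(x$communities),
              paste(lengths(x$communities), collapse = ","),
              length(x$singletons), x$iterations))
  invisible(x)
}

#' Adjusted-free Rand index between two partitions
#'
#' Fraction of node pairs on which two partitions agree (same/different
#' cluster), used to score recovery of planted communities.
#'
#' @param a,b Named membership vectors over the same nodes (NA = singleton
#'   treated as its own cluster).
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  nodes <- intersect(names(a), names(b))
  stop_if_not(length(nodes) >= 2, "need >= 2 shared nodes")
  fix <- function(m) {
    m <- m[nodes]
    na <- is.na(m)
    m[na] <- paste0("singleton_", seq_len(sum(na)))
    m
  }
  ma <- fix(a); mb <- fix(b)
  agree <- 0; total <- 0
  for (i in seq_along(nodes)[-length(nodes)]) for (j in (i + 1):length(nodes)) {
    sa <- ma[i] == ma[j]; sb <- mb[i] == mb[j]
    agree <- agree + (sa == sb); total <- total + 1
  }
  unname(agree / total)
}
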
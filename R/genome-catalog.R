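#' Classify genome quality from completeness and contamination
#'
#' Assigns each genome to one of four quality classes using the standard
#' single-copy-marker-gene quality conventions for metagenome-assembled
#' genomes: high quality (HQ) for completeness >= 90% and contamination
#' <= 5%, medium-to-high (MHQ) for >= 75% and <= 10%, medium (MQ) for
#' >= 50% and <= 25%, and low quality (LQ) otherwise. LQ genomes are
#' conventionally excluded from all downstream analyses.
#'
#' @param completeness Numeric vector of completeness fractions in \[0, 1\].
#' @param contamination Numeric vector of contamination fractions (>= 0).
#' @return Character vector with values in `c("HQ", "MHQ", "MQ", "LQ")`.
#' @examples
#' classify_quality(0.95, 0.02) # "HQ"
#' classify_quality(0.80, 0.08) # "MHQ"
#' @export
classify_quality <- function(completeness, contamination) {
  stop_if_not(all(completeness >= 0 & completeness <= 1),
              "completeness must lie in [0, 1]")
  stop_if_not(all(contamination >= 0), "contamination must be >= 0")
  stop_if_not(length(completeness) == length(contamination),
              "completeness and contamination must have the same length")
  out <- rep("LQ", length(completeness))
  out[completeness >= 0.50 & contamination <= 0.25] <- "MQ"
  out[completeness >= 0.75 & contamination <= 0.10] <- "MHQ"
  out[completeness >= 0.90 & contamination <= 0.05] <- "HQ"
  out
}

#' Correct a genome statistic for incomplete assembly
#'
#' Divides a raw genome statistic (genome length, CDS count, ...) by the
#' estimated completeness, giving the expected value for the complete genome.
#'
#' @param value Numeric vector of raw values.
#' @param completeness Completeness fraction(s), strictly positive.
#' @return `value / completeness`.
#' @export
completeness_corrected <- function(value, completeness) {
  stop_if_not(all(completeness > 0), "completeness must be > 0")
  value / completeness
}

#' Dereplicate genomes into species-level clusters from precomputed ANI
#'
#' Two-step single-linkage clustering on thresholded average nucleotide
#' identity (ANI) graphs, mirroring coarse-then-fine dereplication: first,
#' connected components of the graph with edges where `ani >= coarse_ani`
#' and alignment coverage `>= min_cov`; then, within each coarse component,
#' components where `ani >= fine_ani` and coverage `>= min_cov`. The
#' representative of each cluster maximizes the quality score
#' `completeness - quality_weight * contamination`, with ties broken by
#' larger genome length and then lexicographic genome id.
#'
#' @param ani Symmetric numeric matrix of pairwise ANI values in \[0, 1\],
#'   with genome ids as dimnames.
#' @param cov Symmetric numeric matrix of pairwise alignment coverage
#'   fractions, same dimnames as `ani`.
#' @param genomes Data frame with columns `genome_id`, `completeness`,
#'   `contamination`, `genome_length`.
#' @param coarse_ani,fine_ani ANI thresholds for the two passes.
#' @param min_cov Minimum alignment coverage for an edge in either pass.
#' @param quality_weight Contamination penalty in the representative score.
#' @return Data frame with columns `cluster_id`, `genome_id`,
#'   `representative_id`, one row per genome; clusters partition the input.
#' @export
dereplicate <- function(ani, cov, genomes, coarse_ani = 0.90, fine_ani = 0.95,
                        min_cov = 0.60, quality_weight = 5) {
  ids <- rownames(ani)
  stop_if_not(!is.null(ids) && identical(ids, colnames(ani)),
              "ani must have matching row/col genome ids")
  stop_if_not(identical(dimnames(ani), dimnames(cov)),
              "ani and cov must share dimnames")
  stop_if_not(max(abs(ani - t(ani))) < 1e-8, "ani matrix must be symmetric")
  stop_if_not(max(abs(cov - t(cov))) < 1e-8, "cov matrix must be symmetric")
  stop_if_not(all(ids %in% genomes$genome_id), "genome metadata missing ids")

  meta <- genomes[match(ids, genomes$genome_id), ]

  components_at <- function(sub_ids, ani_thr) {
    a <- ani[sub_ids, sub_ids, drop = FALSE]
    v <- cov[sub_ids, sub_ids, drop = FALSE]
    adj <- (a >= ani_thr) & (v >= min_cov)
    diag(adj) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    split(sub_ids, comp)
  }

  coarse <- components_at(ids, coarse_ani)
  fine <- list()
  for (cc in coarse) fine <- c(fine, components_at(cc, fine_ani))

  pick_representative <- function(members) {
    m <- meta[match(members, meta$genome_id), ]
    score <- m$completeness - quality_weight * m$contamination
    ord <- order(-score, -m$genome_length, m$genome_id)
    members[ord[1]]
  }

  fine <- fine[order(vapply(fine, function(m) sort(m)[1], character(1)))]
  out <- do.call(rbind, lapply(seq_along(fine), function(i) {
    members <- sort(fine[[i]])
    data.frame(cluster_id = sprintf("cluster_%03d", i),
               genome_id = members,
               representative_id = pick_representative(members),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Join bacterial and archaeal trees at the root
#'
#' Domain-level reference trees are built independently for Bacteria and
#' Archaea; this links the two rooted subtrees through a new root with a
#' total inter-domain bridge of `bridge` substitutions/site (split equally
#' across the two root edges, so only path lengths through the root are
#' affected). Intra-domain patristic distances are unchanged.
#'
#' @param bacteria,archaea Rooted trees of class `phylo` with disjoint
#'   leaf sets.
#' @param bridge Total branch length inserted between the two subtree
#'   roots (default 0.122, the standard bacteria-archaea linking distance).
#' @return A rooted `phylo` tree over the union of leaves.
#' @export
join_domain_trees <- function(bacteria, archaea, bridge = 0.122) {
  stop_if_not(inherits(bacteria, "phylo") && inherits(archaea, "phylo"),
              "inputs must be phylo trees")
  stop_if_not(length(intersect(bacteria$tip.label, archaea$tip.label)) == 0,
              "leaf sets must be disjoint")
  half <- bridge / 2
  t1 <- bacteria; t2 <- archaea
  n1 <- length(t1$tip.label); n2 <- length(t2$tip.label)
  n <- n1 + n2
  root <- n + 1L
  # renumber: tips first (t1 then t2), new root, then internal nodes of each
  f1 <- function(v) ifelse(v <= n1, v, root + (v - n1))
  f2 <- function(v) ifelse(v <= n2, n1 + v, root + t1$Nnode + (v - n2))
  e1 <- matrix(f1(t1$edge), ncol = 2)
  e2 <- matrix(f2(t2$edge), ncol = 2)
  root1 <- f1(n1 + 1L)
  root2 <- f2(n2 + 1L)
  edge <- rbind(c(root, root1), c(root, root2), e1, e2)
  edge_len <- c(half + (t1$root.edge %||% 0), half + (t2$root.edge %||% 0),
                t1$edge.length, t2$edge.length)
  joined <- structure(list(edge = edge,
                           edge.length = edge_len,
                           tip.label = c(t1$tip.label, t2$tip.label),
                           Nnode = t1$Nnode + t2$Nnode + 1L),
                      class = "phylo", order = "cladewise")
  joined
}

# minimal single-tip tree: one edge of length `stem` from root to the tip
single_tip_tree <- function(label, stem = 0) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2),
                 edge.length = stem,
                 tip.label = label,
                 Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique tree path between two tips.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param g1,g2 Tip labels.
#' @return Non-negative numeric distance; 0 iff `g1 == g2`.
#' @export
patristic_distance <- function(tree, g1, g2) {
  stop_if_not(all(c(g1, g2) %in% tree$tip.label), "unknown leaf")
  if (g1 == g2) return(0)
  i <- match(g1, tree$tip.label)
  j <- match(g2, tree$tip.label)
  d <- ape::dist.nodes(tree)
  unname(d[i, j])
}

#' Mean pairwise phylogenetic distance of a community
#'
#' Average patristic distance over all unordered pairs of member genomes.
#'
#' @param tree A `phylo` tree containing all members as tips.
#' @param members Character vector of >= 2 genome ids.
#' @param dist_matrix Optional precomputed cophenetic matrix (tips x tips)
#'   to avoid repeated tree traversal when typing many communities.
#' @return Mean pairwise patristic distance.
#' @export
mean_community_pd <- function(tree, members, dist_matrix = NULL) {
  members <- unique(members)
  stop_if_not(length(members) >= 2, "community must have >= 2 members")
  if (is.null(dist_matrix)) dist_matrix <- ape::cophenetic.phylo(tree)
  stop_if_not(all(members %in% rownames(dist_matrix)), "unknown leaf")
  d <- dist_matrix[members, members]
  mean(d[upper.tri(d)])
}
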
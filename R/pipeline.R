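# One-call synthetic-world pipeline: generate inputs, profile, infer the
# co-activity network, cluster, score cross-feeding, and type communities.

#' Run the full co-activity / cross-feeding pipeline on a synthetic world
#'
#' Generates a seeded synthetic world (genome table, domain trees, planted
#' co-active communities with one obligate cross-feeding each, omics
#' coverage tables), then runs every downstream stage: activity matrices
#' (breadth detection, observation filter, CLR), direct-association
#' network inference, Markov clustering, constraint-based cross-feeding
#' scores per recovered community, and null-model community typing.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param n_genomes Number of genomes in the world.
#' @param n_samples Number of samples.
#' @param planted_sizes Sizes of the planted co-active communities
#'   (default: three pairs; see the vignette for why pairs are the
#'   canonical recoverable plan under conditional-independence pruning).
#' @param noise Activity noise dispersion (lognormal sdlog).
#' @param alpha,max_k,n_obs_min Network inference parameters.
#' @param inflation MCL inflation.
#' @param n_random Random communities for the typing null (>= 30).
#' @return List with the world, matrices, network, clustering, recovery
#'   Rand index, per-community score reports, typing table and planted
#'   exchange flags.
#' @export
run_coactivity_pipeline <- function(seed = 1, n_genomes = 30, n_samples = 40,
                                    planted_sizes = c(2, 2, 2), noise = 0.25,
                                    alpha = 0.01, max_k = 3, n_obs_min = 10,
                                    inflation = 1.5, n_random = 30) {
  ids <- sprintf("G%04d", seq_len(n_genomes))
  stopifnot(sum(planted_sizes) <= n_genomes)

  # --- planted co-active communities + one obligate cross-feed each
  cut_points <- cumsum(c(0, planted_sizes))
  plans <- lapply(seq_along(planted_sizes), function(i) {
    members <- ids[(cut_points[i] + 1):cut_points[i + 1]]
    list(community_id = paste0("planted_", i), member_genomes = members,
         loadings = stats::setNames(rep(1, length(members)), members),
         sample_support = sprintf("S%02d", seq_len(min(25, n_samples))))
  })
  xf_mets <- c("aa3_e", "aa4_e", "thb_e")
  xf <- do.call(rbind, lapply(seq_along(plans), function(i) {
    m <- plans[[i]]$member_genomes
    data.frame(donor = m[1], receiver = m[2],
               metabolite = xf_mets[(i - 1) %% length(xf_mets) + 1],
               obligate = TRUE, stringsAsFactors = FALSE)
  }))

  # --- world
  specs <- data.frame(category_id = sprintf("cat%02d", 1:5),
                      c = c(0.1, 0.05, 0.2, 0.08, 0.12),
                      beta = c(1.0, 1.25, 0.9, 1.1, 1.0), sigma = 0.1)
  gt <- gen_genome_table(n_genomes, specs, seed = derive_seed(seed, 1))
  gt$genomes$genome_id <- ids  # align ids with the plan labels
  gt$annotations$genome_id <- rep(ids, nrow(specs))
  domains <- stats::setNames(gt$genomes$domain, ids)
  trees <- gen_phylogeny(ids, domains, seed = derive_seed(seed, 2))
  joined <- if (length(trees) == 2)
    join_domain_trees(trees$Bacteria, trees$Archaea) else trees[[1]]
  omics <- gen_omics_profiles(ids, plans, n_samples, noise = noise,
                              seed = derive_seed(seed, 3))
  models_world <- gen_toy_models(ids, xf, seed = derive_seed(seed, 4))

  # --- profiling
  mats <- build_matrices(omics$metaG, omics$metaT, n_obs_min = n_obs_min,
                         normalization = "none")
  act_clr <- clr_transform(mats$activity)

  # --- network + clustering
  net <- infer_network(act_clr, alpha = alpha, max_k = max_k,
                       n_obs_min = n_obs_min)
  clus <- mcl_cluster(net, inflation = inflation)

  truth_membership <- stats::setNames(rep(NA_integer_, n_genomes), ids)
  for (i in seq_along(plans))
    truth_membership[plans[[i]]$member_genomes] <- i
  shared <- intersect(names(clus$membership), ids)
  ri <- rand_index(truth_membership[shared], clus$membership[shared])

  # --- metabolic scoring of recovered communities
  pd_mat <- ape::cophenetic.phylo(joined)
  reports <- list()
  for (i in seq_along(clus$communities)) {
    members <- clus$communities[[i]]
    if (length(members) < 2 || length(members) > 6) next
    mods <- models_world$models[members]
    recs <- detailed_scores(mods)
    cs <- community_scores(recs, length(members))
    ann <- gt$annotations[gt$annotations$genome_id %in% members &
                            gt$annotations$count > 0, ]
    ko_sets <- split(ann$category_id, ann$genome_id)
    reports[[i]] <- list(
      community_id = sprintf("coact_%02d", i), members = members,
      records = recs, sum_score = cs$sum_score,
      normalized_score = cs$normalized_score,
      mean_pd = mean_community_pd(joined, members, pd_mat),
      gini = if (length(ko_sets) >= 2) functional_gini(ko_sets)$gini
             else NA_real_)
  }

  # --- planted exchange recovery
  xf$recovered <- vapply(seq_len(nrow(xf)), function(r) {
    for (rep in reports) {
      hit <- rep$records$donor == xf$donor[r] &
        rep$records$receiver == xf$receiver[r] &
        rep$records$metabolite == xf$metabolite[r]
      if (any(hit) && any(rep$records$smetana[hit] > 0)) return(TRUE)
    }
    FALSE
  }, logical(1))

  # --- null-model typing
  sizes <- vapply(reports, function(r) length(r$members), numeric(1))
  typing <- NULL; thr <- NULL
  if (length(reports) >= 1 && n_random >= 30) {
    pool <- rownames(mats$activity)
    rand_comms <- sample_random_communities(pool, sizes, n_random,
                                            seed = derive_seed(seed, 5))
    null_pd <- vapply(rand_comms, function(m)
      mean_community_pd(joined, m, pd_mat), numeric(1))
    null_score <- vapply(rand_comms, function(m) {
      recs <- detailed_scores(models_world$models[m])
      community_scores(recs, length(m))$normalized_score
    }, numeric(1))
    thr <- null_thresholds(null_pd, null_score)
    typing <- data.frame(
      community_id = vapply(reports, `[[`, character(1), "community_id"),
      n_members = sizes,
      mean_pd = vapply(reports, `[[`, numeric(1), "mean_pd"),
      normalized_score = vapply(reports, `[[`, numeric(1),
                                "normalized_score"),
      gini = vapply(reports, `[[`, numeric(1), "gini"),
      stringsAsFactors = FALSE)
    typing$type <- classify_community(typing$mean_pd,
                                      typing$normalized_score, thr)
  }

  list(genomes = gt, trees = trees, joined_tree = joined, omics = omics,
       models_world = models_world, matrices = mats, network = net,
       clustering = clus, rand_index = ri, reports = reports,
       planted_exchanges = xf, thresholds = thr, typing = typing)
}
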
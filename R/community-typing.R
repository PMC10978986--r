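# Null-model community typing and community-level functional statistics.

#' Sample random communities from a genome pool
#'
#' Draws `n` communities by uniform sampling without replacement within
#' each community; community sizes are resampled from the observed
#' co-active community size multiset (or drawn uniformly from
#' `size_range` when given).
#'
#' @param pool Character vector of genome ids.
#' @param sizes Multiset of observed community sizes to resample.
#' @param n Number of random communities.
#' @param seed Integer seed.
#' @param size_range Optional c(min, max) for uniform sizes instead.
#' @return List of character vectors.
#' @export
sample_random_communities <- function(pool, sizes, n, seed = 1,
                                      size_range = NULL) {
  stop_if_not(max(sizes) <= length(pool), "community size exceeds pool")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      k <- if (is.null(size_range)) sizes[sample.int(length(sizes), 1)]
           else sample(size_range[1]:size_range[2], 1)
      sort(sample(pool, k))
    })
  })
}

#' Null thresholds for community typing
#'
#' Quantiles of the random-community null: the 5th percentile of mean
#' phylogenetic distance and the 95th percentile of the normalized
#' cross-feeding (SMETANA) score, with linear-interpolation quantiles
#' (type 7) for reproducibility.
#'
#' @param null_pd Mean phylogenetic distances of random communities.
#' @param null_score Normalized scores of random communities.
#' @return List of class `null_thresholds`: `pd_q05`, `score_q95`,
#'   `n_random`.
#' @export
null_thresholds <- function(null_pd, null_score) {
  stop_if_not(length(null_pd) >= 30 && length(null_score) >= 30,
              "need >= 30 random communities")
  structure(list(pd_q05 = unname(stats::quantile(null_pd, 0.05, type = 7)),
                 score_q95 = unname(stats::quantile(null_score, 0.95,
                                                    type = 7)),
                 n_random = length(null_pd)),
            class = "null_thresholds")
}

#' Classify a community against the random-community null
#'
#' Low phylogenetic distance (LPD) when the mean pairwise phylogenetic
#' distance is below the null 5th percentile (smaller than 95% of random
#' communities), high cross-feeding potential (HCP) when the normalized
#' score exceeds the null 95th percentile; the four labels are the
#' quadrants LPD/HPD x LCP/HCP.
#'
#' @param mean_pd Mean phylogenetic distance(s).
#' @param normalized_score Normalized SMETANA score(s).
#' @param thresholds A `null_thresholds`.
#' @return Character vector in
#'   `c("LPD-LCP", "LPD-HCP", "HPD-LCP", "HPD-HCP")`.
#' @export
classify_community <- function(mean_pd, normalized_score, thresholds) {
  pd_lab <- ifelse(mean_pd < thresholds$pd_q05, "LPD", "HPD")
  cp_lab <- ifelse(normalized_score > thresholds$score_q95, "HCP", "LCP")
  paste(pd_lab, cp_lab, sep = "-")
}

#' Functional Gini coefficient of a community
#'
#' The functional capital of each member is the number of occurring KOs
#' (KOs present in at least one member) that it carries; the bias-corrected
#' Gini index of these capitals is
#' `sum_{i,j} |x_i - x_j| / (2 n (n-1) mean(x))`, so perfectly even
#' capitals give 0 and a single functional holder gives exactly 1. The
#' uncorrected (n^2 denominator) variant is available via `corrected =
#' FALSE`.
#'
#' @param ko_sets Named list (member genome -> character vector of KOs),
#'   or a numeric vector of precomputed capitals.
#' @param corrected Use the n(n-1) denominator (default TRUE).
#' @return List with `gini` and `capitals`.
#' @export
functional_gini <- function(ko_sets, corrected = TRUE) {
  if (is.numeric(ko_sets)) {
    x <- ko_sets
  } else {
    stop_if_not(length(ko_sets) >= 2, "community must have >= 2 members")
    occurring <- unique(unlist(ko_sets))
    x <- vapply(ko_sets, function(s) length(intersect(s, occurring)),
                numeric(1))
  }
  n <- length(x)
  stop_if_not(n >= 2, "need >= 2 capitals")
  stop_if_not(any(x > 0), "all capitals zero")
  num <- sum(abs(outer(x, x, "-")))
  den <- 2 * n * (if (corrected) n - 1 else n) * mean(x)
  list(gini = num / den, capitals = x)
}

#' Functional Jaccard distance between two genomes
#'
#' `1 - |A inter B| / |A union B|` over KO presence sets; in expressed
#' mode the sets are first restricted to KOs whose expression was detected
#' in at least `min_samples` samples.
#'
#' @param ko_a,ko_b Character vectors of KO ids.
#' @param expressed_mode Restrict to expressed KOs.
#' @param expression_detection Data frame (ko, n_samples_detected), needed
#'   in expressed mode.
#' @param min_samples Detection threshold for an expressed KO.
#' @return Jaccard distance in \[0, 1\].
#' @export
functional_jaccard <- function(ko_a, ko_b, expressed_mode = FALSE,
                               expression_detection = NULL,
                               min_samples = 10) {
  if (expressed_mode) {
    stop_if_not(!is.null(expression_detection),
                "expression table needed in expressed mode")
    expressed <- expression_detection$ko[
      expression_detection$n_samples_detected >= min_samples]
    ko_a <- intersect(ko_a, expressed)
    ko_b <- intersect(ko_b, expressed)
  }
  u <- union(ko_a, ko_b)
  stop_if_not(length(u) > 0, "both KO sets empty")
  1 - length(intersect(ko_a, ko_b)) / length(u)
}

#' Community-by-category matrix of summed exchange scores
#'
#' Sums the SMETANA score of each community's cross-feeding records within
#' broad metabolite categories; unmapped metabolites fall into the
#' `"uncategorized"` column, so row sums equal the community sum scores.
#'
#' @param records Data frame with `community_id`, `metabolite`, `smetana`.
#' @param category_map Data frame (metabolite, category).
#' @return Numeric matrix, communities x categories.
#' @export
exchange_category_profile <- function(records, category_map) {
  cats <- categorize_metabolites(records$metabolite, category_map)
  all_cats <- unique(c(category_map$category, "uncategorized"))
  comms <- sort(unique(records$community_id))
  m <- matrix(0, length(comms), length(all_cats),
              dimnames = list(comms, all_cats))
  for (r in seq_len(nrow(records)))
    m[records$community_id[r], cats[r]] <-
      m[records$community_id[r], cats[r]] + records$smetana[r]
  m[, colSums(m) > 0 | all_cats != "uncategorized", drop = FALSE]
}

#' Significance stars for corrected p values
#' @param p Numeric vector of p values.
#' @return `"****"` for p <= 1e-4, `"***"` for p <= 1e-3, `"**"` for
#'   p <= 1e-2, `"*"` for p <= 0.05, else `"ns"`.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Per-metabolite exchange-score tests between community types
#'
#' Two-sided Mann-Whitney U tests of the per-community summed exchange
#' score of each metabolite between two groups of communities, BH-corrected
#' across metabolites, with significance stars by the usual convention.
#'
#' @param records Data frame (community_id, metabolite, smetana).
#' @param groups Named list of two character vectors of community ids.
#' @return Data frame (metabolite, u_statistic, p_value, p_bh, stars);
#'   degenerate metabolites (all-tied scores) are kept with NA p.
#' @export
per_metabolite_tests <- function(records, groups) {
  stop_if_not(length(groups) == 2, "exactly two groups")
  stop_if_not(all(lengths(groups) >= 3), "need >= 3 communities per group")
  mets <- sort(unique(records$metabolite))
  score_of <- function(comms, met) {
    vapply(comms, function(cc)
      sum(records$smetana[records$community_id == cc &
                            records$metabolite == met]), numeric(1))
  }
  rows <- lapply(mets, function(met) {
    a <- score_of(groups[[1]], met); b <- score_of(groups[[2]], met)
    if (length(unique(c(a, b))) == 1)
      return(data.frame(metabolite = met, u_statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    data.frame(metabolite = met, u_statistic = unname(wt$statistic),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, "BH")
  out$stars <- ifelse(is.na(out$p_bh), "ns", p_stars(out$p_bh))
  out
}

#' NMDS ordination of community exchange profiles
#'
#' Non-metric multidimensional scaling (stress minimization with monotone
#' regression) of the community x category exchange matrix under
#' Bray-Curtis dissimilarity.
#'
#' @param profile Community x category non-negative matrix (>= 4 rows).
#' @param dims Embedding dimension.
#' @param seed Integer seed (NMDS restarts are stochastic).
#' @return List with `points` (communities x dims) and `stress`.
#' @export
nmds_ordination <- function(profile, dims = 2, seed = 1) {
  stop_if_not(nrow(profile) >= 4, "need >= 4 communities")
  stop_if_not(all(rowSums(profile) > 0), "all-zero community rows")
  with_seed(seed, {
    fit <- vegan::metaMDS(profile, distance = "bray", k = dims,
                          trymax = 20, trace = 0, autotransform = FALSE)
    list(points = fit$points, stress = fit$stress)
  })
}

#' Compare donor versus non-donor genomes
#'
#' Donors are genomes appearing as donor in at least one cross-feeding
#' record (optionally restricted to metabolite categories of interest,
#' e.g. amino acids and B vitamins). Two-sided Mann-Whitney U tests
#' compare closeness centrality in the co-activity network and
#' completeness-corrected genome size between donors and non-donors.
#'
#' @param net An `assoc_network`.
#' @param records Cross-feeding records (donor, metabolite, smetana > 0).
#' @param genomes Genome metadata (genome_id, genome_length, completeness).
#' @param categories Optional metabolite categories to restrict donors to.
#' @param category_map Needed when `categories` given.
#' @return Data frame with one row per comparison (centrality, size):
#'   medians, U statistic, raw and BH-corrected p values; NULL (with a
#'   message) when either group is empty.
#' @export
donor_summaries <- function(net, records, genomes, categories = NULL,
                            category_map = NULL) {
  recs <- records[records$smetana > 0, , drop = FALSE]
  if (!is.null(categories)) {
    stop_if_not(!is.null(category_map), "category_map needed")
    recs <- recs[categorize_metabolites(recs$metabolite, category_map)
                 %in% categories, , drop = FALSE]
  }
  donors <- intersect(unique(recs$donor), net$nodes)
  non_donors <- setdiff(net$nodes, donors)
  if (length(donors) == 0 || length(non_donors) == 0) {
    message("donor/non-donor comparison skipped: one group empty")
    return(NULL)
  }
  cc <- closeness_centrality(net)
  size <- completeness_corrected(genomes$genome_length, genomes$completeness)
  names(size) <- genomes$genome_id
  one <- function(metric, vals) {
    a <- vals[donors]; b <- vals[non_donors]
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    data.frame(metric = metric, median_donor = stats::median(a),
               median_non_donor = stats::median(b),
               u_statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("closeness_centrality", cc),
               one("corrected_genome_size", size[net$nodes]))
  out$p_bh <- stats::p.adjust(out$p_value, "BH")
  out
}
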
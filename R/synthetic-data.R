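# Synthetic inputs with planted ground truth for every pipeline stage.

# Evaluate code under a temporary RNG state so generators are deterministic
# under their seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

#' Generate a genome metadata and annotation-count table
#'
#' Draws total gene counts per genome log-uniformly over at least one order
#' of magnitude, then per-category gene counts from power laws of the total
#' count: `log10(y) = log10(c) + beta * log10(x) + Normal(0, sigma)`,
#' rounded half-up to non-negative integers. A designated genome subset can
#' receive per-category log10 offsets (planted enrichment); those genomes
#' are flagged in the output and in the truth record.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param specs Data frame with columns `category_id`, `c` (> 0), `beta`,
#'   `sigma` (>= 0).
#' @param group_shifts Named numeric vector, category -> log10 offset,
#'   applied to the shifted subset (default: none).
#' @param shifted_fraction Fraction of genomes receiving the shifts.
#' @param total_range Range of total gene counts (log-uniform draw).
#' @param completeness_range,contamination_range Quality metric ranges.
#' @param seed Integer seed.
#' @return List with `genomes` (metadata incl. quality class and
#'   `shifted` flag), `annotations` (genome_id, category_id, count, and
#'   `total_genes`), and `truth` (specs, shifts, shifted ids).
#' @export
gen_genome_table <- function(n_genomes, specs, group_shifts = NULL,
                             shifted_fraction = 0.5,
                             total_range = c(1000, 20000),
                             completeness_range = c(0.7, 1.0),
                             contamination_range = c(0, 0.08),
                             seed = 1) {
  stop_if_not(n_genomes >= 2, "need >= 2 genomes")
  stop_if_not(nrow(specs) > 0, "empty spec list")
  stop_if_not(all(specs$c > 0), "non-positive power-law prefactor c")
  stop_if_not(all(specs$sigma >= 0), "negative sigma")
  with_seed(seed, {
    ids <- sprintf("G%04d", seq_len(n_genomes))
    x <- round(10^stats::runif(n_genomes, log10(total_range[1]),
                               log10(total_range[2])))
    shifted <- rep(FALSE, n_genomes)
    if (!is.null(group_shifts) && length(group_shifts) > 0) {
      n_shift <- max(1L, round(shifted_fraction * n_genomes))
      shifted[sample.int(n_genomes, n_shift)] <- TRUE
    }
    ann <- list()
    for (k in seq_len(nrow(specs))) {
      s <- specs[k, ]
      ly <- log10(s$c) + s$beta * log10(x) +
        stats::rnorm(n_genomes, 0, s$sigma)
      if (!is.null(group_shifts) && s$category_id %in% names(group_shifts))
        ly[shifted] <- ly[shifted] + group_shifts[[s$category_id]]
      ann[[k]] <- data.frame(genome_id = ids, category_id = s$category_id,
                             count = pmax(0, round_half_up(10^ly)),
                             total_genes = x, stringsAsFactors = FALSE)
    }
    completeness <- stats::runif(n_genomes, completeness_range[1],
                                 completeness_range[2])
    contamination <- stats::runif(n_genomes, contamination_range[1],
                                  contamination_range[2])
    genomes <- data.frame(
      genome_id = ids,
      completeness = completeness,
      contamination = contamination,
      genome_length = x * 1000L,
      n_cds = x,
      domain = sample(c("Bacteria", "Archaea"), n_genomes, TRUE,
                      prob = c(0.9, 0.1)),
      source_class = sample(c("MAG", "WGS", "SAG"), n_genomes, TRUE,
                            prob = c(0.6, 0.3, 0.1)),
      quality_class = classify_quality(completeness, contamination),
      shifted = shifted,
      stringsAsFactors = FALSE)
    list(genomes = genomes,
         annotations = do.call(rbind, ann),
         truth = list(specs = specs, group_shifts = group_shifts,
                      shifted_ids = ids[shifted]))
  })
}

#' Generate random domain phylogenies
#'
#' One random bifurcating tree per domain (Bacteria/Archaea) with the
#' given genomes as leaves and positive branch lengths; single-genome
#' domains yield a one-tip tree. Deterministic under seed.
#'
#' @param genome_ids Character vector of unique leaf names.
#' @param domain_labels Named character vector genome_id -> domain.
#' @param seed Integer seed.
#' @return Named list of `phylo` trees, one per domain present.
#' @export
gen_phylogeny <- function(genome_ids, domain_labels, seed = 1) {
  stop_if_not(!anyDuplicated(genome_ids), "duplicate leaf names")
  stop_if_not(all(genome_ids %in% names(domain_labels)),
              "every genome needs a domain label")
  with_seed(seed, {
    out <- list()
    for (dom in unique(unname(domain_labels[genome_ids]))) {
      tips <- genome_ids[domain_labels[genome_ids] == dom]
      out[[dom]] <- if (length(tips) == 1) {
        single_tip_tree(tips, stem = stats::runif(1, 0.05, 0.5))
      } else {
        tr <- ape::rtree(length(tips), tip.label = sample(tips))
        tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 0.5)
        tr
      }
    }
    out
  })
}

#' Generate metagenomic and metatranscriptomic coverage tables
#'
#' Emulates per-sample genome coverage for both omics layers. Metagenomic
#' depths are weakly structured (independent lognormal); activity
#' (metatranscriptomic/metagenomic depth ratio) carries the planted
#' structure: within each community plan's support samples, member
#' activities co-vary through a shared lognormal latent factor scaled by
#' per-member loadings, with multiplicative lognormal noise of dispersion
#' `noise`. Outside support, activity is independent background.
#' Metagenomic breadth is drawn above the 30% detection rule for planted
#' members in their support samples and broadly (0.05-0.95) elsewhere.
#' Per-sample depths are closed to a fixed total (compositional closure).
#'
#' @param genome_ids Character vector of genome ids.
#' @param plans List of community plans, each a list with `community_id`,
#'   `member_genomes` (>= 2), `loadings` (named positive weights, default
#'   1), `sample_support` (sample ids).
#' @param n_samples Number of samples (ids `S01`, ...).
#' @param noise Lognormal dispersion (sdlog) of activity noise.
#' @param seed Integer seed.
#' @param sample_total Per-sample depth total after closure.
#' @return List with `metaG` and `metaT` coverage data frames (genome_id,
#'   sample_id, depth, breadth), `truth` (the plans), and
#'   `overlapping_members` flag (TRUE when plans share genomes).
#' @export
gen_omics_profiles <- function(genome_ids, plans, n_samples, noise = 0.2,
                               seed = 1, sample_total = 100) {
  samples <- sprintf("S%02d", seq_len(n_samples))
  all_members <- unlist(lapply(plans, `[[`, "member_genomes"))
  stop_if_not(all(all_members %in% genome_ids),
              "plan references unknown genome")
  for (p in plans) {
    stop_if_not(length(p$member_genomes) >= 2, "plans need >= 2 members")
    stop_if_not(all(p$sample_support %in% samples),
                "plan references unknown sample")
  }
  overlapping <- anyDuplicated(all_members) > 0
  ng <- length(genome_ids); ns <- n_samples
  with_seed(seed, {
    depth_g <- matrix(stats::rlnorm(ng * ns, meanlog = 1, sdlog = 0.4),
                      ng, ns, dimnames = list(genome_ids, samples))
    breadth_g <- matrix(stats::runif(ng * ns, 0.05, 0.95), ng, ns,
                        dimnames = list(genome_ids, samples))
    activity <- matrix(stats::rlnorm(ng * ns, meanlog = 0, sdlog = 0.5),
                       ng, ns, dimnames = list(genome_ids, samples))
    for (p in plans) {
      loadings <- p$loadings %||%
        stats::setNames(rep(1, length(p$member_genomes)), p$member_genomes)
      stop_if_not(all(loadings > 0), "loadings must be positive")
      latent <- stats::setNames(
        stats::rlnorm(length(p$sample_support), 0, 1), p$sample_support)
      for (g in p$member_genomes) for (s in p$sample_support) {
        activity[g, s] <- loadings[[g]] * latent[[s]] *
          stats::rlnorm(1, 0, noise)
        breadth_g[g, s] <- stats::runif(1, 0.55, 0.95)
      }
    }
    depth_t <- activity * depth_g
    breadth_t <- pmin(0.95, breadth_g * stats::runif(ng * ns, 0.5, 1.0))
    close_cols <- function(m) sweep(m, 2, colSums(m) / sample_total, "/")
    depth_g <- close_cols(depth_g)
    depth_t <- close_cols(depth_t)
    long <- function(depth, breadth) data.frame(
      genome_id = rep(genome_ids, ns),
      sample_id = rep(samples, each = ng),
      depth = as.vector(depth), breadth = as.vector(breadth),
      stringsAsFactors = FALSE)
    list(metaG = long(depth_g, breadth_g),
         metaT = long(depth_t, breadth_t),
         truth = plans, overlapping_members = overlapping)
  })
}

#' Generate synthetic alignment summary records
#'
#' Draws alignment records (read length L, edit distance NM, ambiguous
#' reference bases XN, MAPQ, position span) with internally consistent
#' fields (0 <= XN <= NM <= L) and attaches ground-truth pass/fail labels
#' under the standard specificity filter (MAPQ >= 20 and nucleotide
#' identity 1 - (NM - XN)/L >= 0.95).
#'
#' @param n_records Number of records.
#' @param length_range Integer range of read lengths.
#' @param identity_range Range of true identities used to draw NM.
#' @param mapq_range Integer MAPQ range.
#' @param ambiguous_base_rate Expected fraction of ambiguous reference
#'   bases per read.
#' @param genome_ids,genome_length,sample_ids Mapping targets for spans.
#' @param seed Integer seed.
#' @return Data frame with read_id, genome_id, sample_id, L, NM, XN, MAPQ,
#'   start, end, and logical `truth_pass`.
#' @export
gen_alignment_records <- function(n_records, length_range = c(80L, 150L),
                                  identity_range = c(0.85, 1.0),
                                  mapq_range = c(0L, 42L),
                                  ambiguous_base_rate = 0.005,
                                  genome_ids = c("G0001", "G0002"),
                                  genome_length = 1e5, sample_ids = "S01",
                                  seed = 1) {
  stop_if_not(length_range[1] > 0 && length_range[1] <= length_range[2],
              "invalid length range")
  stop_if_not(identity_range[1] <= identity_range[2] &&
                identity_range[2] <= 1, "invalid identity range")
  with_seed(seed, {
    L <- sample(length_range[1]:length_range[2], n_records, TRUE)
    ident <- stats::runif(n_records, identity_range[1], identity_range[2])
    XN <- stats::rbinom(n_records, L, ambiguous_base_rate)
    NM <- pmin(L, XN + round_half_up((1 - ident) * L))
    MAPQ <- sample(mapq_range[1]:mapq_range[2], n_records, TRUE)
    start <- sample.int(genome_length - max(L), n_records, TRUE)
    rec <- data.frame(
      read_id = sprintf("read%06d", seq_len(n_records)),
      genome_id = sample(genome_ids, n_records, TRUE),
      sample_id = sample(sample_ids, n_records, TRUE),
      L = L, NM = NM, XN = XN, MAPQ = MAPQ,
      start = start, end = start + L,  # 0-based half-open span
      stringsAsFactors = FALSE)
    rec$truth_pass <- rec$MAPQ >= 20 & (1 - (rec$NM - rec$XN) / rec$L) >= 0.95
    rec
  })
}

#' Generate a planted-partition ANI and coverage matrix
#'
#' Within-cluster pairs receive ANI >= 0.95 with alignment coverage
#' >= 0.60; between-cluster pairs receive ANI <= 0.90. Dereplication at the
#' standard thresholds therefore recovers exactly the planted partition.
#'
#' @param cluster_plan List of character vectors (the planted clusters;
#'   must partition the genome ids).
#' @param seed Integer seed.
#' @return List with symmetric matrices `ani`, `cov` and the `truth`
#'   partition.
#' @export
gen_ani_matrix <- function(cluster_plan, seed = 1) {
  ids <- unlist(cluster_plan)
  stop_if_not(!anyDuplicated(ids), "cluster plan must partition genomes")
  n <- length(ids)
  with_seed(seed, {
    ani <- matrix(0, n, n, dimnames = list(ids, ids))
    cov <- matrix(0, n, n, dimnames = list(ids, ids))
    member_of <- stats::setNames(rep(seq_along(cluster_plan),
                                     lengths(cluster_plan)), ids)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      same <- member_of[ids[i]] == member_of[ids[j]]
      ani[i, j] <- if (same) stats::runif(1, 0.96, 0.999)
                   else stats::runif(1, 0.75, 0.88)
      cov[i, j] <- if (same) stats::runif(1, 0.65, 0.95)
                   else stats::runif(1, 0.30, 0.90)
      ani[j, i] <- ani[i, j]; cov[j, i] <- cov[i, j]
    }
    diag(ani) <- 1; diag(cov) <- 1
    list(ani = ani, cov = cov, truth = cluster_plan)
  })
}

#' Write a synthetic world to plain-text files
#'
#' Emits the standard file layout consumed by the pipeline: genomes.tsv,
#' annotations.tsv, ani.tsv, coverage_metaG.tsv, coverage_metaT.tsv,
#' alignments.tsv, trees/*.nwk, models/*.json and truth/*.json (planted
#' ground truth, so downstream recovery tests are self-contained).
#'
#' @param world List with any of `genomes` (from [gen_genome_table()]),
#'   `ani` (from [gen_ani_matrix()]), `omics` (from
#'   [gen_omics_profiles()]), `alignments`, `trees`, `models_world`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_world <- function(world, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(world$genomes)) {
    w(world$genomes$genomes, "genomes.tsv")
    w(world$genomes$annotations, "annotations.tsv")
  }
  if (!is.null(world$ani)) {
    utils::write.table(world$ani$ani, file.path(outdir, "ani.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(world$ani$cov, file.path(outdir, "cov.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(world$omics)) {
    w(world$omics$metaG, "coverage_metaG.tsv")
    w(world$omics$metaT, "coverage_metaT.tsv")
  }
  if (!is.null(world$alignments)) w(world$alignments, "alignments.tsv")
  if (!is.null(world$trees)) {
    dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
    for (dom in names(world$trees))
      ape::write.tree(world$trees[[dom]],
                      file.path(outdir, "trees", paste0(dom, ".nwk")))
  }
  if (!is.null(world$models_world)) {
    dir.create(file.path(outdir, "models"), showWarnings = FALSE)
    for (m in world$models_world$models)
      write_model_json(m, file.path(outdir, "models", paste0(m$id, ".json")))
  }
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  truths <- list(
    omics = if (!is.null(world$omics)) world$omics$truth,
    genomes = if (!is.null(world$genomes)) world$genomes$truth,
    ani = if (!is.null(world$ani)) world$ani$truth,
    crossfeed = if (!is.null(world$models_world)) world$models_world$truth)
  jsonlite::write_json(truths[!vapply(truths, is.null, logical(1))],
                       file.path(outdir, "truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
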
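# Community-level competition and cross-feeding scores on stoichiometric
# models, computed by exhaustive enumeration at toy scale.

#' Metabolic resource overlap (MRO) of a community
#'
#' Quantifies how much community members compete for the same nutrients.
#' For each member, the union of metabolites over all its minimal media
#' (computed in isolation over organic candidates) defines its requirement
#' set M_i; then
#' `MRO = sum_{i<j} |M_i inter M_j| / sum_{i<j} min(|M_i|, |M_j|)`.
#' Identical members give 1, disjoint requirements give 0.
#'
#' @param models Named list of `metabolic_model` (>= 2 members).
#' @param g_min,uptake_max Growth threshold and uptake bound.
#' @return List with `mro` and the per-member requirement sets.
#' @export
mro <- function(models, g_min = 1e-4, uptake_max = 10) {
  stop_if_not(length(models) >= 2, "community must have >= 2 members")
  req <- lapply(models, function(m) {
    mm <- minimal_media(m, g_min = g_min, uptake_max = uptake_max)
    if (!attr(mm, "feasible")) return(NULL)
    sort(unique(unlist(mm)))
  })
  empty <- vapply(req, is.null, logical(1))
  if (any(empty))
    warning("members with no feasible medium excluded: ",
            paste(names(models)[empty], collapse = ", "))
  req <- req[!empty]
  stop_if_not(length(req) >= 2, "fewer than 2 members with feasible media")
  num <- den <- 0
  n <- length(req)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- num + length(intersect(req[[i]], req[[j]]))
    den <- den + min(length(req[[i]]), length(req[[j]]))
  }
  list(mro = if (den == 0) 0 else num / den, requirements = req)
}

#' Metabolic interaction potential (MIP) of a community
#'
#' Number of external metabolites the community can spare through
#' exchanges: the size of the smallest medium supporting growth of every
#' member without any inter-species exchange (private extracellular
#' compartments) minus the size of the smallest medium with a shared
#' extracellular pool. Always >= 0, since sharing only relaxes the
#' non-interacting problem.
#'
#' @param models Named list of `metabolic_model` (>= 2 members).
#' @param g_min,uptake_max Growth threshold and uptake bound.
#' @return List with `mip`, `medium_private`, `medium_shared` (smallest
#'   media found, first in deterministic enumeration order).
#' @export
mip <- function(models, g_min = 1e-4, uptake_max = 10) {
  stop_if_not(length(models) >= 2, "community must have >= 2 members")
  smallest <- function(mode) {
    cm <- community_model(models, mode)
    mm <- minimal_media(cm, g_min = g_min, uptake_max = uptake_max)
    stop_if_not(attr(mm, "feasible"),
                sprintf("community infeasible in %s mode", mode))
    sizes <- lengths(mm)
    mm[[which.min(sizes)]]
  }
  m_priv <- smallest("private")
  m_shared <- smallest("shared")
  list(mip = length(m_priv) - length(m_shared),
       medium_private = m_priv, medium_shared = m_shared)
}

# Minimal donor sets: inclusion-minimal D subsets of C \ {r} such that the
# shared community {r} u D grows (all members) on the medium.
minimal_donor_sets <- function(models, receiver, medium, g_min, uptake_max) {
  others <- setdiff(names(models), receiver)
  grows_with <- function(D) {
    mem <- models[c(receiver, D)]
    if (length(mem) == 1) {
      check_growth(mem[[1]], medium, g_min = g_min,
                   uptake_max = uptake_max)$grows
    } else {
      check_growth(community_model(mem, "shared"), medium,
                   g_min = g_min, uptake_max = uptake_max)$grows
    }
  }
  if (grows_with(character(0))) return(list())  # self-sufficient
  minimal <- list()
  for (k in seq_along(others)) {
    for (s in subsets_of(others, k)) {
      if (is_superset_of_any(s, minimal)) next
      if (grows_with(s)) minimal[[length(minimal) + 1L]] <- s
    }
  }
  minimal
}

# Minimal uptake sets for a member within a community environment:
# inclusion-minimal subsets U of candidate organic uptakes such that the
# member grows alone with organic uptake restricted to U.
minimal_uptake_sets <- function(model, candidates, g_min, uptake_max) {
  minimal <- list()
  for (k in 0:length(candidates)) {
    for (s in subsets_of(candidates, k)) {
      if (is_superset_of_any(s, minimal)) next
      if (check_growth(model, s, g_min = g_min,
                       uptake_max = uptake_max)$grows)
        minimal[[length(minimal) + 1L]] <- s
    }
  }
  minimal
}

#' Detailed pairwise cross-feeding scores (SCS, MUS, MPS, SMETANA)
#'
#' Exhaustive-enumeration implementation of the three component scores for
#' every ordered (donor, receiver) pair and organic metabolite:
#' * SCS (species coupling) - fraction of inclusion-minimal donor sets
#'   (subsets of the community enabling the receiver's growth on the
#'   medium, all members growing) that contain the donor; 0 for receivers
#'   that grow without help.
#' * MUS (metabolite uptake) - fraction of the receiver's inclusion-minimal
#'   organic uptake sets, within the community environment (medium plus
#'   everything other members can secrete), containing the metabolite.
#' * MPS (metabolite production) - 1 when the donor can secrete the
#'   metabolite at non-zero flux on the medium, else 0.
#' The SMETANA score of a record is the product SCS * MUS * MPS. Inorganic
#' metabolites are excluded throughout.
#'
#' @param models Named list of `metabolic_model` (community members).
#' @param medium Organic medium; default: smallest shared-mode community
#'   minimal medium.
#' @param max_members Enumeration guard (default 6).
#' @param g_min,uptake_max Growth threshold and uptake bound.
#' @return Data frame with columns `donor`, `receiver`, `metabolite`,
#'   `scs`, `mus`, `mps`, `smetana`, restricted to records with
#'   `smetana > 0`; the full SCS matrix is attached as attribute `scs`.
#' @export
detailed_scores <- function(models, medium = NULL, max_members = 6,
                            g_min = 1e-4, uptake_max = 10) {
  stop_if_not(length(models) >= 2, "community must have >= 2 members")
  stop_if_not(length(models) <= max_members,
              "community too large for exact enumeration; raise max_members only with care")
  members <- names(models)
  if (is.null(medium)) {
    cm <- community_model(models, "shared")
    mm <- minimal_media(cm, g_min = g_min, uptake_max = uptake_max)
    stop_if_not(attr(mm, "feasible"), "community has no feasible medium")
    medium <- mm[[which.min(lengths(mm))]]
  }
  organics <- organic_exchange_metabolites(models)

  # MPS for all (donor, metabolite)
  mps <- matrix(0, length(members), length(organics),
                dimnames = list(members, organics))
  for (d in members) for (m in organics)
    mps[d, m] <- as.numeric(max_secretion(models[[d]], m, medium,
                                          uptake_max) > 1e-6)

  # SCS for all (donor, receiver)
  scs <- matrix(0, length(members), length(members),
                dimnames = list(members, members))  # donor x receiver
  for (r in members) {
    dsets <- minimal_donor_sets(models, r, medium, g_min, uptake_max)
    if (length(dsets) == 0) next
    for (d in setdiff(members, r))
      scs[d, r] <- mean(vapply(dsets, function(s) d %in% s, logical(1)))
  }

  # MUS per receiver within the community environment
  mus <- matrix(0, length(members), length(organics),
                dimnames = list(members, organics))
  for (r in members) {
    secretable <- organics[colSums(mps[setdiff(members, r), , drop = FALSE]) > 0]
    env <- union(medium, secretable)
    mod_ex <- organic_exchange_metabolites(models[[r]])
    candidates <- sort(intersect(env, mod_ex))
    usets <- minimal_uptake_sets(models[[r]], candidates, g_min, uptake_max)
    if (length(usets) == 0) next
    for (m in candidates)
      mus[r, m] <- mean(vapply(usets, function(s) m %in% s, logical(1)))
  }

  recs <- list()
  for (d in members) for (r in setdiff(members, d)) for (m in organics) {
    sm <- scs[d, r] * mus[r, m] * mps[d, m]
    if (sm > 0)
      recs[[length(recs) + 1L]] <- data.frame(
        donor = d, receiver = r, metabolite = m,
        scs = scs[d, r], mus = mus[r, m], mps = mps[d, m], smetana = sm,
        stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(donor = character(0), receiver = character(0),
               metabolite = character(0), scs = numeric(0), mus = numeric(0),
               mps = numeric(0), smetana = numeric(0))
  attr(out, "scs") <- scs
  attr(out, "medium") <- medium
  out
}

#' Community-level SMETANA sum and normalized score
#'
#' Sums the SMETANA scores of all records of a community and normalizes by
#' the number of potential genome-genome interactions `N * (N - 1) / 2`.
#'
#' @param records Data frame from [detailed_scores()] (needs `smetana`).
#' @param n_members Community size N (>= 2).
#' @return List with `sum_score` and `normalized_score`.
#' @export
community_scores <- function(records, n_members) {
  stop_if_not(n_members >= 2, "N must be >= 2")
  s <- sum(records$smetana)
  list(sum_score = s, normalized_score = s / (n_members * (n_members - 1) / 2))
}
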
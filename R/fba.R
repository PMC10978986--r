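# Constraint-based growth and minimal-medium computations.
#
# All linear programs are flux balance problems: maximize c'v subject to
# S v = 0 and lb <= v <= ub. pracma::linprog expects nonnegative
# variables, so problems are shifted by their lower bounds before solving.

solve_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  res <- .simplex_fba(S, as.numeric(lb), as.numeric(ub), as.numeric(obj),
                      maximize)
  switch(res$status,
         optimal = list(status = "optimal", objective = res$objective,
                        x = res$x),
         infeasible = list(status = "infeasible", objective = NA_real_,
                           x = NULL),
         unbounded = list(status = "error", objective = NA_real_, x = NULL,
                          message = "LP unbounded"),
         list(status = "error", objective = NA_real_, x = NULL,
              message = res$message %||% "LP solver failure"))
}

# Apply a medium to exchange bounds: uptake (negative flux) is opened for
# medium metabolites and for all inorganic environment metabolites, closed
# otherwise; secretion stays open for every exchange.
apply_medium_single <- function(model, mats, medium, uptake_max = 10) {
  inorg <- inorganic_exchange_metabolites(model)
  open <- union(medium, inorg)
  for (rid in exchange_ids(model)) {
    j <- match(rid, mats$rids)
    met <- exchanged_metabolite(model, rid)
    mats$lb[j] <- if (met %in% open) -uptake_max else 0
  }
  mats
}

apply_medium_community <- function(cm, mats, medium, uptake_max = 10) {
  open <- union(medium, cm$inorganic_env)
  for (met in names(cm$env_exchange)) {
    for (rid in cm$env_exchange[[met]]) {
      j <- match(rid, mats$rids)
      mats$lb[j] <- if (met %in% open) -uptake_max else 0
    }
  }
  mats
}

#' Test growth of a model or community on a medium
#'
#' Solves the flux balance linear program: maximize biomass flux subject to
#' steady-state mass balance and flux bounds, with uptake allowed only for
#' medium metabolites (inorganic environment metabolites are always
#' available). A model grows when the optimum reaches `g_min`. For a
#' `community_model` without `species`, growth means simultaneous non-zero
#' growth of every member (each biomass constrained to at least `g_min`);
#' with `species`, that member's biomass is maximized while the others are
#' merely balanced.
#'
#' @param x A `metabolic_model` or `community_model`.
#' @param medium Character vector of organic environment metabolite ids
#'   opened for uptake.
#' @param species Optional member id (community models only).
#' @param g_min Minimum biomass flux counted as growth (default 1e-4).
#' @param uptake_max Uptake bound magnitude for open exchanges.
#' @return List with `grows` (logical), `objective` (max biomass flux or
#'   NA), `status` (LP status). LP solver failures raise an error,
#'   distinctly from infeasibility.
#' @export
check_growth <- function(x, medium = character(0), species = NULL,
                         g_min = 1e-4, uptake_max = 10) {
  if (inherits(x, "metabolic_model")) {
    mats <- model_matrices(x)
    mats <- apply_medium_single(x, mats, medium, uptake_max)
    obj <- as.numeric(mats$rids == x$biomass_id)
    sol <- solve_lp(obj, mats$S, mats$lb, mats$ub)
    if (sol$status == "error") stop("LP solver failure: ", sol$message)
    grows <- sol$status == "optimal" && sol$objective >= g_min
    return(list(grows = grows, objective = sol$objective, status = sol$status))
  }
  stop_if_not(inherits(x, "community_model"), "unsupported model type")
  mats <- community_matrices(x)
  mats <- apply_medium_community(x, mats, medium, uptake_max)
  bio_j <- match(x$biomass_ids, mats$rids)
  if (is.null(species)) {
    mats$lb[bio_j] <- pmax(mats$lb[bio_j], g_min)
    obj <- numeric(length(mats$rids)); obj[bio_j] <- 1
    sol <- solve_lp(obj, mats$S, mats$lb, mats$ub)
    if (sol$status == "error") stop("LP solver failure: ", sol$message)
    return(list(grows = sol$status == "optimal",
                objective = sol$objective, status = sol$status))
  }
  j <- match(x$biomass_ids[[species]], mats$rids)
  obj <- numeric(length(mats$rids)); obj[j] <- 1
  sol <- solve_lp(obj, mats$S, mats$lb, mats$ub)
  if (sol$status == "error") stop("LP solver failure: ", sol$message)
  grows <- sol$status == "optimal" && sol$objective >= g_min
  list(grows = grows, objective = sol$objective, status = sol$status)
}

# Maximal secretion flux of environment metabolite `met` by a single model
# on a medium (no growth requirement: producibility).
max_secretion <- function(model, met, medium, uptake_max = 10) {
  mats <- model_matrices(model)
  mats <- apply_medium_single(model, mats, medium, uptake_max)
  ex <- exchange_ids(model)
  rid <- ex[vapply(ex, function(r) exchanged_metabolite(model, r) == met,
                   logical(1))]
  if (length(rid) == 0) return(0)
  j <- match(rid[1], mats$rids)
  # secretion only: forbid uptake of the metabolite being measured
  mats$lb[j] <- max(mats$lb[j], 0)
  obj <- numeric(length(mats$rids)); obj[j] <- 1
  sol <- solve_lp(obj, mats$S, mats$lb, mats$ub)
  if (sol$status == "error") stop("LP solver failure: ", sol$message)
  if (sol$status != "optimal") 0 else sol$objective
}

#' Enumerate minimal media of a model or community
#'
#' Exhaustive lattice search over subsets of candidate organic environment
#' metabolites, returning every inclusion-minimal subset on which the model
#' (or every community member, in shared mode) grows. Supersets of media
#' already found minimal are pruned. With `weighting = "molweight"`,
#' minimality is by total molecular weight instead: among all
#' inclusion-minimal media, those with the smallest total weight are
#' returned.
#'
#' @param x A `metabolic_model` or `community_model`.
#' @param candidates Candidate metabolite ids; defaults to all organic
#'   exchange metabolites of the model(s).
#' @param weighting `"count"` (cardinality) or `"molweight"`.
#' @param max_candidates Guard on exhaustive enumeration size.
#' @param g_min,uptake_max Passed to [check_growth()].
#' @return List of character vectors (each one minimal medium), possibly
#'   empty when no candidate subset supports growth (flagged via the
#'   `feasible` attribute).
#' @export
minimal_media <- function(x, candidates = NULL,
                          weighting = c("count", "molweight"),
                          max_candidates = 20, g_min = 1e-4,
                          uptake_max = 10) {
  weighting <- match.arg(weighting)
  if (is.null(candidates)) {
    candidates <- if (inherits(x, "community_model"))
      sort(setdiff(names(x$env_exchange), x$inorganic_env))
    else organic_exchange_metabolites(x)
  }
  stop_if_not(length(candidates) <= max_candidates,
              "too many candidate metabolites for exact enumeration")
  grows_on <- function(M)
    check_growth(x, medium = M, g_min = g_min, uptake_max = uptake_max)$grows
  minimal <- list()
  for (k in 0:length(candidates)) {
    for (s in subsets_of(candidates, k)) {
      if (is_superset_of_any(s, minimal)) next
      if (grows_on(s)) minimal[[length(minimal) + 1L]] <- s
    }
  }
  feasible <- length(minimal) > 0
  if (weighting == "molweight" && feasible) {
    mw_tab <- mw_table(x)
    w <- vapply(minimal, function(s) sum(mw_tab[s]), numeric(1))
    stop_if_not(!anyNA(w), "molecular weights missing for some candidates")
    minimal <- minimal[abs(w - min(w)) < 1e-9]
  }
  attr(minimal, "feasible") <- feasible
  minimal
}

mw_table <- function(x) {
  mets <- if (inherits(x, "community_model")) {
    m <- x$metabolites
    stats::setNames(m$mw, sub("@.*$", "", m$id))
  } else stats::setNames(x$metabolites$mw, x$metabolites$id)
  mets[!duplicated(names(mets))]
}
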
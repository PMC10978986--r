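#' Construct a stoichiometric metabolic model
#'
#' A light-weight container for a genome-scale (here: toy-scale)
#' stoichiometric model. Exchange reactions follow the usual convention:
#' their id starts with `"EX_"`, they touch exactly one extracellular
#' metabolite with coefficient -1, and negative flux means uptake from the
#' environment while positive flux means secretion.
#'
#' @param id Model id (conventionally the genome id).
#' @param metabolites Data frame with columns `id`, `name`, `compartment`,
#'   `is_inorganic` (logical), `mw` (molecular weight, g/mol; NA allowed).
#' @param reactions List; each element a list with `id`, `stoich` (named
#'   numeric vector, metabolite id -> coefficient), `lb`, `ub`, `gene_rule`
#'   (character boolean expression over gene ids, `""` for spontaneous), and
#'   optional `transport` (list with `mechanism`, `direction`).
#' @param biomass_id Id of the biomass reaction.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass_id) {
  rids <- vapply(reactions, `[[`, character(1), "id")
  stop_if_not(!anyDuplicated(rids), "duplicate reaction ids")
  stop_if_not(biomass_id %in% rids, "biomass reaction missing")
  stop_if_not(!anyDuplicated(metabolites$id), "duplicate metabolite ids")
  for (r in reactions) {
    stop_if_not(all(names(r$stoich) %in% metabolites$id),
                sprintf("reaction %s references unknown metabolites", r$id))
    stop_if_not(r$lb <= r$ub, sprintf("reaction %s has lb > ub", r$id))
    if (startsWith(r$id, "EX_")) {
      ext <- names(r$stoich)
      stop_if_not(length(ext) == 1 && r$stoich[[1]] == -1,
                  sprintf("exchange %s must consume one metabolite", r$id))
    }
  }
  names(reactions) <- rids
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 biomass_id = biomass_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions (%d exchanges), biomass = %s\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(exchange_ids(x)), x$biomass_id))
  invisible(x)
}

#' Exchange reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids starting with `"EX_"`.
#' @export
exchange_ids <- function(model) {
  rids <- names(model$reactions)
  rids[startsWith(rids, "EX_")]
}

# metabolite consumed by an exchange reaction
exchanged_metabolite <- function(model, rid) names(model$reactions[[rid]]$stoich)

#' Organic exchange metabolites of a model or model list
#'
#' Metabolites with an exchange reaction and `is_inorganic == FALSE`;
#' these are the candidates for minimal-medium enumeration and the only
#' metabolites reported in cross-feeding records.
#' @param models A `metabolic_model` or list of them.
#' @return Character vector of metabolite ids.
#' @export
organic_exchange_metabolites <- function(models) {
  if (inherits(models, "metabolic_model")) models <- list(models)
  out <- character(0)
  for (m in models) {
    mets <- vapply(exchange_ids(m), function(r) exchanged_metabolite(m, r),
                   character(1))
    inorg <- m$metabolites$is_inorganic[match(mets, m$metabolites$id)]
    out <- c(out, mets[!inorg])
  }
  sort(unique(out))
}

inorganic_exchange_metabolites <- function(models) {
  if (inherits(models, "metabolic_model")) models <- list(models)
  out <- character(0)
  for (m in models) {
    mets <- vapply(exchange_ids(m), function(r) exchanged_metabolite(m, r),
                   character(1))
    inorg <- m$metabolites$is_inorganic[match(mets, m$metabolites$id)]
    out <- c(out, mets[inorg])
  }
  sort(unique(out))
}

# Dense stoichiometric matrix (metabolites x reactions) with bounds.
model_matrices <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  lb <- ub <- numeric(length(rids))
  for (j in seq_along(rids)) {
    r <- model$reactions[[j]]
    S[names(r$stoich), j] <- r$stoich
    lb[j] <- r$lb
    ub[j] <- r$ub
  }
  list(S = S, lb = lb, ub = ub, rids = rids, mids = mids)
}

#' Write a metabolic model to JSON
#'
#' Serializes the model to a versioned JSON schema (plain text, stable key
#' order) that round-trips through [read_model_json()].
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    schema = "coactomics-model/1",
    id = model$id,
    biomass_id = model$biomass_id,
    metabolites = model$metabolites,
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id,
           stoich = as.list(r$stoich),
           lb = r$lb, ub = r$ub,
           gene_rule = r$gene_rule %||% "",
           transport = r$transport)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metabolic model from JSON
#' @param path Path written by [write_model_json()].
#' @return A `metabolic_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  stop_if_not(identical(obj$schema, "coactomics-model/1"),
              "unrecognized model schema")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = m$name, compartment = m$compartment,
               is_inorganic = isTRUE(m$is_inorganic),
               mw = if (is.null(m$mw) || is.na(m$mw)) NA_real_ else as.numeric(m$mw),
               stringsAsFactors = FALSE)))
  rxns <- lapply(obj$reactions, function(r) {
    tr <- r$transport
    list(id = r$id,
         stoich = unlist(r$stoich),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         gene_rule = r$gene_rule %||% "",
         transport = if (is.null(tr)) NULL else
           list(mechanism = tr$mechanism, direction = tr$direction))
  })
  metabolic_model(obj$id, mets, rxns, obj$biomass_id)
}

#' Merge member models into a community model
#'
#' Builds a community stoichiometric model from member models. In
#' `"shared"` mode, extracellular metabolites form a single common pool:
#' anything one member secretes can be taken up by another. In `"private"`
#' mode each member keeps its own extracellular compartment, so no
#' metabolite can flow between species (the non-interacting control used
#' by the metabolic interaction potential).
#'
#' @param models List of `metabolic_model` objects with distinct ids.
#' @param mode `"shared"` or `"private"`.
#' @return A list of class `community_model` with the merged matrices,
#'   per-member biomass reaction ids, and the community exchange reaction
#'   ids per environment metabolite.
#' @export
community_model <- function(models, mode = c("shared", "private")) {
  mode <- match.arg(mode)
  ids <- vapply(models, `[[`, character(1), "id")
  stop_if_not(!anyDuplicated(ids), "duplicate member model ids")
  met_rows <- list(); rxn_cols <- list()
  # community environment metabolite -> exchange id bookkeeping
  env_exchange <- list()  # env met id -> vector of exchange column ids
  biomass_ids <- character(0)
  for (m in models) {
    suf <- paste0("@", m$id)
    is_ex_met <- m$metabolites$compartment == "e"
    met_map <- m$metabolites$id
    names(met_map) <- m$metabolites$id
    if (mode == "shared") {
      met_map[!is_ex_met] <- paste0(m$metabolites$id[!is_ex_met], suf)
    } else {
      met_map[] <- paste0(m$metabolites$id, suf)
    }
    mm <- m$metabolites
    mm$community_id <- unname(met_map[mm$id])
    mm$member <- m$id
    met_rows[[m$id]] <- mm
    for (r in m$reactions) {
      st <- r$stoich
      names(st) <- unname(met_map[names(st)])
      is_ex <- startsWith(r$id, "EX_")
      new_id <- if (is_ex && mode == "shared")
        r$id else paste0(r$id, suf)
      if (is_ex) {
        env_met <- exchanged_metabolite(m, r$id)  # original (shared) id
        env_exchange[[env_met]] <- unique(c(env_exchange[[env_met]], new_id))
      }
      if (!is.null(rxn_cols[[new_id]])) next  # shared EX already added
      rxn_cols[[new_id]] <- list(id = new_id, stoich = st, lb = r$lb,
                                 ub = r$ub, gene_rule = r$gene_rule,
                                 member = m$id, source_id = r$id)
      if (r$id == m$biomass_id) biomass_ids[m$id] <- new_id
    }
  }
  mets <- do.call(rbind, met_rows)
  mets <- mets[!duplicated(mets$community_id), ]
  inorganic_env <- unique(unlist(lapply(models, inorganic_exchange_metabolites)))
  structure(list(members = ids, mode = mode,
                 metabolites = mets, reactions = rxn_cols,
                 biomass_ids = biomass_ids,
                 env_exchange = env_exchange,
                 inorganic_env = inorganic_env),
            class = "community_model")
}

community_matrices <- function(cm) {
  mids <- cm$metabolites$community_id
  rids <- names(cm$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  lb <- ub <- numeric(length(rids))
  for (j in seq_along(rids)) {
    r <- cm$reactions[[j]]
    S[names(r$stoich), j] <- r$stoich
    lb[j] <- r$lb
    ub[j] <- r$ub
  }
  list(S = S, lb = lb, ub = ub, rids = rids, mids = mids)
}
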
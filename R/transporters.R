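# Transporter classification and activity, metabolite categories.

transporter_mechanisms <- c(
  "ABC", "proton symport", "proton antiport", "sodium symport", "uniport",
  "diffusion", "PTS", "vectorial group translocation", "other")

#' Classify transport reactions by mechanism and direction
#'
#' Extracts every reaction carrying a transport annotation (or spanning the
#' extracellular and cytosolic compartments without one, classified
#' `"other"`) and tabulates mechanism and direction. Reversible
#' transporters are duplicated into one import and one export row, so both
#' directions are counted.
#'
#' @param model A `metabolic_model`.
#' @return Data frame with columns `reaction`, `mechanism` (one of the nine
#'   standard classes), `direction` (`"import"`/`"export"`), `genes`
#'   (gene rule string), `reversible`.
#' @export
classify_transporters <- function(model) {
  met_comp <- stats::setNames(model$metabolites$compartment,
                              model$metabolites$id)
  rows <- list()
  for (r in model$reactions) {
    if (startsWith(r$id, "EX_")) next
    comps <- unique(met_comp[names(r$stoich)])
    is_transport <- !is.null(r$transport) || length(comps) > 1
    if (!is_transport) next
    mech <- r$transport$mechanism %||% "other"
    if (!mech %in% transporter_mechanisms) mech <- "other"
    dir <- r$transport$direction %||% NA_character_
    if (is.na(dir)) {
      # infer from stoichiometry: extracellular metabolite consumed => import
      e_coef <- r$stoich[met_comp[names(r$stoich)] == "e"]
      dir <- if (length(e_coef) && e_coef[1] < 0) "import" else "export"
    }
    reversible <- r$lb < 0 && r$ub > 0
    dirs <- if (reversible) c("import", "export") else dir
    for (d in dirs)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = r$id, mechanism = mech, direction = d,
        genes = r$gene_rule %||% "", reversible = reversible,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(reaction = character(0), mechanism = character(0),
                      direction = character(0), genes = character(0),
                      reversible = logical(0)))
  do.call(rbind, rows)
}

rule_genes <- function(rule) {
  if (is.null(rule) || !nzchar(rule)) return(character(0))
  g <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(g, c("", "and", "or", "AND", "OR"))
}

#' Flag transporters as transcriptionally active
#'
#' A transporter is considered active when at least one of the genes in its
#' gene rule is actively transcribed, regardless of the boolean structure
#' of the rule (any expressed component marks the complex as active).
#' Reactions without associated genes are inactive and flagged.
#'
#' @param transporters Data frame from [classify_transporters()].
#' @param expressed_genes Character vector of expressed gene ids.
#' @return The input with logical columns `active` and `no_genes` added.
#' @export
transporter_activity <- function(transporters, expressed_genes) {
  genes <- lapply(transporters$genes, rule_genes)
  transporters$no_genes <- lengths(genes) == 0
  transporters$active <- vapply(genes, function(g)
    length(g) > 0 && any(g %in% expressed_genes), logical(1))
  transporters
}

#' Map metabolites to broad metabolic categories
#'
#' Deterministic lookup of metabolite ids in a category map (e.g., amino
#' acids, B vitamins, carboxylates); any id without a mapping is assigned
#' `"uncategorized"`. Total on arbitrary ids (never errors).
#'
#' @param metabolite_ids Character vector.
#' @param category_map Data frame with columns `metabolite`, `category`.
#' @return Character vector of categories, same length as input.
#' @export
categorize_metabolites <- function(metabolite_ids, category_map) {
  idx <- match(metabolite_ids, category_map$metabolite)
  out <- category_map$category[idx]
  out[is.na(out)] <- "uncategorized"
  out
}
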
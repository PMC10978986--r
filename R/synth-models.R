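# Toy stoichiometric models with planted auxotrophies and cross-feedings.

toy_universe <- function() {
  data.frame(
    id = c("glc_e", "ac_e", "aa1_e", "aa2_e", "aa3_e", "aa4_e", "aa5_e",
           "thb_e", "rib_e", "nh4_e", "pi_e", "h2o_e", "co2_e"),
    name = c("D-glucose", "acetate", "L-alanine", "L-valine", "L-methionine",
             "L-lysine", "L-arginine", "thiamine", "D-ribose", "ammonium",
             "phosphate", "water", "carbon dioxide"),
    compartment = "e",
    is_inorganic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    mw = c(180.2, 60.1, 89.1, 117.1, 149.2, 146.2, 174.2,
           265.4, 150.1, 18.0, 95.0, 18.0, 44.0),
    stringsAsFactors = FALSE
  )
}

cyto <- function(id) sub("_e$", "_c", id)

#' Build one toy genome-scale model
#'
#' Small (about 10-20 reaction) stoichiometric model over a shared
#' metabolite universe: a carbon source is imported and combined with
#' ammonium into a generic biomass precursor; the biomass reaction consumes
#' the precursor, phosphate and any required organic metabolites.
#' Auxotrophies are planted by listing a requirement without a biosynthetic
#' route (the model then carries an import route instead); secretion
#' capability by a synthesis plus export route.
#'
#' @param genome_id Model id.
#' @param carbon `"glc_e"` or `"ac_e"`.
#' @param aux_requirements Organic env metabolites required by biomass with
#'   no biosynthetic route (import only).
#' @param proto_requirements Required metabolites with a biosynthetic route.
#' @param secretes Organic env metabolites with synthesis + export routes.
#' @param facultative_imports Metabolites the model can import although it
#'   can also synthesize them (facultative uptake routes).
#' @param alt_routes Named character vector mapping a required metabolite
#'   to an importable precursor (e.g. `c(aa1_e = "rib_e")`): the model can
#'   then satisfy that requirement either by direct uptake or by importing
#'   the precursor and converting it, which splits its minimal uptake sets.
#' @return A `metabolic_model`.
#' @export
build_toy_model <- function(genome_id, carbon = "glc_e",
                            aux_requirements = character(0),
                            proto_requirements = character(0),
                            secretes = character(0),
                            facultative_imports = character(0),
                            alt_routes = NULL) {
  uni <- toy_universe()
  stop_if_not(carbon %in% uni$id[!uni$is_inorganic], "unknown carbon source")
  precursors <- unname(alt_routes)
  organics <- unique(c(aux_requirements, proto_requirements, secretes,
                       facultative_imports, precursors))
  stop_if_not(all(organics %in% uni$id[!uni$is_inorganic]),
              "planted metabolite not in universe")
  stop_if_not(all(names(alt_routes) %in% aux_requirements),
              "alt_routes must target auxotrophic requirements")
  used_e <- unique(c(carbon, "nh4_e", "pi_e", "co2_e", "h2o_e", organics))
  used_c <- cyto(c(carbon, "nh4_e", "pi_e", "co2_e",
                   unique(c(aux_requirements, proto_requirements, secretes,
                            facultative_imports, precursors))))
  mets <- uni[uni$id %in% used_e, ]
  mets_c <- data.frame(id = c(used_c, "prec_c"),
                       name = c(sub("_e$", "", used_c), "biomass precursor"),
                       compartment = "c", is_inorganic = FALSE, mw = NA_real_,
                       stringsAsFactors = FALSE)
  mets_c$is_inorganic <- mets_c$id %in% cyto(uni$id[uni$is_inorganic])
  metabolites <- rbind(mets, mets_c)

  g <- function(tag) sprintf("g_%s_%s", genome_id, tag)
  rxn <- function(id, stoich, lb = 0, ub = 100, gene_rule = "",
                  transport = NULL)
    list(id = id, stoich = stoich, lb = lb, ub = ub, gene_rule = gene_rule,
         transport = transport)
  ex <- function(met) rxn(paste0("EX_", sub("_e$", "", met)),
                          stats::setNames(-1, met), lb = 0, ub = 100)
  rxns <- list(
    ex(carbon), ex("nh4_e"), ex("pi_e"), ex("co2_e"), ex("h2o_e"),
    rxn(paste0("T_", sub("_e$", "", carbon)),
        stats::setNames(c(-1, 1), c(carbon, cyto(carbon))),
        gene_rule = paste(g("tc1"), "and", g("tc2")),
        transport = list(mechanism = "ABC", direction = "import")),
    rxn("T_nh4", c(nh4_e = -1, nh4_c = 1), gene_rule = g("tnh4"),
        transport = list(mechanism = "uniport", direction = "import")),
    rxn("T_pi", c(pi_e = -1, pi_c = 1), gene_rule = g("tpi"),
        transport = list(mechanism = "proton symport", direction = "import")),
    rxn("D_co2", c(co2_c = -1, co2_e = 1), lb = -100, ub = 100,
        gene_rule = "",
        transport = list(mechanism = "diffusion", direction = "export")),
    rxn("CM", stats::setNames(c(-1, -1, 2, 0.5),
                              c(cyto(carbon), "nh4_c", "prec_c", "co2_c")),
        gene_rule = g("cm"))
  )
  requires <- unique(c(aux_requirements, proto_requirements))
  bio_st <- stats::setNames(c(-1, -0.1, rep(-1, length(requires))),
                            c("prec_c", "pi_c", cyto(requires)))
  rxns <- c(rxns, list(rxn("BIOMASS", bio_st, gene_rule = g("bio"))))
  for (m in unique(c(proto_requirements, secretes))) {
    rxns <- c(rxns, list(
      rxn(paste0("SYN_", sub("_e$", "", m)),
          stats::setNames(c(-1, 1), c("prec_c", cyto(m))),
          gene_rule = g(paste0("syn_", sub("_e$", "", m))))))
  }
  for (m in secretes) {
    rxns <- c(rxns, list(
      ex(m),
      rxn(paste0("EXP_", sub("_e$", "", m)),
          stats::setNames(c(-1, 1), c(cyto(m), m)),
          gene_rule = g(paste0("exp_", sub("_e$", "", m))),
          transport = list(mechanism = "diffusion", direction = "export"))))
  }
  for (m in names(alt_routes %||% character(0))) {
    pre <- alt_routes[[m]]
    rxns <- c(rxns, list(
      rxn(paste0("SYN_", sub("_e$", "", m), "_from_",
                 sub("_e$", "", pre)),
          stats::setNames(c(-1, 1), c(cyto(pre), cyto(m))),
          gene_rule = g(paste0("alt_", sub("_e$", "", m))))))
  }
  for (m in unique(c(aux_requirements, facultative_imports, precursors))) {
    ex_id <- paste0("EX_", sub("_e$", "", m))
    if (!ex_id %in% vapply(rxns, `[[`, character(1), "id"))
      rxns <- c(rxns, list(ex(m)))
    rxns <- c(rxns, list(
      rxn(paste0("IMP_", sub("_e$", "", m)),
          stats::setNames(c(-1, 1), c(m, cyto(m))),
          gene_rule = paste(g(paste0("imp_", sub("_e$", "", m), "_a")), "or",
                            g(paste0("imp_", sub("_e$", "", m), "_b"))),
          transport = list(mechanism = "ABC", direction = "import"))))
  }
  metabolic_model(genome_id, metabolites, rxns, "BIOMASS")
}

#' Generate toy metabolic models with planted cross-feedings
#'
#' Builds one toy model per genome over a shared small metabolite universe.
#' Genomes named in a cross-feed plan become donor (synthesis + secretion
#' route for the metabolite) or receiver (biomass requirement without a
#' biosynthetic route when `obligate`, with one when facultative); all
#' other genomes are prototroph controls. The planted ground truth and the
#' base medium are returned alongside the models.
#'
#' @param genome_ids Character vector of genome ids.
#' @param plans Optional data frame with columns `donor`, `receiver`,
#'   `metabolite`, `obligate` (logical); `donor != receiver` required.
#' @param seed Integer seed (kept for interface symmetry; construction is
#'   deterministic).
#' @return List with `models` (named list of `metabolic_model`),
#'   `base_medium` (organic ids), and `truth` (the plans).
#' @export
gen_toy_models <- function(genome_ids, plans = NULL, seed = 1) {
  uni <- toy_universe()
  if (!is.null(plans) && nrow(plans) > 0) {
    stop_if_not(all(plans$donor != plans$receiver), "donor must differ from receiver")
    stop_if_not(all(c(plans$donor, plans$receiver) %in% genome_ids),
                "plan references unknown genome")
    stop_if_not(all(plans$metabolite %in% uni$id[!uni$is_inorganic]),
                "infeasible plan: metabolite not in universe")
  }
  models <- list()
  for (gid in genome_ids) {
    aux <- fac <- sec <- character(0)
    if (!is.null(plans) && nrow(plans) > 0) {
      as_rec <- plans[plans$receiver == gid, , drop = FALSE]
      aux <- unique(as_rec$metabolite[as_rec$obligate])
      fac <- unique(as_rec$metabolite[!as_rec$obligate])
      sec <- unique(plans$metabolite[plans$donor == gid])
    }
    models[[gid]] <- build_toy_model(gid, carbon = "glc_e",
                                     aux_requirements = setdiff(aux, sec),
                                     proto_requirements = fac,
                                     secretes = sec,
                                     facultative_imports = fac)
  }
  list(models = models, base_medium = "glc_e",
       truth = plans %||% data.frame(donor = character(0),
                                     receiver = character(0),
                                     metabolite = character(0),
                                     obligate = logical(0)))
}
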
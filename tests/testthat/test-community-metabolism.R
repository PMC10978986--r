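plans_obligate <- data.frame(donor = "d1", receiver = "r1",
                             metabolite = "aa3_e", obligate = TRUE,
                             stringsAsFactors = FALSE)

test_that("growth checks reproduce the planted auxotrophy structure", {
  tw <- gen_toy_models(c("d1", "r1", "p1"), plans_obligate)
  m <- tw$models
  expect_true(check_growth(m$p1, "glc_e")$grows)
  expect_false(check_growth(m$r1, "glc_e")$grows)          # auxotroph
  expect_true(check_growth(m$r1, c("glc_e", "aa3_e"))$grows)
  expect_false(check_growth(m$p1, character(0))$grows)     # empty medium
  # donor co-presence rescues the receiver in shared mode only
  cm_s <- community_model(m[c("d1", "r1")], "shared")
  cm_p <- community_model(m[c("d1", "r1")], "private")
  expect_true(check_growth(cm_s, "glc_e")$grows)
  expect_false(check_growth(cm_p, "glc_e")$grows)
  expect_true(check_growth(cm_p, c("glc_e", "aa3_e"))$grows)
  expect_error(gen_toy_models("g1", data.frame(donor = "g1", receiver = "g1",
                                               metabolite = "aa1_e",
                                               obligate = TRUE)))
  expect_error(gen_toy_models(c("a", "b"),
                              data.frame(donor = "a", receiver = "b",
                                         metabolite = "unobtainium",
                                         obligate = TRUE)))
})

test_that("minimal media enumeration equals the all-subsets oracle", {
  # AND requirement: auxotroph needs carbon and its amino acid
  aux <- build_toy_model("aux", aux_requirements = "aa1_e")
  mm <- minimal_media(aux)
  expect_equal(lapply(mm, sort), list(c("aa1_e", "glc_e")))
  # OR requirement via an alternative precursor route
  alt <- build_toy_model("alt", aux_requirements = "aa1_e",
                         alt_routes = c(aa1_e = "rib_e"))
  mm_alt <- minimal_media(alt)
  expect_setequal(lapply(mm_alt, sort),
                  list(c("aa1_e", "glc_e"), c("glc_e", "rib_e")))
  # oracle agreement on a 2-requirement model
  two <- build_toy_model("two", aux_requirements = c("aa1_e", "aa2_e"))
  want <- oracle_minimal_sets(organic_exchange_metabolites(two),
                              function(s) check_growth(two, s)$grows)
  expect_setequal(lapply(minimal_media(two), sort), lapply(want, sort))
  # molweight mode keeps only the lighter medium (aa1 89.1 < rib 150.1)
  mw <- minimal_media(alt, weighting = "molweight")
  expect_equal(lapply(mw, sort), list(c("aa1_e", "glc_e")))
})

test_that("MRO spans complete overlap to disjoint requirements", {
  a <- build_toy_model("a"); b <- build_toy_model("b")
  expect_equal(mro(list(a = a, b = b))$mro, 1.0)
  c2 <- build_toy_model("c2", carbon = "ac_e")
  expect_equal(mro(list(a = a, c2 = c2))$mro, 0.0)
  # partial overlap fixture equals hand-enumerated set arithmetic
  r1 <- build_toy_model("r1", aux_requirements = "aa1_e")
  r2 <- build_toy_model("r2", aux_requirements = c("aa1_e", "aa2_e"))
  # M_r1 = {glc, aa1}; M_r2 = {glc, aa1, aa2}: |inter| = 2, min = 2
  expect_equal(mro(list(r1 = r1, r2 = r2))$mro, 1.0)
  # three members: pairs (a,r1) 1/1? a={glc}: inter 1 min 1;  (a,r2) 1/1; (r1,r2) 2/2
  expect_equal(mro(list(a = a, r1 = r1, r2 = r2))$mro, (1 + 1 + 2) / (1 + 1 + 2))
  m3 <- mro(list(c2 = c2, r1 = r1))  # {ac} vs {glc, aa1}
  expect_equal(m3$mro, 0)
})

test_that("MIP counts metabolites spared by exchange", {
  tw <- gen_toy_models(c("d1", "r1", "p1"), plans_obligate)
  expect_equal(mip(tw$models[c("p1", "d1")])$mip, 0)   # two prototrophs
  got <- mip(tw$models[c("d1", "r1")])
  expect_equal(got$mip, 1)                              # obligate pair
  expect_setequal(got$medium_private, c("glc_e", "aa3_e"))
  expect_setequal(got$medium_shared, "glc_e")
  expect_gte(mip(tw$models[c("d1", "r1")])$mip, 0)
})

test_that("detailed scores hit the planted obligate exchange exactly", {
  tw <- gen_toy_models(c("d1", "r1", "p1"), plans_obligate)
  ds <- detailed_scores(tw$models[c("d1", "r1")])
  expect_equal(nrow(ds), 1)
  expect_equal(ds$donor, "d1")
  expect_equal(ds$receiver, "r1")
  expect_equal(ds$metabolite, "aa3_e")
  expect_equal(ds$scs, 1); expect_equal(ds$mus, 1)
  expect_equal(ds$mps, 1); expect_equal(ds$smetana, 1)
  # prototroph receiver: SCS = 0, no records towards it
  ds3 <- detailed_scores(tw$models)
  expect_false("p1" %in% ds3$receiver)
  scs <- attr(ds3, "scs")
  expect_true(all(scs[, "p1"] == 0))
  # all scores bounded as typed
  expect_true(all(ds3$scs >= 0 & ds3$scs <= 1))
  expect_true(all(ds3$smetana <= pmin(ds3$scs, ds3$mus, ds3$mps) + 1e-12))
})

test_that("detailed scores equal the naive all-subsets oracle on mixed communities", {
  pool <- make_typing_pool()
  communities <- list(c("h01", "d01"), c("h04", "d05"),
                      c("h02", "d02", "d04"), c("h01", "h03", "d03"))
  for (mem in communities) {
    got <- detailed_scores(pool[mem], medium = "glc_e")
    want <- oracle_detailed_scores(pool[mem], medium = "glc_e")
    key <- function(d) if (nrow(d) == 0) character(0) else
      sort(sprintf("%s>%s:%s=%.6f", d$donor, d$receiver, d$metabolite,
                   d$smetana))
    expect_identical(key(got), key(want))
  }
})

test_that("adding an isolated prototroph leaves existing records unchanged", {
  tw <- gen_toy_models(c("d1", "r1", "p1"), plans_obligate)
  base <- detailed_scores(tw$models[c("d1", "r1")], medium = "glc_e")
  ext <- detailed_scores(tw$models, medium = "glc_e")
  cols <- c("donor", "receiver", "metabolite", "scs", "mus", "mps", "smetana")
  expect_equal(ext[ext$donor != "p1" & ext$receiver != "p1", cols],
               base[, cols], ignore_attr = TRUE)
})

test_that("community score normalization follows N(N-1)/2", {
  recs <- data.frame(smetana = c(0.5, 1.0))
  expect_equal(community_scores(recs, 2)$normalized_score, 1.5)
  expect_equal(community_scores(data.frame(smetana = 1.5), 3)$normalized_score,
               0.5)
  expect_equal(community_scores(recs[0, , drop = FALSE], 4)$sum_score, 0)
  expect_error(community_scores(recs, 1))
})

test_that("transporter classification duplicates reversible reactions and maps mechanisms", {
  m <- build_toy_model("t1", aux_requirements = "aa1_e",
                       secretes = "aa2_e")
  tt <- classify_transporters(m)
  # reversible CO2 diffusion appears in both directions
  co2 <- tt[tt$reaction == "D_co2", ]
  expect_setequal(co2$direction, c("import", "export"))
  expect_equal(unique(co2$mechanism), "diffusion")
  expect_equal(tt$mechanism[tt$reaction == "T_glc"][1], "ABC")
  expect_equal(tt$direction[tt$reaction == "IMP_aa1"][1], "import")
  # counts per class equal a hand tally
  expect_equal(sum(tt$mechanism == "ABC"), 2)             # T_glc, IMP_aa1
  expect_equal(sum(tt$mechanism == "proton symport"), 1)  # T_pi
  # unclassified cross-compartment reaction falls into "other"
  m2 <- m
  m2$reactions[["T_glc"]]$transport <- list(mechanism = "warp drive",
                                            direction = "import")
  expect_equal(classify_transporters(m2)$mechanism[
    classify_transporters(m2)$reaction == "T_glc"][1], "other")
})

test_that("transporter activity needs one expressed component", {
  m <- build_toy_model("t2")
  tt <- classify_transporters(m)
  genes_glc <- coactomics:::rule_genes(tt$genes[tt$reaction == "T_glc"][1])
  # AND rule with a single expressed subunit still counts as active
  act <- transporter_activity(tt, genes_glc[1])
  expect_true(all(act$active[act$reaction == "T_glc"]))
  act0 <- transporter_activity(tt, character(0))
  expect_false(any(act0$active))
  # reaction without genes: inactive and flagged
  expect_true(all(act0$no_genes[act0$reaction == "D_co2"]))
})

test_that("metabolite categorization is total with an uncategorized fallback", {
  cmap <- data.frame(metabolite = c("aa1_e", "aa2_e", "thb_e"),
                     category = c("amino acids", "amino acids", "B vitamins"))
  expect_equal(categorize_metabolites(c("aa1_e", "thb_e", "mystery"), cmap),
               c("amino acids", "B vitamins", "uncategorized"))
  expect_equal(categorize_metabolites(character(0), cmap), character(0))
})
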
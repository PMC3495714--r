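#' Configuration of the bundled clostridial core model
#'
#' @param glucose_uptake Maximum glucose uptake in mmol/(h.gDCW); SPF scans
#'   later fix uptake to exactly this rate (default 10, the conventional
#'   simulation condition for clostridial batch metabolism).
#' @param include_tca_to_succinate Include the lumped reductive TCA branch to
#'   succinate and its export (default `TRUE`).
#' @param biomass_atp_cost ATP consumed per unit of biomass flux, mmol
#'   ATP/gDCW (default 13; makes ATP the growth-limiting currency so that
#'   fast growth coincides with acidogenic ATP generation).
#' @param default_bound Magnitude used for unconstrained fluxes.
#' @return A list of class `fbr_toy_config`.
#' @export
toy_model_config <- function(glucose_uptake = 10,
                             include_tca_to_succinate = TRUE,
                             biomass_atp_cost = 13,
                             default_bound = FBR_DEFAULT_BOUND) {
  stopifnot(glucose_uptake > 0, biomass_atp_cost >= 0, default_bound > 0)
  structure(
    list(glucose_uptake = glucose_uptake,
         include_tca_to_succinate = include_tca_to_succinate,
         biomass_atp_cost = biomass_atp_cost,
         default_bound = default_bound),
    class = "fbr_toy_config"
  )
}

#' Build the bundled clostridial core model
#'
#' Constructs a compact model of Clostridium acetobutylicum primary carbon
#' metabolism: lumped glycolysis to pyruvate, the lactate (LDH) and
#' pyruvate:ferredoxin oxidoreductase (PFO) branches, the ferredoxin /
#' hydrogenase block (HYDA, FNO, FNPO) with its irreversibility bounds, the
#' acetate (PTA, AK), butyrate (THL, BHBD, CRO, BCD, PTB, BK), ethanol
#' (AAD_1, AAD_3), butanol (AAD_2, BDH) and acetone (CoAT, AADC) branches,
#' the CO2/bicarbonate split feeding pyruvate carboxylation, and a minimal
#' biomass drain. Cofactors (ATP/ADP, NAD(H), NADP(H), CoA, oxidized/reduced
#' ferredoxin, orthophosphate, protons) are balanced metabolites.
#'
#' Proton economics drive the specific-proton-flux phenotype switch: acids
#' (acetate, butyrate, lactate, succinate) leave by undissociated-acid
#' diffusion carrying one proton each and can re-enter only through the two
#' CoA-transferase reactions (which import the acid's proton); an F-type
#' ATPase pumps protons at ATP expense, bicarbonate can leave as carbonic
#' acid, and ammonium and phosphate are taken up by proton-coupled transport
#' to meet the biomass nitrogen and phosphorus demand. Acetyl-CoA synthetase
#' (ACS) allows ratio-forced acetate production to be re-assimilated
#' internally at ATP expense, so that during solventogenesis acids are
#' net-consumed rather than secreted.
#'
#' @param config A [toy_model_config()].
#' @return An `fbr_model` with `biomass_id = "BIOMASS"` and
#'   `proton_exchange_id = "H_EXCHANGE"` set, ferredoxin bounds applied, and
#'   no ratio constraints attached (see [wildtype_ratio_set()]).
#' @examples
#' m <- build_toy_model()
#' m
#' @export
build_toy_model <- function(config = toy_model_config()) {
  B <- config$default_bound
  atp_cost <- config$biomass_atp_cost

  mets <- toy_composition_table()[c("id", "name", "compartment")]

  rx <- function(id, sto, lb = 0, ub = B, exch = FALSE) {
    tibble(id = id, stoichiometry = list(sto), lower_bound = lb,
           upper_bound = ub, is_exchange = exch,
           gene_association = NA_character_)
  }

  reactions <- dplyr::bind_rows(
    # substrate uptake
    rx("EX_GLC", c(glc_e = -1), lb = -config$glucose_uptake, ub = 0, exch = TRUE),
    rx("GLC_UPTAKE", c(glc_e = -1, glc = 1)),
    rx("GLYCOLYSIS", c(glc = -1, adp = -2, pi = -2, nad = -2,
                       pyr = 2, atp = 2, nadh = 2, h_c = 2)),
    # pyruvate node
    rx("LDH", c(pyr = -1, nadh = -1, h_c = -1, lac = 1, nad = 1)),
    rx("PFO", c(pyr = -1, coa = -1, fdox = -1,
                accoa = 1, co2 = 1, fdred = 1, h_c = 1)),
    # ferredoxin block (irreversible, see ferredoxin_bounds_table())
    rx("HYDA", c(h_c = -2, fdred = -1, h2 = 1, fdox = 1)),
    rx("FNO", c(nad = -1, h_c = -1, fdred = -1, nadh = 1, fdox = 1)),
    rx("FNPO", c(nadp = -1, h_c = -1, fdred = -1, nadph = 1, fdox = 1)),
    # acetate branch
    rx("PTA", c(accoa = -1, pi = -1, actp = 1, coa = 1)),
    rx("AK", c(actp = -1, adp = -1, ac = 1, atp = 1)),
    rx("AC_SECRETION", c(ac = -1, h_c = -1, ac_e = 1, h_e = 1)),
    rx("EX_AC", c(ac_e = -1), lb = -B, exch = TRUE),
    # acetate re-assimilation (ACS; AMP recycling lumped into a 2-ATP cost)
    rx("ACS", c(ac = -1, atp = -2, coa = -1, accoa = 1, adp = 2, pi = 2)),
    # butyrate branch
    rx("THL", c(accoa = -2, aacoa = 1, coa = 1)),
    rx("BHBD", c(aacoa = -1, nadh = -1, h_c = -1, hbcoa = 1, nad = 1)),
    rx("CRO", c(hbcoa = -1, crotcoa = 1)),
    rx("BCD", c(crotcoa = -1, nadh = -1, h_c = -1, btcoa = 1, nad = 1)),
    rx("PTB", c(btcoa = -1, pi = -1, btp = 1, coa = 1), lb = -B),
    rx("BK", c(btp = -1, adp = -1, but = 1, atp = 1), lb = -B),
    rx("BUT_SECRETION", c(but = -1, h_c = -1, but_e = 1, h_e = 1)),
    rx("EX_BUT", c(but_e = -1), lb = -B, exch = TRUE),
    # solvent branches: the three activities of the bifunctional AAD
    rx("AAD_1", c(accoa = -1, nadh = -1, h_c = -1, acald = 1, coa = 1, nad = 1)),
    rx("AAD_3", c(acald = -1, nadh = -1, h_c = -1, etoh = 1, nad = 1)),
    rx("AAD_2", c(btcoa = -1, nadh = -1, h_c = -1, btal = 1, coa = 1, nad = 1)),
    rx("BDH", c(btal = -1, nadph = -1, h_c = -1, btoh = 1, nadp = 1)),
    rx("ETOH_SECRETION", c(etoh = -1, etoh_e = 1)),
    rx("EX_ETOH", c(etoh_e = -1), exch = TRUE),
    rx("BTOH_SECRETION", c(btoh = -1, btoh_e = 1)),
    rx("EX_BTOH", c(btoh_e = -1), exch = TRUE),
    # acetone branch; CoA transferase accepts either extracellular acid
    rx("CoAT_ACETATE", c(aacoa = -1, ac_e = -1, h_e = -1,
                         acac = 1, accoa = 1, h_c = 1)),
    rx("CoAT_BUTYRATE", c(aacoa = -1, but_e = -1, h_e = -1,
                          acac = 1, btcoa = 1, h_c = 1)),
    rx("AADC", c(acac = -1, h_c = -1, acetone = 1, co2 = 1)),
    rx("ACETONE_SECRETION", c(acetone = -1, acetone_e = 1)),
    rx("EX_ACETONE", c(acetone_e = -1), exch = TRUE),
    # lactate export
    rx("LAC_SECRETION", c(lac = -1, h_c = -1, lac_e = 1, h_e = 1)),
    rx("EX_LAC", c(lac_e = -1), exch = TRUE),
    # acetoin / 2,3-butanediol overflow branch at the pyruvate node
    rx("ACETOIN_SYNTH", c(pyr = -2, h_c = -2, actn = 1, co2 = 2)),
    rx("ACETOIN_SECRETION", c(actn = -1, actn_e = 1)),
    rx("EX_ACETOIN", c(actn_e = -1), exch = TRUE),
    rx("BTD_SYNTH", c(actn = -1, nadh = -1, h_c = -1, btd = 1, nad = 1)),
    rx("BTD_SECRETION", c(btd = -1, btd_e = 1)),
    rx("EX_BTD", c(btd_e = -1), exch = TRUE),
    # hydrogen
    rx("H2_SECRETION", c(h2 = -1, h2_e = 1)),
    rx("EX_H2", c(h2_e = -1), exch = TRUE),
    # CO2 fate: export, or hydration to bicarbonate
    rx("CO2_EXPORT", c(co2 = -1, co2_e = 1)),
    rx("EX_CO2", c(co2_e = -1), exch = TRUE),
    rx("CO2_TO_HCO3", c(co2 = -1, hco3 = 1, h_c = 1)),
    rx("HCO3_EXPORT", c(hco3 = -1, h_c = -1, hco3_e = 1, h_e = 1)),
    rx("EX_HCO3", c(hco3_e = -1), exch = TRUE),
    rx("PYR_TO_OAA", c(pyr = -1, hco3 = -1, atp = -1,
                       oaa = 1, adp = 1, pi = 1, h_c = 1)),
    # nutrient and energy housekeeping
    rx("NH4_UPTAKE", c(nh3_e = -1, h_e = -1, nh4 = 1)),
    rx("EX_NH3", c(nh3_e = -1), lb = -B, ub = 0, exch = TRUE),
    rx("PI_UPTAKE", c(pi_e = -1, h_e = -2, pi = 1, h_c = 1)),
    rx("EX_PI", c(pi_e = -1), lb = -B, ub = 0, exch = TRUE),
    rx("ATPASE", c(atp = -1, h_c = -1, adp = 1, pi = 1, h_e = 2)),
    rx("ATP_MAINTENANCE", c(atp = -1, adp = 1, pi = 1, h_c = 1)),
    # bounded passive proton conductance of the membrane
    rx("H_LEAK", c(h_e = -1, h_c = 1), ub = 3),
    rx("H_EXCHANGE", c(h_e = -1), lb = -B, exch = TRUE),
    # minimal biomass drain (one phosphate is retained in biomass polymers;
    # reducing equivalents lumped as NADH)
    rx("BIOMASS", c(accoa = -1, pyr = -1, oaa = -1.2, nh4 = -2,
                    atp = -atp_cost, nadph = -1, nadh = -6,
                    coa = 1, adp = atp_cost, pi = atp_cost - 1, h_c = 2,
                    nadp = 1, nad = 6))
  )

  if (config$include_tca_to_succinate) {
    reactions <- dplyr::bind_rows(
      reactions,
      rx("OAA_TO_SUCC", c(oaa = -1, nadh = -2, h_c = -2, succ = 1, nad = 2)),
      rx("SUCC_EXPORT", c(succ = -1, h_c = -1, succ_e = 1, h_e = 1)),
      rx("EX_SUCC", c(succ_e = -1), exch = TRUE)
    )
  } else {
    mets <- mets[!mets$id %in% c("succ", "succ_e"), ]
  }

  model <- metabolic_model(metabolites = mets, reactions = reactions,
                           biomass_id = "BIOMASS",
                           proton_exchange_id = "H_EXCHANGE")
  apply_irreversibility_table(model, ferredoxin_bounds_table())
}

#' Irreversibility bounds of the ferredoxin block
#'
#' The four ferredoxin-coupled reactions are constrained to run forward only
#' (bounds `[0, 1000]`): pyruvate:ferredoxin oxidoreductase (PFO),
#' hydrogenase (HYDA), and the ferredoxin NAD+/NADP+ oxidoreductases
#' (FNO, FNPO).
#'
#' @return A tibble suitable for [apply_irreversibility_table()].
#' @export
ferredoxin_bounds_table <- function() {
  tibble(reaction = c("PFO", "HYDA", "FNO", "FNPO"),
         lower = 0, upper = FBR_DEFAULT_BOUND)
}

#' The five wild-type flux-ratio constraints
#'
#' The set of branch-point ratios that, imposed simultaneously, yields a
#' qualitatively wild-type picture of clostridial acid/solvent metabolism:
#'
#' * butyrate over acetate re-uptake through the CoA transferase = 0.63,
#' * PFO over LDH at the pyruvate node = 10 (lactate is a minor product),
#' * CO2 export over CO2 hydration to bicarbonate = 5,
#' * THL over PTA at the acetyl-CoA node = 2 (butyrate pathway favored), and
#' * THL over AAD_1 = 10 (ethanol is a minor product).
#'
#' @return A list of five [flux_ratio()] objects.
#' @examples
#' vapply(wildtype_ratio_set(), `[[`, numeric(1), "ratio")
#' @export
wildtype_ratio_set <- function() {
  list(
    flux_ratio("coat_butyrate_acetate", "CoAT_BUTYRATE", "CoAT_ACETATE", 0.63),
    flux_ratio("pfo_ldh", "PFO", "LDH", 10),
    flux_ratio("co2_export_conversion", "CO2_EXPORT", "CO2_TO_HCO3", 5),
    flux_ratio("thl_pta", "THL", "PTA", 2),
    flux_ratio("thl_aad1", "THL", "AAD_1", 10)
  )
}

#' Attach the wild-type ratio set to a model
#'
#' @param model An `fbr_model` (typically [build_toy_model()]).
#' @return The model with the five wild-type constraints added.
#' @export
add_wildtype_ratios <- function(model) {
  for (rc in wildtype_ratio_set()) model <- add_flux_ratio(model, rc)
  model
}

#' Element and moiety composition of the core-model metabolites
#'
#' Carbon counts plus conserved-moiety indicators (CoA, adenine nucleotide,
#' phosphate, NAD, NADP, ferredoxin, nitrogen) for every metabolite of the
#' bundled model. [audit_toy_balances()] checks each non-exchange reaction
#' column of the stoichiometric matrix against this table.
#'
#' @return A tibble with one row per metabolite.
#' @export
toy_composition_table <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tbl <- tribble_(
    ~id, ~name, ~compartment, ~carbon, ~coa, ~adenine, ~phosphate, ~nad, ~nadp, ~fd, ~nitrogen,
    "glc_e", "D-glucose", "extracellular", 6, 0, 0, 0, 0, 0, 0, 0,
    "ac_e", "acetate", "extracellular", 2, 0, 0, 0, 0, 0, 0, 0,
    "but_e", "butyrate", "extracellular", 4, 0, 0, 0, 0, 0, 0, 0,
    "lac_e", "lactate", "extracellular", 3, 0, 0, 0, 0, 0, 0, 0,
    "etoh_e", "ethanol", "extracellular", 2, 0, 0, 0, 0, 0, 0, 0,
    "btoh_e", "butanol", "extracellular", 4, 0, 0, 0, 0, 0, 0, 0,
    "acetone_e", "acetone", "extracellular", 3, 0, 0, 0, 0, 0, 0, 0,
    "h2_e", "hydrogen", "extracellular", 0, 0, 0, 0, 0, 0, 0, 0,
    "co2_e", "carbon dioxide", "extracellular", 1, 0, 0, 0, 0, 0, 0, 0,
    "hco3_e", "bicarbonate", "extracellular", 1, 0, 0, 0, 0, 0, 0, 0,
    "succ_e", "succinate", "extracellular", 4, 0, 0, 0, 0, 0, 0, 0,
    "actn_e", "acetoin", "extracellular", 4, 0, 0, 0, 0, 0, 0, 0,
    "btd_e", "2,3-butanediol", "extracellular", 4, 0, 0, 0, 0, 0, 0, 0,
    "nh3_e", "ammonia", "extracellular", 0, 0, 0, 0, 0, 0, 0, 1,
    "pi_e", "orthophosphate", "extracellular", 0, 0, 0, 1, 0, 0, 0, 0,
    "h_e", "proton", "extracellular", 0, 0, 0, 0, 0, 0, 0, 0,
    "glc", "D-glucose", "cytosol", 6, 0, 0, 0, 0, 0, 0, 0,
    "pyr", "pyruvate", "cytosol", 3, 0, 0, 0, 0, 0, 0, 0,
    "lac", "lactate", "cytosol", 3, 0, 0, 0, 0, 0, 0, 0,
    "accoa", "acetyl-CoA", "cytosol", 2, 1, 0, 0, 0, 0, 0, 0,
    "coa", "coenzyme A", "cytosol", 0, 1, 0, 0, 0, 0, 0, 0,
    "aacoa", "acetoacetyl-CoA", "cytosol", 4, 1, 0, 0, 0, 0, 0, 0,
    "hbcoa", "beta-hydroxybutyryl-CoA", "cytosol", 4, 1, 0, 0, 0, 0, 0, 0,
    "crotcoa", "crotonyl-CoA", "cytosol", 4, 1, 0, 0, 0, 0, 0, 0,
    "btcoa", "butyryl-CoA", "cytosol", 4, 1, 0, 0, 0, 0, 0, 0,
    "acald", "acetaldehyde", "cytosol", 2, 0, 0, 0, 0, 0, 0, 0,
    "etoh", "ethanol", "cytosol", 2, 0, 0, 0, 0, 0, 0, 0,
    "btal", "butyraldehyde", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "btoh", "butanol", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "actp", "acetyl phosphate", "cytosol", 2, 0, 0, 1, 0, 0, 0, 0,
    "ac", "acetate", "cytosol", 2, 0, 0, 0, 0, 0, 0, 0,
    "btp", "butyryl phosphate", "cytosol", 4, 0, 0, 1, 0, 0, 0, 0,
    "but", "butyrate", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "acac", "acetoacetate", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "acetone", "acetone", "cytosol", 3, 0, 0, 0, 0, 0, 0, 0,
    "actn", "acetoin", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "btd", "2,3-butanediol", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "co2", "carbon dioxide", "cytosol", 1, 0, 0, 0, 0, 0, 0, 0,
    "hco3", "bicarbonate", "cytosol", 1, 0, 0, 0, 0, 0, 0, 0,
    "oaa", "oxaloacetate", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "succ", "succinate", "cytosol", 4, 0, 0, 0, 0, 0, 0, 0,
    "h2", "hydrogen", "cytosol", 0, 0, 0, 0, 0, 0, 0, 0,
    "atp", "ATP", "cytosol", 0, 0, 1, 3, 0, 0, 0, 0,
    "adp", "ADP", "cytosol", 0, 0, 1, 2, 0, 0, 0, 0,
    "pi", "orthophosphate", "cytosol", 0, 0, 0, 1, 0, 0, 0, 0,
    "nad", "NAD+", "cytosol", 0, 0, 0, 0, 1, 0, 0, 0,
    "nadh", "NADH", "cytosol", 0, 0, 0, 0, 1, 0, 0, 0,
    "nadp", "NADP+", "cytosol", 0, 0, 0, 0, 0, 1, 0, 0,
    "nadph", "NADPH", "cytosol", 0, 0, 0, 0, 0, 1, 0, 0,
    "fdox", "oxidized ferredoxin", "cytosol", 0, 0, 0, 0, 0, 0, 1, 0,
    "fdred", "reduced ferredoxin", "cytosol", 0, 0, 0, 0, 0, 0, 1, 0,
    "nh4", "ammonium", "cytosol", 0, 0, 0, 0, 0, 0, 0, 1,
    "h_c", "proton", "cytosol", 0, 0, 0, 0, 0, 0, 0, 0
  )
  tbl
}

#' Audit elemental and moiety balance of the core model
#'
#' Multiplies each non-exchange reaction column of the stoichiometric matrix
#' by the composition table and reports the net amount of carbon and of each
#' conserved moiety the reaction creates or destroys. The biomass drain is
#' exempt (its products leave the small-molecule pool by construction);
#' everything else must balance exactly.
#'
#' @param model A model built by [build_toy_model()].
#' @return A tibble with one row per audited reaction and one column per
#'   audited quantity; all values are zero for a balanced fixture.
#' @export
audit_toy_balances <- function(model) {
  comp <- toy_composition_table()
  S <- stoich_matrix(model, ratio_rows = FALSE)
  keep <- !model$reactions$is_exchange & model$reactions$id != model$biomass_id
  quantities <- c("carbon", "coa", "adenine", "phosphate", "nad", "nadp",
                  "fd", "nitrogen")
  M <- as.matrix(comp[match(rownames(S), comp$id), quantities])
  net <- t(S[, keep, drop = FALSE]) %*% M
  dplyr::bind_cols(tibble(reaction = model$reactions$id[keep]),
                   as_tibble(net))
}

#' Assumed wild-type PTB:AAD_2 ratio during solventogenesis
#'
#' The branch split at butyryl-CoA between phosphotransbutyrylase and the
#' butyraldehyde-forming activity of the aldehyde/alcohol dehydrogenase is
#' unconstrained in wild-type simulations; 0.25 is the assumed solventogenic
#' reference value used as the basis for knockdown and over-expression
#' arithmetic at that node (an assumption, not a computed quantity).
#' @export
FBR_WT_PTB_AAD2 <- 0.25
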
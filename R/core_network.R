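# Curated core-scale network of N. lanati central carbon, fermentation and
# hydrogenosomal energy metabolism, plus lumped anabolic routes feeding the
# measured-composition biomass reaction.

#' Scenario configuration for the core model
#'
#' @param hydrogenase `"ferredoxin"` (base case) or `"bifurcating"`. The
#'   bifurcating mode replaces the ferredoxin hydrogenase unless
#'   `keep_ferredoxin = TRUE`.
#' @param proton_module Enable the speculative complex-1/complex-2 proton
#'   pump plus ATP synthase module.
#' @param h2_dehydrogenase_reversible If `FALSE` (default) the hydrogen
#'   dehydrogenase NAD⁺ + H₂ → NADH + H⁺ only runs in the forward,
#'   energetically favorable direction (the reverse, H₂-producing direction
#'   has ΔG ≈ +34 ± 5.9 kJ/mol and is disallowed in the base case).
#' @param glucose_uptake Glucose uptake bound, mmol/gDW/h (default 1.5, the
#'   experimentally measured flux used in all simulations).
#' @param keep_ferredoxin Keep the ferredoxin hydrogenase active alongside
#'   the bifurcating one.
#' @param bifurcating_stoich Named vector with elements `nadh`, `fd`, `h2`:
#'   mol NADH and reduced ferredoxin oxidized and H₂ produced per turnover
#'   (default 1:1:2, Thermotoga-type coupling).
#' @param protons_pumped_per_nadh Protons translocated out of the
#'   hydrogenosome per NADH by the complex-1/2 module (default 2).
#' @param protons_per_atp Protons consumed by the ATP synthase per ATP
#'   (default 3).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(hydrogenase = c("ferredoxin", "bifurcating"),
                            proton_module = FALSE,
                            h2_dehydrogenase_reversible = FALSE,
                            glucose_uptake = 1.5,
                            keep_ferredoxin = FALSE,
                            bifurcating_stoich = c(nadh = 1, fd = 1, h2 = 2),
                            protons_pumped_per_nadh = 2,
                            protons_per_atp = 3) {
  hydrogenase <- match.arg(hydrogenase)
  stopifnot(glucose_uptake >= 0,
            all(c("nadh", "fd", "h2") %in% names(bifurcating_stoich)))
  if (abs(bifurcating_stoich[["h2"]] - bifurcating_stoich[["nadh"]] -
            bifurcating_stoich[["fd"]]) > 1e-9) {
    stop("bifurcating hydrogenase electron balance requires h2 = nadh + fd",
         call. = FALSE)
  }
  structure(list(hydrogenase = hydrogenase,
                 proton_module = isTRUE(proton_module),
                 h2_dehydrogenase_reversible =
                   isTRUE(h2_dehydrogenase_reversible),
                 glucose_uptake = glucose_uptake,
                 keep_ferredoxin = isTRUE(keep_ferredoxin),
                 bifurcating_stoich = bifurcating_stoich,
                 protons_pumped_per_nadh = protons_pumped_per_nadh,
                 protons_per_atp = protons_per_atp),
            class = "scenario_config")
}

# species registry: base id -> formula, charge, name
species_registry <- function() {
  reg <- tibble::tribble(
    ~base, ~formula, ~charge, ~name,
    "glc", "C6H12O6", 0, "D-glucose",
    "g6p", "C6H11O9P", -2, "glucose 6-phosphate",
    "f6p", "C6H11O9P", -2, "fructose 6-phosphate",
    "fdp", "C6H10O12P2", -4, "fructose 1,6-bisphosphate",
    "dhap", "C3H5O6P", -2, "dihydroxyacetone phosphate",
    "g3p", "C3H5O6P", -2, "glyceraldehyde 3-phosphate",
    "dpg", "C3H4O10P2", -4, "1,3-bisphosphoglycerate",
    "pg3", "C3H4O7P", -3, "3-phosphoglycerate",
    "pg2", "C3H4O7P", -3, "2-phosphoglycerate",
    "pep", "C3H2O6P", -3, "phosphoenolpyruvate",
    "pyr", "C3H3O3", -1, "pyruvate",
    "lac", "C3H5O3", -1, "L-lactate",
    "coa", "C21H32N7O16P3S", -4, "coenzyme A",
    "accoa", "C23H34N7O17P3S", -4, "acetyl-CoA",
    "acald", "C2H4O", 0, "acetaldehyde",
    "etoh", "C2H6O", 0, "ethanol",
    "ac", "C2H3O2", -1, "acetate",
    "for", "CHO2", -1, "formate",
    "oaa", "C4H2O5", -2, "oxaloacetate",
    "mal", "C4H4O5", -2, "L-malate",
    "fum", "C4H2O4", -2, "fumarate",
    "succ", "C4H4O4", -2, "succinate",
    "succoa", "C25H35N7O19P3S", -5, "succinyl-CoA",
    "atp", "C10H12N5O13P3", -4, "ATP",
    "adp", "C10H12N5O10P2", -3, "ADP",
    "amp", "C10H12N5O7P", -2, "AMP",
    "pi", "HO4P", -2, "phosphate",
    "ppi", "HO7P2", -3, "pyrophosphate",
    "nad", "C21H26N7O14P2", -1, "NAD+",
    "nadh", "C21H27N7O14P2", -2, "NADH",
    "nadp", "C21H25N7O17P3", -3, "NADP+",
    "nadph", "C21H26N7O17P3", -4, "NADPH",
    "h", "H", 1, "proton",
    "h2o", "H2O", 0, "water",
    "co2", "CO2", 0, "carbon dioxide",
    "h2", "H2", 0, "molecular hydrogen",
    "nh4", "H4N", 1, "ammonium",
    "h2s", "H2S", 0, "hydrogen sulfide",
    "fdox", "", 0, "oxidized ferredoxin (2e- carrier)",
    "fdred", "", -2, "reduced ferredoxin (2e- carrier)",
    "xyl", "C5H10O5", 0, "D-xylose",
    "xylu", "C5H10O5", 0, "D-xylulose",
    "xu5p", "C5H9O8P", -2, "xylulose 5-phosphate",
    "ru5p", "C5H9O8P", -2, "ribulose 5-phosphate",
    "r5p", "C5H9O8P", -2, "ribose 5-phosphate",
    "s7p", "C7H13O10P", -2, "sedoheptulose 7-phosphate",
    "e4p", "C4H7O7P", -2, "erythrose 4-phosphate",
    "fru", "C6H12O6", 0, "D-fructose",
    "man", "C6H12O6", 0, "D-mannose",
    "man6p", "C6H11O9P", -2, "mannose 6-phosphate",
    "gal", "C6H12O6", 0, "D-galactose",
    "g1p", "C6H11O9P", -2, "glucose 1-phosphate",
    "srb", "C6H14O6", 0, "D-sorbitol",
    "glyc", "C3H8O3", 0, "glycerol",
    "glcnac", "C8H15NO6", 0, "N-acetylglucosamine",
    "cellb", "C12H22O11", 0, "cellobiose",
    "malt", "C12H22O11", 0, "maltose",
    "sucr", "C12H22O11", 0, "sucrose",
    "raff", "C18H32O16", 0, "raffinose",
    "arab", "C5H10O5", 0, "L-arabinose",
    "rmn", "C6H12O5", 0, "L-rhamnose",
    "cit", "C6H5O7", -3, "citrate",
    "pectin", "C6H8O6", 0, "pectin (galacturonan unit)",
    "cellul", "C6H10O5", 0, "cellulose (glucan unit)",
    "xylan", "C5H8O4", 0, "xylan (xylose unit)",
    "mdx", "C6H10O5", 0, "maltodextrin (glucan unit)",
    "lignoc", "C11H18O9", 0, "lignocellulose (glucan+xylan unit)",
    "meoh", "CH4O", 0, "methanol",
    # amino acids
    "ala", "C3H7NO2", 0, "L-alanine",
    "arg", "C6H15N4O2", 1, "L-arginine",
    "asn", "C4H8N2O3", 0, "L-asparagine",
    "asp", "C4H6NO4", -1, "L-aspartate",
    "cys", "C3H7NO2S", 0, "L-cysteine",
    "gln", "C5H10N2O3", 0, "L-glutamine",
    "glu", "C5H8NO4", -1, "L-glutamate",
    "gly", "C2H5NO2", 0, "glycine",
    "his", "C6H9N3O2", 0, "L-histidine",
    "ile", "C6H13NO2", 0, "L-isoleucine",
    "leu", "C6H13NO2", 0, "L-leucine",
    "lys", "C6H15N2O2", 1, "L-lysine",
    "met", "C5H11NO2S", 0, "L-methionine",
    "phe", "C9H11NO2", 0, "L-phenylalanine",
    "pro", "C5H9NO2", 0, "L-proline",
    "ser", "C3H7NO3", 0, "L-serine",
    "thr", "C4H9NO3", 0, "L-threonine",
    "trp", "C11H12N2O2", 0, "L-tryptophan",
    "tyr", "C9H11NO3", 0, "L-tyrosine",
    "val", "C5H11NO2", 0, "L-valine",
    # nucleotides
    "gtp", "C10H12N5O14P3", -4, "GTP",
    "ctp", "C9H12N3O14P3", -4, "CTP",
    "utp", "C9H11N2O15P3", -4, "UTP",
    "gmp", "C10H12N5O8P", -2, "GMP",
    "cmp", "C9H12N3O8P", -2, "CMP",
    "ump", "C9H11N2O9P", -2, "UMP",
    "gdp", "C10H12N5O11P2", -3, "GDP",
    "cdp", "C9H12N3O11P2", -3, "CDP",
    "udp", "C9H11N2O12P2", -3, "UDP",
    "datp", "C10H12N5O12P3", -4, "dATP",
    "dgtp", "C10H12N5O13P3", -4, "dGTP",
    "dctp", "C9H12N3O13P3", -4, "dCTP",
    "dttp", "C10H13N2O14P3", -4, "dTTP",
    "dadp", "C10H12N5O9P2", -3, "dADP",
    "dgdp", "C10H12N5O10P2", -3, "dGDP",
    "dcdp", "C9H12N3O10P2", -3, "dCDP",
    "dtdp", "C10H13N2O11P2", -3, "dTDP",
    "dtmp", "C10H13N2O8P", -2, "dTMP",
    # fatty acids
    "ttdca", "C14H27O2", -1, "myristate (C14:0)",
    "hdca", "C16H31O2", -1, "palmitate (C16:0)",
    "ocdca", "C18H35O2", -1, "stearate (C18:0)",
    # vitamins and cofactors
    "pydxn", "C8H11NO3", 0, "pyridoxine",
    "pab", "C7H6NO2", -1, "4-aminobenzoate",
    "btn", "C10H15N2O3S", -1, "biotin",
    "cbl", "C63H88N14O14P", 0, "cobalamin (CHONPS proxy, Co omitted)",
    "ribflv", "C17H20N4O6", 0, "riboflavin",
    "fol", "C19H18N7O6", -1, "folate",
    "pnto", "C9H16NO5", -1, "pantothenate",
    "nac", "C6H4NO2", -1, "nicotinate",
    "thm", "C12H17N4OS", 1, "thiamine",
    "pheme", "C34H32N4O4", -2, "heme b (CHONPS proxy, Fe omitted)"
  )
  reg
}

amino_acid_ids <- function() {
  c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his", "ile",
    "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp", "tyr", "val")
}

vitamin_ids <- function() {
  c("pydxn", "pab", "btn", "cbl", "ribflv", "fol", "pnto", "nac", "thm",
    "pheme")
}

# vitamins with a lumped de novo synthesis route (folate requires pABA)
vitamin_synth_ids <- function() {
  c("pydxn", "cbl", "ribflv", "fol", "pnto", "nac", "thm")
}

BIG <- 1000

#' Build the curated N. lanati core metabolic model
#'
#' Constructs the three-compartment core network: EMP glycolysis with both
#' NAD⁺- and NADP⁺-linked glyceraldehyde-3-phosphate dehydrogenase variants,
#' non-oxidative pentose phosphate pathway only (the oxidative branch is
#' absent), xylose isomerase/xylulokinase, mixed-acid fermentation routes
#' (lactate, formate, acetate, ethanol, reductive succinate), catabolic entry
#' routes for every substrate the model is curated to grow on, lumped
#' extracellular CAZyme hydrolysis of polymeric substrates, the hydrogenosome
#' (malate/pyruvate import, malic enzyme, PFL, PFO, ferredoxin hydrogenase,
#' forward-only hydrogen dehydrogenase, the ATP-yielding
#' acetate:succinyl-CoA transferase + succinyl-CoA synthetase couple, and the
#' speculative bifurcating hydrogenase and proton-pumping module), lumped
#' anabolic monomer synthesis, vitamin demands, and exchanges. Speculative
#' reactions carry bounds (0, 0) unless enabled by the scenario.
#'
#' All internal reactions are mass and charge balanced ([check_balance()]
#' is run during construction and aborts the build naming the offending
#' reaction). Hydrogenosomal anion transport is proton-compensated
#' (electroneutral), so free protons cross the hydrogenosomal inner membrane
#' only alongside metabolites or through the explicit pumping module.
#'
#' @param config A [scenario_config()].
#' @param biomass A biomass reaction from [build_biomass_reaction()].
#' @return A `metabolic_model` (without the maintenance reaction; see
#'   [attach_maintenance()]).
#' @export
build_core_model <- function(config = scenario_config(),
                             biomass = build_biomass_reaction()) {
  stopifnot(inherits(config, "scenario_config"))
  reg <- species_registry()
  aa <- amino_acid_ids()
  vit <- vitamin_ids()

  mets_c <- c("glc", "g6p", "f6p", "fdp", "dhap", "g3p", "dpg", "pg3", "pg2",
              "pep", "pyr", "lac", "coa", "accoa", "acald", "etoh", "ac",
              "for", "oaa", "mal", "fum", "succ", "atp", "adp", "amp", "pi",
              "ppi", "nad", "nadh", "nadp", "nadph", "h", "h2o", "co2", "h2",
              "nh4", "h2s", "xyl", "xylu", "xu5p", "ru5p", "r5p", "s7p",
              "e4p", "fru", "man", "man6p", "gal", "g1p", "srb", "glyc",
              "glcnac", aa,
              "gtp", "ctp", "utp", "gmp", "cmp", "ump", "gdp", "cdp", "udp",
              "datp", "dgtp", "dctp", "dttp", "dadp", "dgdp", "dcdp", "dtdp",
              "dtmp", "ttdca", "hdca", "ocdca", vit)
  mets_h <- c("pyr", "mal", "fum", "succ", "succoa", "accoa", "coa", "ac",
              "for", "co2", "h2", "h2o", "h", "pi", "atp", "adp", "nad",
              "nadh", "fdox", "fdred")
  mets_e <- c("glc", "fru", "gal", "man", "srb", "xyl", "cellb", "malt",
              "sucr", "raff", "cellul", "xylan", "mdx", "lignoc", "pectin",
              "arab", "rmn", "cit", "meoh", "glcnac", "pyr", "oaa", "mal",
              "fum", "glyc", "lac", "etoh", "for", "ac", "succ", "h2", "co2",
              "h2o", "h", "nh4", "h2s", "pi",
              "phe", "arg", "leu", "pro", "ser", "thr", vit)

  inst <- function(bases, comp) {
    i <- match(bases, reg$base)
    if (anyNA(i)) stop("unknown species: ", paste(bases[is.na(i)],
                                                  collapse = ", "))
    tibble::tibble(id = paste0(bases, "_", comp),
                   name = reg$name[i], formula = reg$formula[i],
                   charge = reg$charge[i], compartment = comp)
  }
  metabolites <- dplyr::bind_rows(inst(mets_c, "c"), inst(mets_h, "h"),
                                  inst(mets_e, "e"))

  rxns <- list()
  st <- list()
  add <- function(id, name, stoich, lb = -BIG, ub = BIG, kind = "internal",
                  subsystem = "", speculative = FALSE, confidence = 3L,
                  gene = NA_character_) {
    rxns[[id]] <<- tibble::tibble(
      id = id, name = name, lower_bound = lb, upper_bound = ub, kind = kind,
      subsystem = subsystem, speculative = speculative,
      confidence = as.integer(confidence), gene_association = gene)
    st[[id]] <<- tibble::tibble(reaction = id, metabolite = names(stoich),
                                coefficient = unname(stoich))
  }
  irr <- function(...) add(..., lb = 0)

  gly <- "glycolysis"
  # --- EMP glycolysis ---
  irr("HEX1", "hexokinase",
      c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1), subsystem = gly)
  add("PGI", "phosphoglucose isomerase", c(g6p_c = -1, f6p_c = 1),
      subsystem = gly)
  irr("PFK", "phosphofructokinase",
      c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1), subsystem = gly)
  add("FBA", "fructose-bisphosphate aldolase",
      c(fdp_c = -1, dhap_c = 1, g3p_c = 1), subsystem = gly)
  add("TPI", "triose-phosphate isomerase", c(dhap_c = -1, g3p_c = 1),
      subsystem = gly)
  add("GAPD", "glyceraldehyde-3-phosphate dehydrogenase (NAD+)",
      c(g3p_c = -1, nad_c = -1, pi_c = -1, dpg_c = 1, nadh_c = 1, h_c = 1),
      subsystem = gly, confidence = 4L)
  irr("GAPN", "non-phosphorylating G3P dehydrogenase (NADP+)",
      c(g3p_c = -1, nadp_c = -1, h2o_c = -1, pg3_c = 1, nadph_c = 1, h_c = 2),
      subsystem = gly, confidence = 4L)
  add("PGK", "phosphoglycerate kinase",
      c(dpg_c = -1, adp_c = -1, pg3_c = 1, atp_c = 1), subsystem = gly)
  add("PGM", "phosphoglycerate mutase", c(pg3_c = -1, pg2_c = 1),
      subsystem = gly)
  add("ENO", "enolase", c(pg2_c = -1, pep_c = 1, h2o_c = 1), subsystem = gly)
  irr("PYK", "pyruvate kinase",
      c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
      subsystem = gly)
  irr("G6PP", "glucose-6-phosphatase",
      c(g6p_c = -1, h2o_c = -1, glc_c = 1, pi_c = 1),
      subsystem = "sugar interconversion", confidence = 1L)

  fer <- "mixed-acid fermentation"
  add("LDH", "lactate dehydrogenase",
      c(pyr_c = -1, nadh_c = -1, h_c = -1, lac_c = 1, nad_c = 1),
      subsystem = fer, confidence = 4L)
  irr("PFL", "pyruvate formate lyase (cytosol)",
      c(pyr_c = -1, coa_c = -1, accoa_c = 1, for_c = 1), subsystem = fer,
      confidence = 4L, gene = "981064 or 1027775")
  add("ACALDH", "acetaldehyde dehydrogenase (CoA-acylating)",
      c(accoa_c = -1, nadh_c = -1, h_c = -1, acald_c = 1, nad_c = 1,
        coa_c = 1), subsystem = fer)
  add("ALCD", "alcohol dehydrogenase",
      c(acald_c = -1, nadh_c = -1, h_c = -1, etoh_c = 1, nad_c = 1),
      subsystem = fer, confidence = 4L)
  irr("PEPCK", "PEP carboxykinase",
      c(pep_c = -1, co2_c = -1, adp_c = -1, oaa_c = 1, atp_c = 1),
      subsystem = fer)
  add("MDH", "malate dehydrogenase",
      c(oaa_c = -1, nadh_c = -1, h_c = -1, mal_c = 1, nad_c = 1),
      subsystem = fer)
  add("FUMC", "fumarase (cytosol)", c(mal_c = -1, fum_c = 1, h2o_c = 1),
      subsystem = fer, gene = "985684")
  irr("FRDC", "fumarate reductase (cytosol, NADH)",
      c(fum_c = -1, nadh_c = -1, h_c = -1, succ_c = 1, nad_c = 1),
      subsystem = fer, confidence = 2L)
  add("THD", "NAD(P) transhydrogenase (soluble)",
      c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
      subsystem = "redox", confidence = 1L)
  irr("PPA", "inorganic pyrophosphatase",
      c(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1), subsystem = "energy")

  ppp <- "pentose phosphate pathway (non-oxidative)"
  add("XYLI", "xylose isomerase", c(xyl_c = -1, xylu_c = 1), subsystem = ppp,
      confidence = 4L)
  irr("XYLK", "xylulokinase",
      c(xylu_c = -1, atp_c = -1, xu5p_c = 1, adp_c = 1, h_c = 1),
      subsystem = ppp, confidence = 4L)
  add("RPE", "ribulose-5P epimerase", c(ru5p_c = -1, xu5p_c = 1),
      subsystem = ppp)
  add("RPI", "ribose-5P isomerase", c(r5p_c = -1, ru5p_c = 1),
      subsystem = ppp)
  add("TKT1", "transketolase 1",
      c(xu5p_c = -1, r5p_c = -1, s7p_c = 1, g3p_c = 1), subsystem = ppp)
  add("TAL", "transaldolase",
      c(s7p_c = -1, g3p_c = -1, e4p_c = 1, f6p_c = 1), subsystem = ppp)
  add("TKT2", "transketolase 2",
      c(xu5p_c = -1, e4p_c = -1, f6p_c = 1, g3p_c = 1), subsystem = ppp)

  cat_ <- "substrate catabolism"
  irr("FRUK", "fructokinase",
      c(fru_c = -1, atp_c = -1, f6p_c = 1, adp_c = 1, h_c = 1),
      subsystem = cat_)
  irr("MANK", "mannose kinase",
      c(man_c = -1, atp_c = -1, man6p_c = 1, adp_c = 1, h_c = 1),
      subsystem = cat_)
  add("MAN6PI", "mannose-6P isomerase", c(man6p_c = -1, f6p_c = 1),
      subsystem = cat_)
  irr("GALKL", "galactokinase + Leloir pathway (lumped)",
      c(gal_c = -1, atp_c = -1, g1p_c = 1, adp_c = 1, h_c = 1),
      subsystem = cat_, confidence = 2L)
  add("PGMT", "phosphoglucomutase", c(g1p_c = -1, g6p_c = 1),
      subsystem = cat_)
  add("SBTD", "sorbitol dehydrogenase",
      c(srb_c = -1, nad_c = -1, fru_c = 1, nadh_c = 1, h_c = 1),
      subsystem = cat_)

  hyd <- "hydrogenosome"
  irr("ME", "malic enzyme (hydrogenosome, NAD+)",
      c(mal_h = -1, nad_h = -1, pyr_h = 1, co2_h = 1, nadh_h = 1),
      subsystem = hyd, confidence = 4L)
  irr("PFLH", "pyruvate formate lyase (hydrogenosome)",
      c(pyr_h = -1, coa_h = -1, accoa_h = 1, for_h = 1), subsystem = hyd,
      confidence = 4L, gene = "981064 or 1027775")
  irr("PFO", "pyruvate:ferredoxin oxidoreductase",
      c(pyr_h = -1, coa_h = -1, fdox_h = -1, accoa_h = 1, co2_h = 1,
        fdred_h = 1, h_h = 1), subsystem = hyd, confidence = 4L,
      gene = "623223")
  fdx_on <- config$hydrogenase == "ferredoxin" || config$keep_ferredoxin
  irr("FDXH2", "ferredoxin hydrogenase",
      c(fdred_h = -1, h_h = -2, fdox_h = 1, h2_h = 1), subsystem = hyd,
      ub = if (fdx_on) BIG else 0, confidence = 4L, gene = "1341048")
  add("H2DH", "hydrogen dehydrogenase (NAD+ + H2 -> NADH + H+)",
      c(h2_h = -1, nad_h = -1, nadh_h = 1, h_h = 1), subsystem = hyd,
      lb = if (config$h2_dehydrogenase_reversible) -BIG else 0,
      confidence = 2L, gene = "1718044")
  add("ASCT", "acetate:succinyl-CoA transferase",
      c(accoa_h = -1, succ_h = -1, ac_h = 1, succoa_h = 1), subsystem = hyd,
      confidence = 4L, gene = "1731457 or 1316948")
  add("SUCOAS", "succinyl-CoA synthetase",
      c(succoa_h = -1, adp_h = -1, pi_h = -1, succ_h = 1, coa_h = 1,
        atp_h = 1), subsystem = hyd, confidence = 4L,
      gene = "1636158 and 1276456")
  bs <- config$bifurcating_stoich
  bif_on <- config$hydrogenase == "bifurcating"
  add("BIFH", "bifurcating hydrogenase (speculative)",
      c(nadh_h = -bs[["nadh"]], fdred_h = -bs[["fd"]],
        h_h = -(bs[["nadh"]] + 2 * bs[["fd"]]),
        nad_h = bs[["nadh"]], fdox_h = bs[["fd"]], h2_h = bs[["h2"]]),
      subsystem = hyd, lb = 0, ub = if (bif_on) BIG else 0,
      speculative = TRUE, confidence = 1L, gene = "1341048 and 1047445")
  np <- config$protons_pumped_per_nadh
  add("CPLX12", "complex 1/2 proton-pumping module (speculative)",
      c(nadh_h = -1, fum_h = -1, h_h = -(1 + np), nad_h = 1, succ_h = 1,
        h_c = np), subsystem = hyd, lb = 0,
      ub = if (config$proton_module) BIG else 0, speculative = TRUE,
      confidence = 1L,
      gene = "1047445 and 993995 and 1702000 and 1688149")
  na_ <- config$protons_per_atp
  add("ATPS", "ATP synthase (hydrogenosome, speculative)",
      c(adp_h = -1, pi_h = -1, h_c = -na_, atp_h = 1, h2o_h = 1,
        h_h = na_ - 1), subsystem = hyd, lb = 0,
      ub = if (config$proton_module) BIG else 0, speculative = TRUE,
      confidence = 1L, gene = "1037070 and 1706307 and 1045818 and 1061751")

  trh <- "hydrogenosomal transport"
  # proton-compensated (electroneutral) anion transport; H+ itself does not
  # cross except through the explicit pumping module
  add("PYRTH", "pyruvate transport (H+ symport)",
      c(pyr_c = -1, h_c = -1, pyr_h = 1, h_h = 1), subsystem = trh,
      confidence = 1L)
  add("MALTH", "malate transport (2H+ symport)",
      c(mal_c = -1, h_c = -2, mal_h = 1, h_h = 2), subsystem = trh,
      confidence = 1L)
  add("FUMTH", "fumarate transport (2H+ symport)",
      c(fum_c = -1, h_c = -2, fum_h = 1, h_h = 2), subsystem = trh,
      confidence = 1L)
  add("SUCCTH", "succinate transport (2H+ symport)",
      c(succ_h = -1, h_h = -2, succ_c = 1, h_c = 2), subsystem = trh,
      confidence = 1L)
  add("ACTH", "acetate transport (H+ symport)",
      c(ac_h = -1, h_h = -1, ac_c = 1, h_c = 1), subsystem = trh,
      confidence = 1L)
  add("FORTH", "formate transport (H+ symport)",
      c(for_h = -1, h_h = -1, for_c = 1, h_c = 1), subsystem = trh,
      confidence = 1L)
  add("PITH", "phosphate transport (2H+ symport)",
      c(pi_c = -1, h_c = -2, pi_h = 1, h_h = 2), subsystem = trh,
      confidence = 1L)
  add("ATPADPTH", "ATP/ADP antiport (H+ compensated)",
      c(atp_h = -1, adp_c = -1, h_h = -1, atp_c = 1, adp_h = 1, h_c = 1),
      subsystem = trh, confidence = 1L)
  add("CO2TH", "CO2 diffusion", c(co2_c = -1, co2_h = 1), subsystem = trh)
  add("H2TH", "H2 diffusion", c(h2_h = -1, h2_c = 1), subsystem = trh)
  add("H2OTH", "water diffusion", c(h2o_c = -1, h2o_h = 1), subsystem = trh)

  caz <- "extracellular CAZyme hydrolysis"
  irr("CELLBH", "beta-glucosidase (extracellular)",
      c(cellb_e = -1, h2o_e = -1, glc_e = 2), subsystem = caz,
      confidence = 4L)
  irr("MALTH2", "maltase (extracellular)",
      c(malt_e = -1, h2o_e = -1, glc_e = 2), subsystem = caz)
  irr("SUCRH", "invertase (extracellular)",
      c(sucr_e = -1, h2o_e = -1, glc_e = 1, fru_e = 1), subsystem = caz)
  irr("RAFFH", "raffinase (extracellular)",
      c(raff_e = -1, h2o_e = -2, glc_e = 1, fru_e = 1, gal_e = 1),
      subsystem = caz)
  irr("CELLULH", "generalized cellulase",
      c(cellul_e = -1, h2o_e = -1, glc_e = 1), subsystem = caz,
      confidence = 4L)
  irr("MDXH", "amylase (extracellular)",
      c(mdx_e = -1, h2o_e = -1, glc_e = 1), subsystem = caz)
  irr("XYLANH", "generalized hemicellulase",
      c(xylan_e = -1, h2o_e = -1, xyl_e = 1), subsystem = caz,
      confidence = 4L)
  irr("LIGNOCH", "lignocellulolytic hydrolysis (lumped)",
      c(lignoc_e = -1, h2o_e = -2, glc_e = 1, xyl_e = 1), subsystem = caz)

  trp <- "plasma membrane transport"
  for (s in c("glc", "fru", "gal", "man", "srb", "xyl", "glyc", "lac",
              "etoh", "for", "ac", "succ", "h2", "co2", "h2o", "nh4", "h2s",
              "pi", "h")) {
    add(paste0(toupper(s), "T"), paste0(s, " transport (plasma membrane)"),
        stats::setNames(c(-1, 1), paste0(s, c("_e", "_c"))),
        subsystem = trp, confidence = 1L)
  }
  for (v in vit) {
    if (v == "fol") next # no folate salvage transporter
    add(paste0(toupper(v), "T"), paste0(v, " transport (plasma membrane)"),
        stats::setNames(c(-1, 1), paste0(v, c("_e", "_c"))),
        subsystem = trp, confidence = 1L)
  }

  # --- lumped anabolism (monomer synthesis from glucose skeleton) ---
  ana <- "lumped anabolism"
  reg_row <- function(b) reg[reg$base == b, ]
  add_lump <- function(base, atp_cost = 0, cosub = NULL, note = NULL) {
    r <- reg_row(base)
    coefs <- lump_synthesis(base, r$formula, r$charge, atp_cost = atp_cost,
                            cosubstrates = cosub)
    names(coefs) <- paste0(names(coefs), "_c")
    irr(paste0("SYN_", toupper(base)),
        paste0(r$name, " synthesis (lumped)"), coefs, subsystem = ana,
        confidence = 2L)
  }
  for (a in aa) add_lump(a)
  for (nmp in c("amp", "gmp", "cmp", "ump", "dtmp")) add_lump(nmp)
  add_lump("glcnac")
  for (fa in c("ttdca", "hdca", "ocdca")) add_lump(fa)
  add_lump("glyc")
  for (v in vitamin_synth_ids()) {
    if (v == "fol") {
      add_lump("fol", atp_cost = 2,
               cosub = list(pab = list(f = "C7H6NO2", z = -1, n = 1)))
    } else add_lump(v, atp_cost = 2)
  }
  # nucleotide phosphorylation chain (real kinases; anhydride bonds cost ATP)
  nk <- "nucleotide interconversion"
  add("ADK", "adenylate kinase", c(amp_c = -1, atp_c = -1, adp_c = 2),
      subsystem = nk)
  for (p in list(c("gmp", "gdp"), c("cmp", "cdp"), c("ump", "udp"),
                 c("dtmp", "dtdp"))) {
    add(paste0("NMPK_", toupper(p[1])), paste0(p[1], " kinase"),
        stats::setNames(c(-1, -1, 1, 1),
                        c(paste0(p[1], "_c"), "atp_c", paste0(p[2], "_c"),
                          "adp_c")), subsystem = nk)
  }
  for (p in list(c("gdp", "gtp"), c("cdp", "ctp"), c("udp", "utp"),
                 c("dadp", "datp"), c("dgdp", "dgtp"), c("dcdp", "dctp"),
                 c("dtdp", "dttp"))) {
    add(paste0("NDPK_", toupper(p[1])), paste0(p[1], " kinase"),
        stats::setNames(c(-1, -1, 1, 1),
                        c(paste0(p[1], "_c"), "atp_c", paste0(p[2], "_c"),
                          "adp_c")), subsystem = nk)
  }
  for (p in list(c("adp", "dadp"), c("gdp", "dgdp"), c("cdp", "dcdp"))) {
    irr(paste0("RNR_", toupper(p[1])), "ribonucleotide reductase",
        stats::setNames(c(-1, -1, -1, 1, 1, 1),
                        c(paste0(p[1], "_c"), "nadph_c", "h_c",
                          paste0(p[2], "_c"), "nadp_c", "h2o_c")),
        subsystem = nk)
  }

  # --- exchanges ---
  open_inorganic <- c("h2o", "h", "co2", "nh4", "h2s", "pi")
  secreted <- c("lac", "etoh", "for", "ac", "succ", "h2", "glyc")
  closed_carbon <- c("fru", "gal", "man", "srb", "xyl", "cellb", "malt",
                     "sucr", "raff", "cellul", "xylan", "mdx", "lignoc",
                     "pectin", "arab", "rmn", "cit", "meoh", "glcnac", "pyr",
                     "oaa", "mal", "fum", "phe", "arg", "leu", "pro", "ser",
                     "thr")
  exch <- function(base, lb, ub = BIG) {
    add(paste0("EX_", base, "_e"), paste0(base, " exchange"),
        stats::setNames(-1, paste0(base, "_e")), lb = lb, ub = ub,
        kind = "exchange", subsystem = "exchange")
  }
  exch("glc", -config$glucose_uptake)
  for (b in open_inorganic) exch(b, -BIG)
  for (b in secreted) exch(b, 0)
  for (b in closed_carbon) exch(b, 0)
  for (v in vit) exch(v, -1)

  # --- biomass ---
  stopifnot(inherits(biomass, "biomass_reaction"))
  add(biomass$id, biomass$name, biomass$stoichiometry, lb = 0, ub = BIG,
      kind = "biomass", subsystem = "biomass")

  rx_tbl <- dplyr::bind_rows(rxns)
  st_tbl <- dplyr::bind_rows(st)

  model <- metabolic_model(
    metabolites, rx_tbl, st_tbl, objective = biomass$id,
    id = paste0("nlan_core_", config$hydrogenase,
                if (config$proton_module) "_proton" else ""),
    provenance = c(
      "curated core-scale network; three compartments (c, h, e)",
      sprintf("scenario: hydrogenase=%s, proton_module=%s, h2dh_reversible=%s",
              config$hydrogenase, config$proton_module,
              config$h2_dehydrogenase_reversible),
      "speculative reactions bounded to zero unless enabled by the scenario"))
  attr(model, "vitamin_exchanges") <- paste0("EX_", vit, "_e")
  attr(model, "config") <- config
  attr(model, "biomass") <- biomass

  if (config$hydrogenase == "bifurcating") {
    log_info("scenario toggle: bifurcating hydrogenase enabled%s",
             if (config$keep_ferredoxin) " (ferredoxin hydrogenase kept)"
             else ", ferredoxin hydrogenase bounds set to (0, 0)")
  }
  if (config$proton_module) {
    log_info("scenario toggle: proton-pumping module and ATP synthase enabled")
  }
  if (config$h2_dehydrogenase_reversible) {
    log_info("bound override: hydrogen dehydrogenase made reversible")
  }

  viol <- check_balance(model)
  if (nrow(viol)) {
    stop("unbalanced reaction(s) in core model build: ",
         paste(unique(viol$reaction), collapse = ", "), call. = FALSE)
  }
  model
}

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("hydrogem.verbose", FALSE))) {
    rlang::inform(paste0("INFO ", sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Fully assembled core model with biomass and maintenance
#'
#' Convenience wrapper: compiles the biomass reaction from a composition and
#' monomer distribution, builds the core network for a scenario, and attaches
#' the non-growth-associated maintenance reaction.
#'
#' @param config A [scenario_config()].
#' @param composition A [biomass_composition()].
#' @param distribution A [monomer_distribution()].
#' @return A ready-to-solve `metabolic_model`.
#' @export
nlan_core_model <- function(config = scenario_config(),
                            composition = biomass_composition(),
                            distribution = monomer_distribution()) {
  bm <- build_biomass_reaction(composition, distribution)
  m <- build_core_model(config, bm)
  attach_maintenance(m, composition)
}
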
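#' Measured macromolecular biomass composition
#'
#' Defaults are the experimentally measured dry-mass fractions of
#' *N. lanati*: carbohydrate 32.4%, protein 43.7%, lipid 4.9%, DNA 0.2%,
#' RNA 0.6% (raw sum 81.8%), with growth-associated maintenance (GAM)
#' 75.98 mmol ATP/gDW and non-growth-associated maintenance (NGAM)
#' 2.27 mmol ATP/gDW/h. Note on units: GAM multiplies the growth rate
#' (mmol ATP per gram biomass formed) while NGAM is a constant flux floor;
#' this is the standard convention even though source tables sometimes
#' transpose the "/h" between the two.
#'
#' @param carbohydrate,protein,lipid,dna,rna Mass fractions (g/gDW).
#' @param gam Growth-associated maintenance, mmol ATP/gDW.
#' @param ngam Non-growth-associated maintenance, mmol ATP/gDW/h.
#' @return A `biomass_composition` list.
#' @export
biomass_composition <- function(carbohydrate = 0.324, protein = 0.437,
                                lipid = 0.049, dna = 0.002, rna = 0.006,
                                gam = 75.98, ngam = 2.27) {
  fr <- c(carbohydrate = carbohydrate, protein = protein, lipid = lipid,
          dna = dna, rna = rna)
  if (any(fr < 0)) stop("mass fractions must be >= 0", call. = FALSE)
  if (sum(fr) > 1 + 1e-9) {
    stop("mass fractions sum to more than 1 g/gDW (", round(sum(fr), 4), ")",
         call. = FALSE)
  }
  if (protein == 0) stop("zero protein fraction: degenerate biomass",
                         call. = FALSE)
  if (gam < 0) stop("gam must be >= 0", call. = FALSE)
  if (ngam < 0) stop("ngam must be >= 0", call. = FALSE)
  structure(list(mass_fractions = fr, gam = gam, ngam = ngam),
            class = "biomass_composition")
}

#' Monomer distributions for the biomass reaction
#'
#' Mole-fraction vectors for the 20 proteinogenic amino acids, the four DNA
#' and four RNA nucleotides, and the three modeled saturated fatty acids
#' (myristate C14:0, palmitate C16:0, stearate C18:0). The amino-acid default
#' is a generic fungal proteome frequency vector; nucleotide defaults are
#' uniform; the fatty-acid default is equal thirds (a documented stand-in —
#' only the relative ratios of the three acids enter the biomass reaction).
#' All vectors are renormalized to sum to one and must be non-negative.
#'
#' @param amino_acids Named 20-vector of mole fractions (names are the
#'   lowercase 3-letter codes used by the model, e.g. `ala`).
#' @param dna_nucleotides Named 4-vector over `datp`, `dctp`, `dgtp`, `dttp`.
#' @param rna_nucleotides Named 4-vector over `atp`, `ctp`, `gtp`, `utp`.
#' @param fatty_acids Named 3-vector over `ttdca`, `hdca`, `ocdca`.
#' @return A `monomer_distribution` list.
#' @export
monomer_distribution <- function(
    amino_acids = c(ala = 0.0826, arg = 0.0553, asn = 0.0406, asp = 0.0546,
                    cys = 0.0137, gln = 0.0393, glu = 0.0674, gly = 0.0708,
                    his = 0.0227, ile = 0.0593, leu = 0.0966, lys = 0.0582,
                    met = 0.0241, phe = 0.0386, pro = 0.0472, ser = 0.0660,
                    thr = 0.0534, trp = 0.0109, tyr = 0.0292, val = 0.0687),
    dna_nucleotides = c(datp = 0.25, dctp = 0.25, dgtp = 0.25, dttp = 0.25),
    rna_nucleotides = c(atp = 0.25, ctp = 0.25, gtp = 0.25, utp = 0.25),
    fatty_acids = c(ttdca = 1 / 3, hdca = 1 / 3, ocdca = 1 / 3)) {
  norm <- function(v, nms) {
    if (!setequal(names(v), nms)) {
      stop("distribution must be named over: ", paste(nms, collapse = ", "),
           call. = FALSE)
    }
    v <- v[nms]
    if (any(v < 0)) stop("mole fractions must be >= 0", call. = FALSE)
    if (abs(sum(v) - 1) > 0.01) {
      stop("mole fractions must sum to ~1 (got ", round(sum(v), 4), ")",
           call. = FALSE)
    }
    v / sum(v)
  }
  structure(list(
    amino_acids = norm(amino_acids, amino_acid_ids()),
    dna_nucleotides = norm(dna_nucleotides,
                           c("datp", "dctp", "dgtp", "dttp")),
    rna_nucleotides = norm(rna_nucleotides, c("atp", "ctp", "gtp", "utp")),
    fatty_acids = norm(fatty_acids, c("ttdca", "hdca", "ocdca"))),
    class = "monomer_distribution")
}

#' Compile the biomass objective reaction
#'
#' Builds the pseudo-reaction that drains monomers (amino acids, dNTPs,
#' NTPs, N-acetylglucosamine for the chitin cell wall, the three fatty acids
#' plus a glycerol backbone as triacylglycerol equivalents) and GAM ATP
#' hydrolysis, scaled so that one unit of flux drains exactly 1 g dry weight
#' per hour. Polymerization water (and pyrophosphate for nucleic acids) is
#' released. Measured mass fractions are proportionally renormalized from
#' their raw sum to 1 g by default; `normalization = "ash"` instead keeps
#' the measured fractions and treats the unaccounted remainder as inert.
#'
#' @param composition A [biomass_composition()].
#' @param distribution A [monomer_distribution()].
#' @param normalization `"renormalize"` (default) or `"ash"`.
#' @return A `biomass_reaction` object; attributes carry the
#'   pre-normalization fraction sum, the drained mass per flux unit and the
#'   drained carbon (mmol C per gDW).
#' @export
build_biomass_reaction <- function(composition = biomass_composition(),
                                   distribution = monomer_distribution(),
                                   normalization = c("renormalize", "ash")) {
  stopifnot(inherits(composition, "biomass_composition"),
            inherits(distribution, "monomer_distribution"))
  normalization <- match.arg(normalization)
  reg <- species_registry()
  mw <- stats::setNames(formula_weight(reg$formula), reg$base)
  mw_h2o <- mw[["h2o"]]
  fr <- composition$mass_fractions
  pre_sum <- sum(fr)
  if (normalization == "renormalize") fr <- fr / pre_sum

  coef <- numeric(0)
  take <- function(ids, v) {
    ids <- paste0(ids, "_c")
    for (i in seq_along(ids)) {
      cur <- if (ids[i] %in% names(coef)) coef[[ids[i]]] else 0
      coef[ids[i]] <<- cur + v[i]
    }
  }
  # protein -> amino acids, releasing polymerization water
  f_aa <- distribution$amino_acids
  res_w <- mw[names(f_aa)] - mw_h2o
  n_prot <- 1000 * fr[["protein"]] / sum(f_aa * res_w)
  take(names(f_aa), -n_prot * f_aa)
  take("h2o", n_prot)
  # carbohydrate: chitin as N-acetylglucosamine residues
  n_chi <- 1000 * fr[["carbohydrate"]] / (mw[["glcnac"]] - mw_h2o)
  take("glcnac", -n_chi)
  take("h2o", n_chi)
  # RNA: NTPs, releasing pyrophosphate
  f_rna <- distribution$rna_nucleotides
  res_rna <- mw[names(f_rna)] - mw[["ppi"]]
  n_rna <- 1000 * fr[["rna"]] / sum(f_rna * res_rna)
  take(names(f_rna), -n_rna * f_rna)
  take("ppi", n_rna)
  # DNA: dNTPs, releasing pyrophosphate
  f_dna <- distribution$dna_nucleotides
  res_dna <- mw[names(f_dna)] - mw[["ppi"]]
  n_dna <- 1000 * fr[["dna"]] / sum(f_dna * res_dna)
  take(names(f_dna), -n_dna * f_dna)
  take("ppi", n_dna)
  # lipid: triacylglycerol equivalents of the three fatty acids
  f_fa <- distribution$fatty_acids
  mw_tag <- 3 * (sum(f_fa * mw[names(f_fa)]) + mw[["h"]]) + mw[["glyc"]] -
    3 * mw_h2o
  n_tag <- 1000 * fr[["lipid"]] / mw_tag
  take(names(f_fa), -3 * n_tag * f_fa)
  take("glyc", -n_tag)
  take("h", -3 * n_tag)
  take("h2o", 3 * n_tag)
  # vitamin/cofactor demands (tiny coefficients)
  cofactors <- setdiff(vitamin_ids(), "pab")
  take(cofactors, rep(-1e-5, length(cofactors)))
  # growth-associated maintenance ATP hydrolysis
  gam <- composition$gam
  take(c("atp", "h2o", "adp", "pi", "h"), c(-gam, -gam, gam, gam, gam))

  coef <- coef[abs(coef) > 0]
  # audits
  base_of <- sub("_c$", "", names(coef))
  mass_drained <- -sum(coef * mw[base_of]) / 1000
  carbon <- stats::setNames(parse_formula(reg$formula)$C, reg$base)
  carbon_drained <- -sum(coef * carbon[base_of])
  structure(list(id = "BIOMASS",
                 name = "biomass objective (measured composition)",
                 stoichiometry = coef,
                 composition = composition, distribution = distribution,
                 normalization = normalization),
            class = "biomass_reaction",
            pre_normalization_sum = pre_sum,
            mass_drained = mass_drained,
            carbon_drained = carbon_drained)
}

#' @export
print.biomass_reaction <- function(x, ...) {
  cat("<biomass_reaction> ", length(x$stoichiometry), " species; drains ",
      round(attr(x, "mass_drained"), 4), " g and ",
      round(attr(x, "carbon_drained"), 2), " mmol C per gDW; raw fraction ",
      "sum ", round(100 * attr(x, "pre_normalization_sum"), 1), "%\n",
      sep = "")
  invisible(x)
}

#' Attach the non-growth-associated maintenance reaction
#'
#' Adds the cytosolic ATP-hydrolysis maintenance reaction `ATPM`
#' (ATP + H₂O → ADP + Pi + H⁺) with lower bound `ngam`, the constant
#' maintenance-energy floor. The growth-associated term is already embedded
#' in the biomass reaction by [build_biomass_reaction()].
#'
#' @param model A `metabolic_model` without a maintenance reaction.
#' @param composition A [biomass_composition()] supplying `ngam`.
#' @return The model with the maintenance reaction attached.
#' @export
attach_maintenance <- function(model, composition = biomass_composition()) {
  if (any(model$reactions$kind == "maintenance")) {
    stop("model already has a maintenance reaction", call. = FALSE)
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = "ATPM", name = "ATP maintenance requirement",
                   lower_bound = composition$ngam, upper_bound = BIG,
                   kind = "maintenance", subsystem = "energy",
                   speculative = FALSE, confidence = 4L,
                   gene_association = NA_character_))
  model$stoichiometry <- dplyr::bind_rows(
    model$stoichiometry,
    tibble::tibble(reaction = "ATPM",
                   metabolite = c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c"),
                   coefficient = c(-1, -1, 1, 1, 1)))
  model
}
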
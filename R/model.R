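#' Construct a compartmentalized stoichiometric model
#'
#' The model is the single source of truth for all linear-programming stages.
#' It is an S3 object (`metabolic_model`) holding three tibbles: metabolites,
#' reactions and a long-format stoichiometry table. Flux units are
#' mmol/gDW/h; uptake is negative, secretion positive; metabolite ids carry a
#' compartment suffix (`_c` cytosol, `_h` hydrogenosome, `_e` extracellular).
#'
#' @param metabolites Tibble with columns `id`, `name`, `formula`, `charge`,
#'   `compartment`.
#' @param reactions Tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `kind` (one of internal, exchange, biomass, maintenance,
#'   demand), `subsystem`, `speculative`, `confidence`, `gene_association`.
#' @param stoichiometry Long tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param objective Reaction id of the objective (usually the biomass
#'   reaction).
#' @param id Model identifier.
#' @param provenance Free-text notes.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective, id = "model",
                            provenance = character()) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_comp <- setdiff(unique(metabolites$compartment), c("c", "h", "e"))
  if (length(bad_comp)) {
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  }
  missing_met <- setdiff(stoichiometry$metabolite, metabolites$id)
  if (length(missing_met)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(missing_met, collapse = ", "), call. = FALSE)
  }
  missing_rxn <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(missing_rxn)) {
    stop("stoichiometry references unknown reactions: ",
         paste(missing_rxn, collapse = ", "), call. = FALSE)
  }
  if (any(reactions$lower_bound > reactions$upper_bound + 1e-12)) {
    bad <- reactions$id[reactions$lower_bound > reactions$upper_bound + 1e-12]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!objective %in% reactions$id) {
    stop("objective reaction not in model: ", objective, call. = FALSE)
  }
  parse_formula(metabolites$formula) # validates
  structure(
    list(id = id,
         compartments = c("c", "h", "e"),
         metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         objective = objective,
         provenance = provenance),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  objective: ", x$objective, "\n", sep = "")
  kinds <- table(x$reactions$kind)
  cat("  kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Dense stoichiometric matrix (metabolites x reactions).
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  idx <- cbind(match(model$stoichiometry$metabolite, model$metabolites$id),
               match(model$stoichiometry$reaction, model$reactions$id))
  S[idx] <- model$stoichiometry$coefficient
  S
}

#' Set reaction bounds
#'
#' @param model A `metabolic_model`.
#' @param reaction Reaction id(s).
#' @param lower,upper New bounds (recycled; `NA` leaves a bound unchanged).
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NA, upper = NA) {
  i <- match(reaction, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction(s): ",
         paste(reaction[is.na(i)], collapse = ", "), call. = FALSE)
  }
  lower <- rep_len(lower, length(i)); upper <- rep_len(upper, length(i))
  model$reactions$lower_bound[i] <-
    ifelse(is.na(lower), model$reactions$lower_bound[i], lower)
  model$reactions$upper_bound[i] <-
    ifelse(is.na(upper), model$reactions$upper_bound[i], upper)
  model
}

#' Check mass and charge balance of internal reactions
#'
#' Exchange, biomass, maintenance and demand reactions are exempt; every
#' other reaction must have zero net count for each of C, H, N, O, P, S and
#' for charge, computed from the metabolite formulas.
#'
#' @param model A `metabolic_model`.
#' @param tol Numerical tolerance on the per-element sums.
#' @return A tibble of violations with columns `reaction`, `element`,
#'   `imbalance`; zero rows iff the model is balanced.
#' @export
check_balance <- function(model, tol = 1e-9) {
  exempt <- c("exchange", "biomass", "maintenance", "demand")
  rxns <- model$reactions$id[!model$reactions$kind %in% exempt]
  elems <- as.matrix(parse_formula(model$metabolites$formula))
  elems <- cbind(elems, charge = model$metabolites$charge)
  rownames(elems) <- model$metabolites$id
  st <- model$stoichiometry[model$stoichiometry$reaction %in% rxns, ]
  contrib <- elems[st$metabolite, , drop = FALSE] * st$coefficient
  sums <- rowsum(contrib, group = st$reaction)
  bad <- which(abs(sums) > tol, arr.ind = TRUE)
  tibble::tibble(
    reaction = rownames(sums)[bad[, 1]],
    element = colnames(sums)[bad[, 2]],
    imbalance = sums[bad])
}

#' Restrict the medium to a single carbon source
#'
#' Closes the uptake (lower) bound of every carbon-bearing exchange except
#' the named substrate, whose uptake is set to `uptake_limit` scaled to
#' glucose-carbon equivalents (`uptake_limit * 6 / substrate carbon count`),
#' so that polymeric substrates are not trivially advantaged. Vitamin and
#' mineral exchanges are untouched.
#'
#' @param model A `metabolic_model`.
#' @param substrate Extracellular metabolite id without the `_e` suffix
#'   (e.g. `"glc"`, `"cellb"`).
#' @param uptake_limit Uptake limit in glucose-equivalent mmol/gDW/h
#'   (positive number; applied as a negative lower bound).
#' @return The modified model.
#' @export
set_sole_carbon_source <- function(model, substrate, uptake_limit = 1.5) {
  ex_id <- paste0("EX_", substrate, "_e")
  if (!ex_id %in% model$reactions$id) {
    stop("unknown substrate (no exchange reaction): ", substrate,
         call. = FALSE)
  }
  met <- paste0(substrate, "_e")
  ccount <- parse_formula(
    model$metabolites$formula[model$metabolites$id == met])$C
  if (ccount == 0) stop(substrate, " carries no carbon", call. = FALSE)
  # carbon-bearing, non-vitamin exchanges
  elems <- parse_formula(model$metabolites$formula)
  carbon_mets <- model$metabolites$id[elems$C > 0 &
                                        model$metabolites$compartment == "e"]
  st <- model$stoichiometry
  ex_rxns <- model$reactions$id[model$reactions$kind == "exchange"]
  carbon_ex <- st$reaction[st$reaction %in% ex_rxns &
                             st$metabolite %in% carbon_mets]
  vitamins <- attr(model, "vitamin_exchanges")
  carbon_ex <- setdiff(carbon_ex, vitamins)
  model <- set_bounds(model, carbon_ex, lower = 0)
  set_bounds(model, ex_id, lower = -uptake_limit * 6 / ccount)
}

#' Write a model to a JSON file
#'
#' The dialect is `{id, compartments, metabolites[], reactions[], objective}`
#' with reaction bounds serialized as `[lb, ub]` pairs at full double
#' precision, so a write/read round trip reproduces the model exactly. A
#' descriptive schema ships in `inst/extdata/model-schema.json`.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rx <- model$reactions
  st <- split(model$stoichiometry[, c("metabolite", "coefficient")],
              model$stoichiometry$reaction)
  rx_list <- lapply(seq_len(nrow(rx)), function(i) {
    s <- st[[rx$id[i]]]
    list(id = rx$id[i], name = rx$name[i],
         bounds = c(rx$lower_bound[i], rx$upper_bound[i]),
         kind = rx$kind[i], subsystem = rx$subsystem[i],
         speculative = rx$speculative[i], confidence = rx$confidence[i],
         gene_association = rx$gene_association[i],
         stoichiometry = stats::setNames(as.list(s$coefficient),
                                         s$metabolite))
  })
  mets <- model$metabolites
  met_list <- lapply(seq_len(nrow(mets)), function(i) {
    list(id = mets$id[i], name = mets$name[i], formula = mets$formula[i],
         charge = mets$charge[i], compartment = mets$compartment[i])
  })
  obj <- list(id = model$id, compartments = as.list(model$compartments),
              metabolites = met_list, reactions = rx_list,
              objective = model$objective,
              provenance = as.list(model$provenance),
              vitamin_exchanges = as.list(attr(model, "vitamin_exchanges")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model from a JSON file
#'
#' @param path Path to a model JSON file written by [write_model()] (or
#'   conforming to the same dialect).
#' @return A `metabolic_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path)
  for (key in c("id", "metabolites", "reactions", "objective")) {
    if (is.null(j[[key]])) {
      stop("model file parse error at /", key, ": missing key",
           call. = FALSE)
    }
  }
  mets <- purrr::map_dfr(seq_along(j$metabolites), function(i) {
    m <- j$metabolites[[i]]
    for (key in c("id", "formula", "charge", "compartment")) {
      if (is.null(m[[key]])) {
        stop("model file parse error at /metabolites/", i - 1, "/", key,
             ": missing key", call. = FALSE)
      }
    }
    tibble::tibble(id = m$id, name = m$name %||% m$id, formula = m$formula,
                   charge = as.numeric(m$charge), compartment = m$compartment)
  })
  rx <- purrr::map_dfr(seq_along(j$reactions), function(i) {
    r <- j$reactions[[i]]
    for (key in c("id", "bounds", "kind", "stoichiometry")) {
      if (is.null(r[[key]])) {
        stop("model file parse error at /reactions/", i - 1, "/", key,
             ": missing key", call. = FALSE)
      }
    }
    tibble::tibble(id = r$id, name = r$name %||% r$id,
                   lower_bound = as.numeric(r$bounds[[1]]),
                   upper_bound = as.numeric(r$bounds[[2]]),
                   kind = r$kind, subsystem = r$subsystem %||% "",
                   speculative = isTRUE(r$speculative),
                   confidence = as.integer(r$confidence %||% 0L),
                   gene_association = r$gene_association %||% NA_character_)
  })
  st <- purrr::map_dfr(j$reactions, function(r) {
    tibble::tibble(reaction = r$id,
                   metabolite = names(r$stoichiometry),
                   coefficient = as.numeric(unlist(r$stoichiometry)))
  })
  m <- metabolic_model(mets, rx, st, objective = j$objective, id = j$id,
                       provenance = unlist(j$provenance) %||% character())
  attr(m, "vitamin_exchanges") <- unlist(j$vitamin_exchanges) %||%
    grep("^EX_(pydxn|pab|btn|cbl|ribflv|fol|pnto|nac|thm|pheme)_e$",
         rx$id, value = TRUE)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
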
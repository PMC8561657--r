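#' Parse an elemental formula
#'
#' Formulas are restricted to the CHONPS alphabet with non-negative integer
#' counts (e.g. `"C6H12O6"`). An empty string is a valid formula with zero
#' atoms and is used for abstract electron carriers such as ferredoxin.
#'
#' @param formula A character vector of formulas.
#' @return A tibble with one row per formula and integer columns
#'   `C`, `H`, `N`, `O`, `P`, `S`.
#' @export
#' @examples
#' parse_formula(c("C6H12O6", "HO4P", ""))
parse_formula <- function(formula) {
  elements <- c("C", "H", "N", "O", "P", "S")
  out <- matrix(0L, nrow = length(formula), ncol = length(elements),
                dimnames = list(NULL, elements))
  for (i in seq_along(formula)) {
    f <- formula[[i]]
    if (is.na(f)) {
      stop("formula is NA at position ", i, call. = FALSE)
    }
    if (!nzchar(f)) next
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    parts <- regmatches(f, list(tokens))[[1]]
    if (!nzchar(f) || sum(nchar(parts)) != nchar(f)) {
      stop("unparseable formula: '", f, "'", call. = FALSE)
    }
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% elements) {
        stop("formula '", f, "' contains element outside CHONPS: ", el,
             call. = FALSE)
      }
      out[i, el] <- out[i, el] + n
    }
  }
  tibble::as_tibble(as.data.frame(out))
}

#' Molecular weight of a formula
#'
#' Monoisotopic-free average atomic masses; adequate for gram-scale biomass
#' bookkeeping.
#'
#' @param formula Character vector of CHONPS formulas.
#' @return Numeric vector of molecular weights in g/mol.
#' @export
formula_weight <- function(formula) {
  masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974,
              S = 32.06)
  m <- as.matrix(parse_formula(formula))
  as.numeric(m %*% masses[colnames(m)])
}

# Balance a lumped biosynthesis reaction for a single product.
#
# Carbon is drawn from glucose, nitrogen from NH4+, sulfur from H2S and
# phosphorus from inorganic phosphate; the remaining hydrogen, oxygen and
# charge balance is closed exactly with an NADPH/NADP+ couple, water and
# protons (a uniquely solvable 3x3 linear system). Extra ATP hydrolysis can
# be added; it is chemically self-balanced. Returns a named coefficient
# vector over metabolite ids WITHOUT compartment suffix (negative =
# consumed), including the product at +1.
lump_synthesis <- function(product_id, product_formula, product_charge,
                           atp_cost = 0, cosubstrates = NULL) {
  species <- list(
    glc  = list(f = "C6H12O6", z = 0),
    nh4  = list(f = "H4N", z = 1),
    h2s  = list(f = "H2S", z = 0),
    pi   = list(f = "HO4P", z = -2)
  )
  prod <- c(as.matrix(parse_formula(product_formula))[1, ], z = product_charge)
  need <- prod
  coefs <- c()
  coefs[product_id] <- 1
  if (!is.null(cosubstrates)) {
    # named list: id -> list(f, z, n) consumed n times
    for (id in names(cosubstrates)) {
      cs <- cosubstrates[[id]]
      v <- c(as.matrix(parse_formula(cs$f))[1, ], z = cs$z)
      need <- need - cs$n * v
      coefs[id] <- -cs$n
    }
  }
  x_glc <- need[["C"]] / 6
  x_nh4 <- need[["N"]]
  x_h2s <- need[["S"]]
  x_pi  <- need[["P"]]
  if (x_glc < -1e-12) stop("lump for ", product_id, ": negative glucose")
  rem <- need
  for (nm in names(species)) {
    xs <- c(glc = x_glc, nh4 = x_nh4, h2s = x_h2s, pi = x_pi)[[nm]]
    v <- c(as.matrix(parse_formula(species[[nm]]$f))[1, ], z = species[[nm]]$z)
    rem <- rem - xs * v
    if (abs(xs) > 1e-12) {
      cur <- if (nm %in% names(coefs)) coefs[[nm]] else 0
      coefs[nm] <- cur - xs
    }
  }
  # remaining H, O, charge closed by (nadph - nadp), h2o, h:
  #   nadph couple contributes per unit: H +1, O 0, charge -1
  #   h2o: H +2, O +1, charge 0 ; h: H +1, O 0, charge +1
  M <- matrix(c(1, 2, 1,   # H
                0, 1, 0,   # O
                -1, 0, 1), # charge
              nrow = 3, byrow = TRUE)
  sol <- solve(M, c(rem[["H"]], rem[["O"]], rem[["z"]]))
  x_nadph <- sol[1]; x_h2o <- sol[2]; x_h <- sol[3]
  add <- function(id, v) {
    if (abs(v) > 1e-12) {
      cur <- if (id %in% names(coefs)) coefs[[id]] else 0
      coefs[id] <<- cur + v
    }
  }
  add("nadph", -x_nadph); add("nadp", x_nadph)
  add("h2o", -x_h2o); add("h", -x_h)
  if (atp_cost != 0) {
    add("atp", -atp_cost); add("h2o", -atp_cost)
    add("adp", atp_cost); add("pi", atp_cost); add("h", atp_cost)
  }
  coefs[abs(coefs) > 1e-12 | names(coefs) == product_id]
}
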
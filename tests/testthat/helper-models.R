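# Shared fixtures: cached core models, toy networks, and an exhaustive
# vertex-enumeration oracle for small LPs.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

base_model <- function() cached("base", nlan_core_model())

gen_model <- function() cached("gen_model", nlan_core_model())

fit0 <- function() {
  cached("fit0", {
    des <- cached("design",
                  growth_experiment_design(generator_spec(seed = 1,
                                                          noise_cv = 0)))
    exps <- generate_growth_experiments(generator_spec(seed = 1,
                                                       noise_cv = 0),
                                        design = des)
    fit_maintenance(gen_model(), exps)
  })
}

emu_net <- function() {
  cached("emu_net", {
    nd <- mfa_network_core()
    emu_decompose(nd$maps, nd$targets, nd$inputs)
  })
}

bif_model <- function() {
  cached("bif", nlan_core_model(scenario_config("bifurcating")))
}

proton_model <- function() {
  cached("proton", nlan_core_model(scenario_config(proton_module = TRUE)))
}

# build a small model from a list of reactions; metabolites get empty
# formulas (balance checking is not the point of these toys)
toy_model <- function(reactions, objective, mets = NULL) {
  st <- purrr::map_dfr(reactions, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coefficient = unname(r$stoich))
  })
  met_ids <- mets %||% unique(st$metabolite)
  mets_tbl <- tibble::tibble(id = met_ids, name = met_ids, formula = "",
                             charge = 0, compartment = "c")
  rx <- purrr::map_dfr(reactions, function(r) {
    tibble::tibble(id = r$id, name = r$id,
                   lower_bound = r$lb %||% 0, upper_bound = r$ub %||% 10,
                   kind = r$kind %||% "internal", subsystem = "",
                   speculative = FALSE, confidence = 0L,
                   gene_association = NA_character_)
  })
  metabolic_model(mets_tbl, rx, st, objective = objective, id = "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear chain ->A->B->C-> with capacity 10
chain_model <- function() {
  toy_model(list(
    list(id = "in", stoich = c(A = 1), kind = "exchange"),
    list(id = "r1", stoich = c(A = -1, B = 1)),
    list(id = "r2", stoich = c(B = -1, C = 1)),
    list(id = "out", stoich = c(C = -1), kind = "exchange")),
    objective = "out")
}

# diamond: two parallel routes from A to B
diamond_model <- function() {
  toy_model(list(
    list(id = "in", stoich = c(A = 1), kind = "exchange"),
    list(id = "left", stoich = c(A = -1, B = 1)),
    list(id = "right", stoich = c(A = -1, B = 1)),
    list(id = "out", stoich = c(B = -1), kind = "exchange")),
    objective = "out")
}

# one degree of freedom: a single free flux through a box [0, 1]
box_model <- function() {
  toy_model(list(
    list(id = "in", stoich = c(A = 1), lb = 0, ub = 1, kind = "exchange"),
    list(id = "out", stoich = c(A = -1), lb = 0, ub = 1,
         kind = "exchange")),
    objective = "out")
}

# exhaustive vertex enumeration for max c'v s.t. Sv = 0, lb <= v <= ub
# (oracle for n <= ~8 reactions)
enumerate_lp_optimum <- function(obj, S, lb, ub) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  best <- -Inf
  feasible_any <- FALSE
  combos <- utils::combn(n, nfix, simplify = FALSE)
  for (fix in combos) {
    freev <- setdiff(seq_len(n), fix)
    Sf <- S[, freev, drop = FALSE]
    if (qr(Sf)$rank < r) next
    grid <- expand.grid(rep(list(c(1, 2)), nfix))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fix] <- ifelse(unlist(grid[g, ]) == 1, lb[fix], ub[fix])
      rhs <- -S[, fix, drop = FALSE] %*% v[fix]
      sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(S[, freev, drop = FALSE] %*% sol - rhs)) > 1e-8) next
      v[freev] <- sol
      if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9)) {
        feasible_any <- TRUE
        best <- max(best, sum(obj * v))
      }
    }
  }
  list(feasible = feasible_any, optimum = best)
}
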
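# Flux balance analysis and friends on a metabolic_model.

lp_parts <- function(model) {
  S <- stoich_matrix(model)
  list(S = S,
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       obj = as.numeric(model$reactions$id == model$objective),
       rxn = model$reactions$id)
}

new_flux_solution <- function(status, objective, fluxes, rxn, kind = "fba") {
  structure(list(status = status, objective_value = objective,
                 fluxes = tibble::tibble(reaction = rxn,
                                         flux = as.numeric(fluxes)),
                 kind = kind),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> (", x$kind, ") status: ", x$status,
      "  objective: ", signif(x$objective_value, 6), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction (by default the biomass reaction, whose
#' flux is the specific growth rate \eqn{\mu} in 1/h) subject to the
#' steady-state constraint \eqn{S v = 0} and the reaction bounds.
#'
#' @param model A `metabolic_model`.
#' @param objective Optional reaction id to maximize instead of the model
#'   objective.
#' @return A `flux_solution` with `status`, `objective_value` and a tibble of
#'   `fluxes`. Infeasibility or unboundedness is reported in `status`, never
#'   silently.
#' @export
fba <- function(model, objective = NULL) {
  p <- lp_parts(model)
  obj <- p$obj
  if (!is.null(objective)) {
    if (!objective %in% p$rxn) stop("unknown objective: ", objective,
                                    call. = FALSE)
    obj <- as.numeric(p$rxn == objective)
  }
  r <- solve_lp(obj, p$S, rep(0, nrow(p$S)), p$lb, p$ub)
  new_flux_solution(r$status, r$objective, r$x, p$rxn)
}

#' Parsimonious flux balance analysis
#'
#' Stage 1 fixes the objective at `objective_fraction` of its FBA optimum;
#' stage 2 minimizes the total absolute flux \eqn{\sum_i |v_i|} by splitting
#' every reaction into irreversible forward/backward parts (no integer
#' programming). Returns the minimal-total-flux solution; used throughout as
#' the device that picks a unique representative from alternate optima.
#'
#' @inheritParams fba
#' @param objective_fraction Fraction of the FBA optimum to retain (default 1).
#' @return A `flux_solution`; the attribute `total_flux` carries
#'   \eqn{\sum|v|}.
#' @export
pfba <- function(model, objective_fraction = 1.0, objective = NULL) {
  p <- lp_parts(model)
  obj <- p$obj
  if (!is.null(objective)) obj <- as.numeric(p$rxn == objective)
  r1 <- solve_lp(obj, p$S, rep(0, nrow(p$S)), p$lb, p$ub)
  if (r1$status != "optimal") {
    return(new_flux_solution(r1$status, NA_real_, rep(NA_real_, length(p$rxn)),
                             p$rxn, kind = "pfba"))
  }
  opt <- r1$objective
  n <- ncol(p$S)
  # v = v+ - v-, v+, v- >= 0; minimize sum(v+) + sum(v-)
  S2 <- cbind(p$S, -p$S)
  lb2 <- c(pmax(p$lb, 0), pmax(-p$ub, 0))
  ub2 <- c(pmax(p$ub, 0), pmax(-p$lb, 0))
  # objective-fraction constraint as an extra row with a slack variable:
  # obj'v - s = fraction*opt, s >= 0
  A <- rbind(cbind(S2, 0), c(obj, -obj, -1))
  rhs <- c(rep(0, nrow(p$S)), objective_fraction * opt)
  lb2 <- c(lb2, 0); ub2 <- c(ub2, 2 * abs(opt) + BIG)
  cost <- c(rep(-1, 2 * n), 0)
  r2 <- solve_lp(cost, A, rhs, lb2, ub2)
  if (r2$status != "optimal") {
    return(new_flux_solution(r2$status, NA_real_, rep(NA_real_, length(p$rxn)),
                             p$rxn, kind = "pfba"))
  }
  v <- r2$x[1:n] - r2$x[(n + 1):(2 * n)]
  sol <- new_flux_solution("optimal", sum(obj * v), v, p$rxn, kind = "pfba")
  attr(sol, "total_flux") <- sum(abs(v))
  sol
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux with the objective constrained to at
#' least `objective_fraction` of its FBA optimum (two LPs per reaction).
#'
#' @inheritParams fba
#' @param objective_fraction Fraction of the optimum to retain (default 0.9,
#'   reflecting the assumption that the fungus maintains a near-maximal
#'   growth rate to compete in its native microbiome).
#' @param reactions Optional subset of reaction ids (default: all).
#' @return A tibble with columns `reaction`, `min_flux`, `max_flux` and the
#'   attribute `objective_fraction`; class `flux_ranges`.
#' @export
fva <- function(model, objective_fraction = 0.9, reactions = NULL) {
  p <- lp_parts(model)
  r1 <- solve_lp(p$obj, p$S, rep(0, nrow(p$S)), p$lb, p$ub)
  if (r1$status != "optimal") {
    stop("FVA requires a solvable model; FBA status: ", r1$status,
         call. = FALSE)
  }
  i_obj <- which(p$obj == 1)
  lb <- p$lb; lb[i_obj] <- max(lb[i_obj], objective_fraction * r1$objective)
  reactions <- reactions %||% p$rxn
  idx <- match(reactions, p$rxn)
  if (anyNA(idx)) stop("unknown reaction(s) in fva()", call. = FALSE)
  res <- purrr::map_dfr(idx, function(j) {
    cj <- as.numeric(seq_along(p$rxn) == j)
    up <- solve_lp(cj, p$S, rep(0, nrow(p$S)), lb, p$ub)
    dn <- solve_lp(cj, p$S, rep(0, nrow(p$S)), lb, p$ub, maximize = FALSE)
    tibble::tibble(reaction = p$rxn[j],
                   min_flux = dn$objective, max_flux = up$objective)
  })
  structure(res, objective_fraction = objective_fraction,
            class = c("flux_ranges", class(res)))
}

#' Apply measured extracellular fluxes as exchange bounds
#'
#' Sets each measured product's exchange-reaction bounds to the measurement's
#' `[lower_bound, upper_bound]` interval (secretion positive).
#'
#' @param model A `metabolic_model`.
#' @param measurements A tibble of measured fluxes with columns `id` (base
#'   metabolite id, e.g. `"h2"`), `lower_bound`, `upper_bound` — e.g. from
#'   [nlan_flux_measurements()] or [generate_flux_measurements()].
#' @return The constrained model.
#' @export
apply_measured_bounds <- function(model, measurements) {
  if (NROW(measurements) == 0) return(model)
  ex <- paste0("EX_", measurements$id, "_e")
  missing <- setdiff(ex, model$reactions$id)
  if (length(missing)) {
    stop("no exchange reaction for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set_bounds(model, ex, lower = measurements$lower_bound,
             upper = measurements$upper_bound)
}

# orthonormal null-space basis of S restricted to non-fixed variables
flux_null_space <- function(S, tol = 1e-10) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  rank <- sum(sv$d > tol * max(sv$d, 1))
  if (rank == ncol(S)) {
    matrix(0, ncol(S), 0)
  } else {
    sv$v[, (rank + 1):ncol(S), drop = FALSE]
  }
}

#' Uniform flux sampling at near-optimal growth
#'
#' Artificial-centering hit-and-run sampling of the steady-state flux
#' polytope with the objective constrained to at least `objective_fraction`
#' of its optimum. Warm-up points are vertices obtained by optimizing random
#' directions in the null space of the stoichiometric matrix (restricted to
#' non-fixed reactions, so every sample satisfies \eqn{S v = 0} and all fixed
#' bounds by construction); the chain starts from their average (an interior
#' point), alternates vertex-difference (centering) and isotropic
#' null-space directions, and records every `thinning`-th step.
#' Fully reproducible given `seed`.
#'
#' @inheritParams fva
#' @param n Number of samples (default 2000).
#' @param objective_fraction Minimum fraction of the FBA optimum (default
#'   0.9).
#' @param seed Integer seed.
#' @param warmup Warm-up steps discarded before recording (default 1000).
#' @param thinning Steps between recorded samples (default 100).
#' @param n_warmup_vertices Number of random-objective vertices used to
#'   build the interior starting point.
#' @return A `flux_sample` object: list with `samples` (n x reactions
#'   tibble), `seed`, `objective_fraction`, `thinning`.
#' @export
sample_fluxes <- function(model, n = 2000, objective_fraction = 0.9,
                          seed = 1L, warmup = 1000L, thinning = 100L,
                          n_warmup_vertices = 20L) {
  p <- lp_parts(model)
  r1 <- solve_lp(p$obj, p$S, rep(0, nrow(p$S)), p$lb, p$ub)
  if (r1$status != "optimal") {
    stop("sampling requires a solvable model; FBA status: ", r1$status,
         call. = FALSE)
  }
  i_obj <- which(p$obj == 1)
  lb <- p$lb; ub <- p$ub
  lb[i_obj] <- max(lb[i_obj], objective_fraction * r1$objective)
  if (lb[i_obj] > ub[i_obj] + 1e-9) {
    stop("empty polytope: objective lower bound ", lb[i_obj],
         " exceeds its upper bound ", ub[i_obj],
         " (binding constraints: objective fraction)", call. = FALSE)
  }
  free <- which(ub - lb > 1e-10)
  Nf <- flux_null_space(p$S[, free, drop = FALSE])
  k <- ncol(Nf)
  if (k == 0) stop("polytope has no degrees of freedom", call. = FALSE)
  set.seed(seed)
  n_rxn <- length(p$lb)
  # warm-up vertices: +/- objectives on the biomass and key branch/exchange
  # fluxes (so no single facet is active in every vertex), topped up with
  # random null-space directions
  key <- intersect(c(model$objective, "EX_glc_e", "EX_cellb_e", "EX_for_e",
                     "EX_ac_e", "EX_etoh_e", "EX_lac_e", "EX_succ_e",
                     "EX_h2_e", "EX_co2_e", "PFO", "PFLH", "PFL", "FDXH2",
                     "BIFH", "LDH", "ME"),
                   p$rxn[free])
  objs <- lapply(key, function(id) {
    e <- numeric(n_rxn); e[match(id, p$rxn)] <- 1; list(e, -e)
  })
  objs <- unlist(objs, recursive = FALSE)
  nv <- length(objs) + max(4L, as.integer(n_warmup_vertices))
  verts <- matrix(0, nv, n_rxn)
  for (j in seq_len(nv)) {
    cj <- if (j <= length(objs)) objs[[j]] else {
      z <- numeric(n_rxn); z[free] <- as.vector(Nf %*% stats::rnorm(k)); z
    }
    rj <- solve_lp(cj, p$S, rep(0, nrow(p$S)), lb, ub)
    if (rj$status != "optimal") {
      stop("warm-up LP failed (", rj$status, ")", call. = FALSE)
    }
    verts[j, ] <- rj$x
  }
  v <- colMeans(verts)
  center <- v
  out <- matrix(NA_real_, n, n_rxn)
  eps <- 1e-9
  total_steps <- warmup + n * thinning
  recorded <- 0L
  step <- 0L
  while (recorded < n && step < 20L * total_steps) {
    step <- step + 1L
    if (step %% 2L == 0L) {
      w <- verts[sample.int(nv, 1L), ]
      d <- w - center
    } else {
      d <- numeric(n_rxn)
      d[free] <- as.vector(Nf %*% stats::rnorm(k))
    }
    nd <- sqrt(sum(d * d))
    if (nd < 1e-12) next
    d <- d / nd
    pos <- d > 1e-11; neg <- d < -1e-11
    if (!any(pos) && !any(neg)) next
    tmax <- suppressWarnings(min((ub[pos] - v[pos]) / d[pos],
                                 (lb[neg] - v[neg]) / d[neg]))
    tmin <- suppressWarnings(max((lb[pos] - v[pos]) / d[pos],
                                 (ub[neg] - v[neg]) / d[neg]))
    if (!is.finite(tmax) || !is.finite(tmin) || tmax - tmin < 1e-12) next
    t <- stats::runif(1, tmin + eps * (tmax - tmin),
                      tmax - eps * (tmax - tmin))
    v <- pmin(pmax(v + t * d, lb), ub)
    center <- center + (v - center) / (step + nv)
    if (step > warmup && (step - warmup) %% thinning == 0L) {
      recorded <- recorded + 1L
      out[recorded, ] <- v
    }
  }
  if (recorded < n) {
    stop("sampler could not draw the requested number of samples",
         call. = FALSE)
  }
  samples <- tibble::as_tibble(as.data.frame(out))
  names(samples) <- p$rxn
  structure(list(samples = samples, seed = seed,
                 objective_fraction = objective_fraction,
                 thinning = thinning, warmup = warmup,
                 optimum = r1$objective),
            class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat("<flux_sample> ", nrow(x$samples), " samples x ", ncol(x$samples),
      " reactions at >=", 100 * x$objective_fraction,
      "% of optimum (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Target-tracking LP: fix some reactions, steer named fluxes toward targets
# by minimizing sum|v_r - t_r| + lambda * sum|v| (flux-splitting, one LP).
# Used by the synthetic-data generator to pick a representative near-optimal
# solution with a realistic fermentation-product profile.
solve_tracking <- function(model, targets, fix = list(), lambda = 1e-3) {
  for (r in names(fix)) {
    model <- set_bounds(model, r, lower = fix[[r]], upper = fix[[r]])
  }
  p <- lp_parts(model)
  n <- ncol(p$S)
  ti <- match(names(targets), p$rxn)
  if (anyNA(ti)) stop("unknown target reaction(s)", call. = FALSE)
  k <- length(ti)
  # vars: v+ (n), v- (n), d+ (k), d- (k)
  S2 <- cbind(p$S, -p$S, matrix(0, nrow(p$S), 2 * k))
  Tm <- matrix(0, k, n)
  Tm[cbind(seq_len(k), ti)] <- 1
  rows <- cbind(Tm, -Tm, -diag(k), diag(k))
  A <- rbind(S2, rows)
  rhs <- c(rep(0, nrow(p$S)), as.numeric(targets))
  lb <- c(pmax(p$lb, 0), pmax(-p$ub, 0), rep(0, 2 * k))
  ub <- c(pmax(p$ub, 0), pmax(-p$lb, 0), rep(2 * BIG, 2 * k))
  cost <- c(rep(lambda, 2 * n), rep(1, 2 * k))
  r <- solve_lp(cost, A, rhs, lb, ub, maximize = FALSE)
  if (r$status != "optimal") {
    stop("tracking LP not optimal: ", r$status, call. = FALSE)
  }
  v <- r$x[1:n] - r$x[(n + 1):(2 * n)]
  new_flux_solution("optimal", sum(p$obj * v), v, p$rxn, kind = "tracking")
}
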
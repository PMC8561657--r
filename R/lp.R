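#' Solve a bounded-variable linear program
#'
#' A dense two-phase primal simplex with general variable bounds, used as the
#' engine behind [fba()], [pfba()] and [fva()]. Solves
#' \deqn{\max\; c^\top x \quad \mathrm{s.t.}\; A x = b,\; l \le x \le u.}
#' Nonbasic variables rest at a finite bound; the basis inverse is maintained
#' by product-form updates and refactorized periodically (recomputing the
#' basic values, so numerical drift cannot accumulate). Termination is only
#' accepted after a fresh factorization, the returned point is verified
#' against the constraints, and on any numerical failure the solve restarts
#' deterministically with Bland's rule.
#'
#' @param obj Objective coefficients (length n).
#' @param A Dense constraint matrix (m x n).
#' @param rhs Right-hand side (length m).
#' @param lb,ub Variable bounds (length n, finite).
#' @param maximize Maximize (default) or minimize.
#' @param tol Reduced-cost / pivot tolerance.
#' @param max_iter Iteration cap.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x`, `objective` and `iterations`.
#' @export
solve_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE, tol = 1e-9,
                     max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, iterations = 0L))
  }
  if (!all(is.finite(lb)) || !all(is.finite(ub))) {
    stop("solve_lp requires finite bounds", call. = FALSE)
  }
  res <- simplex_core(obj, A, rhs, lb, ub, maximize, tol, max_iter,
                      bland = FALSE)
  ok <- res$status %in% c("infeasible", "unbounded") ||
    (res$status == "optimal" &&
       max(abs(A %*% res$x - rhs)) < 1e-6 &&
       all(res$x >= lb - 1e-6) && all(res$x <= ub + 1e-6))
  if (!ok || res$status == "numerical" || res$status == "iteration_limit") {
    res <- simplex_core(obj, A, rhs, lb, ub, maximize, tol, max_iter,
                        bland = TRUE)
    if (res$status == "optimal" &&
        (max(abs(A %*% res$x - rhs)) > 1e-6 ||
         any(res$x < lb - 1e-6) || any(res$x > ub + 1e-6))) {
      stop("LP solver failed to produce a feasible optimum", call. = FALSE)
    }
  }
  res
}

simplex_core <- function(obj, A, rhs, lb, ub, maximize, tol, max_iter,
                         bland = FALSE) {
  m <- nrow(A); n <- ncol(A)
  # row equilibration
  rmax <- apply(abs(A), 1, max)
  rmax[rmax < 1e-12] <- 1
  A <- A / rmax
  rhs <- rhs / rmax
  sgn <- if (maximize) 1 else -1
  c0 <- sgn * obj
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_ub <- abs(lb) > abs(ub)
  r <- rhs - as.vector(A %*% x)
  art_sign <- ifelse(r >= 0, 1, -1)
  N <- n + m
  Af <- cbind(A, diag(art_sign, m, m))
  LB <- c(lb, rep(0, m)); UB <- c(ub, rep(Inf, m))
  basis <- (n + 1L):N
  xf <- c(x, abs(r))
  nb_at_ub <- c(at_ub, rep(FALSE, m))
  Binv <- diag(1 / art_sign, m, m)
  phase <- 1L
  cost <- c(rep(0, n), rep(-1, m))
  iter <- 0L; refact <- 0L
  is_basic <- rep(FALSE, N); is_basic[basis] <- TRUE
  failed <- FALSE
  refactor <- function() {
    B <- Af[, basis, drop = FALSE]
    Bi <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Bi)) { failed <<- TRUE; return(invisible(NULL)) }
    Binv <<- Bi
    # recompute basic values from the nonbasic assignment (kills drift)
    nb <- which(!is_basic)
    xn <- xf[nb]
    xf[basis] <<- as.vector(Bi %*% (rhs - Af[, nb, drop = FALSE] %*% xn))
    refact <<- 0L
  }
  status <- "optimal"
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) { status <- "iteration_limit"; break }
    if (refact >= 40L) refactor()
    if (failed) { status <- "numerical"; break }
    y <- as.vector(crossprod(Binv, cost[basis]))
    d_all <- cost - as.vector(y %*% Af)
    eligible <- !is_basic
    if (phase == 2L) eligible[(n + 1L):N] <- FALSE
    improving <- eligible &
      ((!nb_at_ub & d_all > tol) | (nb_at_ub & d_all < -tol))
    cand <- which(improving)
    if (!length(cand)) {
      if (refact > 0L) {
        refactor()
        if (failed) { status <- "numerical"; break }
        next
      }
      if (phase == 1L) {
        if (sum(xf[(n + 1L):N]) > 1e-7) { status <- "infeasible"; break }
        UB[(n + 1L):N] <- 0
        xf[(n + 1L):N][!is_basic[(n + 1L):N]] <- 0
        phase <- 2L
        cost <- c(c0, rep(0, m))
        next
      }
      status <- "optimal"; break
    }
    e <- if (bland) cand[1L] else cand[which.max(abs(d_all[cand]))]
    sig <- if (nb_at_ub[e]) -1 else 1
    w <- as.vector(Binv %*% Af[, e])
    tmax <- UB[e] - LB[e]
    leave <- 0L; leave_to_ub <- FALSE
    xB <- xf[basis]
    dB <- -sig * w
    bl <- LB[basis]; bu <- UB[basis]
    dn <- dB < -tol; up <- dB > tol
    tks <- rep(Inf, m)
    tks[dn] <- (xB[dn] - bl[dn]) / (-dB[dn])
    tks[up] <- (bu[up] - xB[up]) / dB[up]
    tks <- pmax(tks, 0)
    # Harris-style two-pass ratio test: allow up to `feas_tol` of bound
    # slack so that a numerically large pivot can be chosen among the
    # near-blocking rows; keeps the basis well conditioned under degeneracy
    feas_tol <- 1e-7
    tks_rel <- rep(Inf, m)
    tks_rel[dn] <- (xB[dn] - bl[dn] + feas_tol) / (-dB[dn])
    tks_rel[up] <- (bu[up] - xB[up] + feas_tol) / dB[up]
    t_rel <- suppressWarnings(min(tks_rel))
    if (is.finite(t_rel) && t_rel < tmax - 1e-12) {
      ties <- which(tks <= t_rel)
      k <- ties[which.max(abs(w[ties]))]
      tmax <- tks[k]
      leave <- k; leave_to_ub <- up[k]
    }
    if (!is.finite(tmax)) {
      status <- if (phase == 1L) "infeasible" else "unbounded"
      break
    }
    xf[basis] <- xB + dB * tmax
    xf[e] <- xf[e] + sig * tmax
    if (leave == 0L) {
      nb_at_ub[e] <- !nb_at_ub[e]
    } else {
      l <- basis[leave]
      xf[l] <- if (leave_to_ub) bu[leave] else bl[leave]
      nb_at_ub[l] <- leave_to_ub
      is_basic[l] <- FALSE; is_basic[e] <- TRUE
      basis[leave] <- e
      we <- w[leave]
      if (abs(we) < 1e-9) {
        refactor()
        if (failed) { status <- "numerical"; break }
      } else {
        Brow <- Binv[leave, ] / we
        Binv <- Binv - outer(w, Brow)
        Binv[leave, ] <- Brow
        refact <- refact + 1L
      }
    }
  }
  xs <- xf[1:n]
  list(status = status, x = xs,
       objective = if (status == "optimal") sum(obj * xs) else NA_real_,
       iterations = iter)
}
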
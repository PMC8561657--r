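# Brute-force positional-isotopomer simulator: the independent oracle for
# the EMU machinery on small networks (<= ~6 carbons per metabolite).

# dist over 2^n isotopomer states (bit j of state index-1 = carbon j labeled)
iso_input_dist <- function(n, patterns) {
  d <- numeric(2^n)
  for (p in patterns) {
    state <- sum(2^(p$positions - 1)) + 1
    d[state] <- d[state] + p$fraction
  }
  d
}

iso_simulate <- function(maps, fluxes, input_dists, tol = 1e-14,
                         max_iter = 20000) {
  carbons <- list()
  for (mp in maps) {
    for (rc in mp$from) carbons[[rc$met]] <- nchar(rc$atoms)
    for (pc in mp$to) carbons[[pc$met]] <- nchar(pc$atoms)
  }
  mets <- setdiff(names(carbons), names(input_dists))
  dist <- input_dists
  for (m in mets) {
    d <- numeric(2^carbons[[m]]); d[1] <- 1
    dist[[m]] <- d
  }
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (m in mets) {
      acc <- numeric(2^carbons[[m]])
      total <- 0
      for (mp in maps) {
        f0 <- fluxes[[mp$reaction]]
        if (is.null(f0) || f0 <= 0) next
        for (inst in mp$to) {
          if (inst$met != m) next
          f <- f0 * (inst$weight %||% 1)
          total <- total + f
          # enumerate joint reactant states
          r_mets <- vapply(mp$from, `[[`, character(1), "met")
          r_atoms <- lapply(mp$from, function(r) strsplit(r$atoms, "")[[1]])
          states <- lapply(mp$from,
                           function(r) seq_len(2^nchar(r$atoms)) - 1L)
          grid <- expand.grid(states)
          pchars <- strsplit(inst$atoms, "")[[1]]
          for (gi in seq_len(nrow(grid))) {
            pr <- 1
            for (ri in seq_along(r_mets)) {
              pr <- pr * dist[[r_mets[ri]]][grid[gi, ri] + 1L]
            }
            if (pr == 0) next
            pstate <- 0L
            for (pi in seq_along(pchars)) {
              for (ri in seq_along(r_mets)) {
                j <- match(pchars[pi], r_atoms[[ri]])
                if (!is.na(j)) {
                  bit <- bitwAnd(as.integer(grid[gi, ri]), 2^(j - 1)) > 0
                  if (bit) pstate <- pstate + 2^(pi - 1)
                  break
                }
              }
            }
            acc[pstate + 1L] <- acc[pstate + 1L] + f * pr
          }
        }
      }
      if (total > 0) {
        newd <- acc / total
        delta <- max(delta, max(abs(newd - dist[[m]])))
        dist[[m]] <- newd
      }
    }
    if (delta < tol) break
  }
  dist
}

# MID of a subset of carbon positions from an isotopomer distribution
iso_mid <- function(dist, positions) {
  n <- log2(length(dist))
  states <- 0:(length(dist) - 1)
  shifts <- vapply(states, function(s) {
    sum(bitwAnd(s, 2^(positions - 1)) > 0)
  }, numeric(1))
  mid <- numeric(length(positions) + 1)
  for (i in seq_along(states)) {
    mid[shifts[i] + 1] <- mid[shifts[i] + 1] + dist[i]
  }
  mid
}
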
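# Brute-force enumeration oracle for the SCR marginal likelihood: explicit
# sums over state-space cells and sex classes using dpois().  Deliberately
# independent of the package's likelihood implementation (plain loops, no
# shared code paths).

# counts: n x J matrix; sex: "F"/"M" per row; mu: per-cell intensity (per
# km^2); lam0: J x 2 matrix of baseline rates, columns (F, M); sigma: named
# c(F =, M =); dist: J x G matrix of detector-cell distances.
oracle_session_loglik <- function(counts, sex, mu, cell_area, lam0, sigma,
                                  psi_male, dist) {
  G <- ncol(dist)
  n <- nrow(counts)
  log_psi <- c(F = log(1 - psi_male), M = log(psi_male))
  lam <- list(
    F = lam0[, 1] * exp(-dist^2 / (2 * sigma[["F"]]^2)),
    M = lam0[, 2] * exp(-dist^2 / (2 * sigma[["M"]]^2))
  )
  Lambda_bar <- 0
  for (s in c("F", "M")) {
    pdot <- 1 - exp(-colSums(lam[[s]]))
    Lambda_bar <- Lambda_bar + exp(log_psi[[s]]) * sum(mu * cell_area * pdot)
  }
  ll <- 0
  for (i in seq_len(n)) {
    s <- sex[i]
    cell_terms <- vapply(seq_len(G), function(g) {
      log(mu[g] * cell_area) + sum(dpois(counts[i, ], lam[[s]][, g], log = TRUE))
    }, numeric(1))
    ll <- ll + log_psi[[s]] + log(sum(exp(cell_terms)))
  }
  ll - Lambda_bar
}

# Posterior AC distribution of detected individual i by direct Bayes' rule.
oracle_posterior <- function(counts, i, mu, cell_area, lam0_i, sigma_i, dist) {
  w <- vapply(seq_len(ncol(dist)), function(g) {
    lam_g <- lam0_i * exp(-dist[, g]^2 / (2 * sigma_i^2))
    mu[g] * cell_area * exp(sum(dpois(counts[i, ], lam_g, log = TRUE)))
  }, numeric(1))
  w / sum(w)
}

# Full realized surface by enumeration: summed posteriors plus the expected
# undetected contribution.
oracle_realized_n <- function(counts, sex, mu, cell_area, lam0, sigma,
                              psi_male, dist) {
  G <- ncol(dist)
  out <- numeric(G)
  for (i in seq_len(nrow(counts))) {
    s <- sex[i]
    out <- out + oracle_posterior(counts, i, mu, cell_area,
                                  lam0[, if (s == "F") 1 else 2],
                                  sigma[[s]], dist)
  }
  psi <- c(F = 1 - psi_male, M = psi_male)
  for (s in c("F", "M")) {
    lam_s <- lam0[, if (s == "F") 1 else 2] *
      exp(-dist^2 / (2 * sigma[[s]]^2))
    out <- out + psi[[s]] * mu * cell_area * exp(-colSums(lam_s))
  }
  out
}
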
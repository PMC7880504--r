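# Shared fixtures: random states, a finite-difference Jacobian harness for
# the NER proposal maps, and a generic numeric Jacobian for operator maps.

random_phylo_state <- function(N = 6, mode = "real", seed = NULL, P = 1L) {
  if (!is.null(seed)) set.seed(seed)
  init_state_from_prior(N, mode, P)
}

# Random generic node-height/rate configuration for a narrow-exchange
# neighbourhood: tB, tC < tD < tE, tA < tD, t'_D in (max(tB,tC), tE).
# Heights are kept well separated so the rational solutions are evaluated
# away from their poles (the proposal itself rejects degenerate geometry).
random_ner_vals <- function() {
  tD <- runif(1, 1, 2)
  tE <- tD + runif(1, 0.5, 2)
  tA <- runif(1, 0, tD - 0.3)
  tB <- runif(1, 0, tD - 0.3)
  tC <- runif(1, 0, tD - 0.3)
  repeat {
    tDp <- runif(1, max(tB, tC) + 0.2, tE - 0.2)
    if (abs(tDp - tD) >= 0.05) break
  }
  c(tA = tA, tB = tB, tC = tC, tD = tD, tE = tE, tDp = tDp,
    rA = runif(1, 0.2, 3), rB = runif(1, 0.2, 3),
    rC = runif(1, 0.2, 3), rD = runif(1, 0.2, 3))
}

# Central finite-difference determinant of the 5x5 map
# (rA, rB, rC, rD, tD) -> (r'A, r'B, r'C, r'D, t'D); the walk offset
# t'D - tD is held fixed, as in the proposal.
fd_ner_jacobian <- function(sol, vals, h = 1e-4) {
  off <- vals[["tDp"]] - vals[["tD"]]
  f <- function(x) {
    v <- vals
    v[c("rA", "rB", "rC", "rD", "tD")] <- x
    v["tDp"] <- x[5] + off
    ev <- ner_evaluate(sol, v)
    c(ev$rates, v[["tDp"]])
  }
  x0 <- vals[c("rA", "rB", "rC", "rD", "tD")]
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    e <- numeric(5); e[j] <- h
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  det(J)
}

# Numeric determinant of a generic map R^n -> R^n.
fd_jacobian <- function(f, x0, h = 1e-6) {
  n <- length(x0)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  det(J)
}

# Genetic distance between a node and its parent-side path endpoints under a
# state (real mode): r_i * tau_i per branch.
branch_distances <- function(state) {
  tr <- state$tree
  nonroot <- setdiff(seq_len(tr$nnode), tr$root)
  r <- branch_rate_values(state$rates, state$sigma, state$npieces)
  (tr$height[tr$parent[nonroot]] - tr$height[nonroot]) * r[nonroot]
}

# Auto-tuned single-parameter random-walk Metropolis on a log-normal target;
# returns the per-proposal acceptance indicator.
tuned_rw_chain <- function(kern, n, meanlog = -0.18, sdlog = 0.6) {
  x <- exp(meanlog)
  lp <- dlnorm(x, meanlog, sdlog, log = TRUE)
  acc <- logical(n)
  for (i in seq_len(n)) {
    xp <- x + kern$s * relclock:::kernel_draw(kern)
    lpp <- if (xp > 0) dlnorm(xp, meanlog, sdlog, log = TRUE) else -Inf
    if (log(runif(1)) < lpp - lp) {
      x <- xp; lp <- lpp; acc[i] <- TRUE
    }
    kern <- tune_scale(kern, as.integer(acc[i]), 1L)
  }
  acc
}

# Kolmogorov-Smirnov test against an analytic CDF on a thinned, approximately
# independent subsample of an MCMC series.  Thinning to a third of the
# effective sample size leaves negligible residual autocorrelation, keeping
# the KS null distribution valid.
ks_mcmc <- function(x, cdf, max_keep = 1500) {
  ess <- effective_sample_size(x)
  by <- max(1L, ceiling(length(x) / min(ess / 3, max_keep)))
  thin <- x[seq(1L, length(x), by = by)]
  suppressWarnings(ks.test(thin, cdf))
}

# 3-leaf tree whose single internal non-root node X sits at height 10 with
# children at heights 2 and 4 and parent (the root) at 20; used by the
# constant-distance worked-case and Jacobian checks.
cd_fixture <- function() {
  tr <- timetree(parent = c(4L, 4L, 5L, 5L, NA),
                 height = c(2, 4, 0, 10, 20),
                 tip.label = c("a", "b", "c"))
  v <- c(1, 1, 1, 1, NA)
  phylo_state(tr, branch_rates(v, "real"), 0.5,
              list(list(kappa = 1, freqs = rep(0.25, 4), muC = 1)), 1)
}
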
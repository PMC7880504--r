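# Fixed-seed checks of each proposal operator: worked examples, domain
# guards, Hastings ratios against independent density evaluations, and
# numeric Jacobians for the deterministic rate maps.

test_that("random walk respects parameter domains", {
  set.seed(51)
  st <- random_phylo_state(5, "quant")
  op <- op_random_walk("sigma", kern = kernel("bactrian", s = 0.2))
  for (i in 1:100) {
    pr <- op$propose(st, op)
    if (!pr$reject) {
      expect_gt(pr$state$sigma, 0)
      expect_identical(pr$log_hr, 0)
    }
  }
  # quantile walk with a huge step is rejected rather than reflected
  st$rates$values[1] <- 0.99
  op2 <- op_interval(kern = kernel("bactrian", s = 0))
  pr <- op2$propose(st, op2)     # zero step: exact identity
  expect_equal(pr$state$rates$values[1], 0.99)
  expect_equal(pr$log_hr, 0)
})

test_that("scale operator carries the log-scale change of variables", {
  set.seed(52)
  st <- random_phylo_state(5, "real")
  op <- op_scale("rates", kern = kernel("bactrian", s = 0.7))
  for (i in 1:20) {
    pr <- op$propose(st, op)
    changed <- which(pr$state$rates$values != st$rates$values)
    expect_length(changed, 1L)
    expect_equal(pr$log_hr,
                 log(pr$state$rates$values[changed] /
                     st$rates$values[changed]), tolerance = 1e-12)
  }
  # detailed balance: q(x|x') / q(x'|x) from the kernel density matches the
  # analytic Hastings ratio
  dens <- function(from, to, s, m = 0.95) {
    z <- log(to / from) / s
    mix <- 0.5 * dnorm(z, -m, sqrt(1 - m^2)) + 0.5 * dnorm(z, m, sqrt(1 - m^2))
    mix / (s * to)
  }
  s <- 0.7
  for (i in 1:5) {
    x <- runif(1, 0.2, 3); xp <- x * exp(s * 0.4)
    analytic <- log(xp / x)
    expect_equal(log(dens(xp, x, s)) - log(dens(x, xp, s)), analytic,
                 tolerance = 1e-10)
  }
})

test_that("interval operator's Hastings ratio matches the logit Jacobian", {
  set.seed(53)
  st <- random_phylo_state(5, "quant")
  op <- op_interval(kern = kernel("bactrian", s = 0.8))
  logistic <- function(z) 1 / (1 + exp(-z))
  for (i in 1:20) {
    pr <- op$propose(st, op)
    if (pr$reject) next
    changed <- which(pr$state$rates$values != st$rates$values)
    q <- st$rates$values[changed]; qp <- pr$state$rates$values[changed]
    h <- 1e-7
    num <- (logistic(log(qp / (1 - qp)) + h) -
            logistic(log(qp / (1 - qp)) - h)) / (2 * h)
    den <- (logistic(log(q / (1 - q)) + h) -
            logistic(log(q / (1 - q)) - h)) / (2 * h)
    expect_equal(pr$log_hr, log(num / den), tolerance = 1e-6)
  }
})

test_that("swap is an involution preserving the value multiset", {
  set.seed(54)
  st <- random_phylo_state(6, "real")
  op <- op_swap()
  pr <- op$propose(st, op)
  expect_identical(pr$log_hr, 0)
  expect_equal(sort(pr$state$rates$values), sort(st$rates$values))
  ij <- which(pr$state$rates$values != st$rates$values)
  st2 <- pr$state
  st2$rates$values[ij] <- st2$rates$values[rev(ij)]
  expect_equal(st2$rates$values, st$rates$values)
})

test_that("uniform resampling draws flat and leaves other elements alone", {
  set.seed(55)
  st <- random_phylo_state(5, "cat")
  st$rates$ncat <- 4L
  # all current values 0: an observable change is uniform over {1, 2, 3}
  st$rates$values[!is.na(st$rates$values)] <- 0
  op <- op_uniform_resample()
  draws <- integer(0)
  for (i in 1:2000) {
    pr <- op$propose(st, op)
    changed <- which(pr$state$rates$values != st$rates$values)
    if (length(changed)) {
      expect_length(changed, 1L)
      draws <- c(draws, pr$state$rates$values[changed])
    }
  }
  expect_equal(length(draws) / 2000, 3 / 4, tolerance = 0.05)
  tab <- table(factor(draws, levels = 1:3))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  st_real <- random_phylo_state(5, "real")
  expect_error(op$propose(st_real, op), "cat/quant")
})

test_that("sample-from-prior redraws a Binomial number of elements", {
  set.seed(56)
  st <- random_phylo_state(6, "real")
  n <- 2 * st$tree$N - 2
  # s = n resamples everything
  op_all <- op_sample_from_prior("rates", kern = kernel(s = n))
  pr <- op_all$propose(st, op_all)
  expect_equal(sum(pr$state$rates$values != st$rates$values, na.rm = TRUE), n)
  # E[psi] = s
  op2 <- op_sample_from_prior("rates", kern = kernel(s = 3))
  psi <- replicate(2000, {
    p <- op2$propose(st, op2)
    sum(p$state$rates$values != st$rates$values, na.rm = TRUE)
  })
  se <- sqrt(3 * (1 - 3 / n) / 2000)
  expect_lt(abs(mean(psi) - 3), 3 * se)
  # psi = 0 leaves the state untouched with unit Hastings ratio
  op0 <- op_sample_from_prior("rates", kern = kernel(s = 1e-9))
  pr0 <- op0$propose(st, op0)
  expect_equal(pr0$state$rates$values, st$rates$values)
  expect_identical(pr0$log_hr, 0)
})

test_that("constant distance rescales rates exactly as in the worked case", {
  st <- cd_fixture()
  # direct evaluation of the height move t_X: 10 -> 12
  tauold <- c(10 - 2, 10 - 4, 20 - 10)
  taunew <- c(12 - 2, 12 - 4, 20 - 12)
  expect_equal(1 * tauold / taunew, c(0.8, 0.75, 1.25))
  expect_equal(prod(tauold) / prod(taunew), 0.75)
  # proposals reproduce the relation for whatever height was drawn
  set.seed(57)
  op <- op_constant_distance("all", kernel("bactrian", s = 2))
  for (i in 1:200) {
    pr <- op$propose(st, op)
    if (pr$reject) next
    tXp <- pr$state$tree$height[4]
    expect_true(tXp > 4 && tXp < 20)
    expect_equal(pr$state$rates$values[1:2],
                 c((10 - 2) / (tXp - 2), (10 - 4) / (tXp - 4)),
                 tolerance = 1e-12)
    expect_equal(pr$state$rates$values[4], (20 - 10) / (20 - tXp),
                 tolerance = 1e-12)
    expect_equal(pr$log_jac,
                 sum(log(tauold)) - sum(log(c(tXp - 2, tXp - 4, 20 - tXp))),
                 tolerance = 1e-12)
    # incident genetic distances preserved
    expect_equal(branch_distances(pr$state), branch_distances(st),
                 tolerance = 1e-12)
  }
})

test_that("constant-distance family preserves the likelihood", {
  set.seed(58)
  ds <- simulate_dataset(7, 150, 0.6)
  for (mode in c("real", "quant")) {
    v <- ds$rates
    if (mode == "quant") {
      ok <- !is.na(v); v[ok] <- quant_from_rate(v[ok], 0.6)
    }
    st <- phylo_state(ds$tree, branch_rates(v, mode), 0.6,
                      list(list(kappa = 2, freqs = rep(0.25, 4), muC = 1)), 1)
    ll0 <- tree_log_likelihood(st, ds$aln)
    for (op in list(op_constant_distance("all", kernel(s = 0.2)),
                    op_simple_distance(kernel(s = 0.2)),
                    op_small_pulley(kernel(s = 0.1)))) {
      for (i in 1:50) {
        pr <- op$propose(st, op)
        if (pr$reject) next
        expect_equal(tree_log_likelihood(pr$state, ds$aln), ll0,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("constant-distance Jacobians match finite differences", {
  set.seed(59)
  st <- cd_fixture()
  op <- op_constant_distance("all", kernel("bactrian", s = 1))
  for (i in 1:100) {
    st$rates$values[c(1, 2, 4)] <- runif(3, 0.3, 2)
    pr <- op$propose(st, op)
    if (pr$reject) next
    delta <- pr$state$tree$height[4] - st$tree$height[4]
    # independent map: (r1, r2, rX, tX) -> (r'1, r'2, r'X, t'X)
    f <- function(x) {
      tX <- x[4]; tXp <- tX + delta
      c(x[1] * (tX - 2) / (tXp - 2), x[2] * (tX - 4) / (tXp - 4),
        x[3] * (20 - tX) / (20 - tXp), tXp)
    }
    fd <- fd_jacobian(f, c(st$rates$values[c(1, 2, 4)], 10), h = 1e-5)
    expect_equal(pr$log_jac, log(fd), tolerance = 1e-6)
  }
})

test_that("simple distance reproduces its worked example", {
  # root at 10 with children at 2 and 4, unit rates, proposed root 12
  tr <- timetree(parent = c(3L, 3L, NA), height = c(2, 4, 10),
                 tip.label = c("a", "b"))
  st <- phylo_state(tr, branch_rates(c(1, 1, NA), "real"), 0.5,
                    list(list(kappa = 1, freqs = rep(0.25, 4), muC = 1)), 1)
  tauold <- c(8, 6); taunew <- c(10, 8)
  expect_equal(tauold / taunew, c(0.8, 0.75))
  expect_equal(prod(tauold) / prod(taunew), 0.6)
  set.seed(60)
  op <- op_simple_distance(kernel("bactrian", s = 2))
  for (i in 1:100) {
    pr <- op$propose(st, op)
    if (pr$reject) next
    tRp <- pr$state$tree$height[3]
    expect_equal(pr$state$rates$values[1:2],
                 c(8 / (tRp - 2), 6 / (tRp - 4)), tolerance = 1e-12)
    expect_equal(pr$log_jac, log((8 * 6) / ((tRp - 2) * (tRp - 4))),
                 tolerance = 1e-12)
    expect_equal(branch_distances(pr$state), branch_distances(st),
                 tolerance = 1e-12)
  }
})

test_that("small pulley shifts distance mass at constant total", {
  tr <- timetree(parent = c(3L, 3L, NA), height = c(0, 0, 10),
                 tip.label = c("a", "b"))
  st <- phylo_state(tr, branch_rates(c(1, 1, NA), "real"), 0.5,
                    list(list(kappa = 1, freqs = rep(0.25, 4), muC = 1)), 1)
  # worked case: d = 20, d'_1 = 12 -> rates (1.2, 0.8)
  expect_equal(c(12, 20 - 12) / 10, c(1.2, 0.8))
  set.seed(61)
  op <- op_small_pulley(kernel("bactrian", s = 3))
  for (i in 1:100) {
    pr <- op$propose(st, op)
    if (pr$reject) next
    expect_equal(sum(branch_distances(pr$state)), 20, tolerance = 1e-12)
    expect_equal(pr$state$tree$height, st$tree$height)
    # translation in rate space: unit Jacobian
    expect_identical(pr$log_jac, 0)
    delta <- (pr$state$rates$values[1] - 1) * 10
    fd <- fd_jacobian(function(x) c(x[1] + delta / 10, x[2] - delta / 10),
                      c(1, 1))
    expect_equal(fd, 1, tolerance = 1e-8)
  }
})

test_that("cis-scale preserves rate quantiles in real mode", {
  set.seed(62)
  st <- random_phylo_state(6, "real")
  op <- op_cis_scale(kernel("bactrian", s = 0.6))
  nonroot <- !is.na(st$rates$values)
  for (i in 1:50) {
    pr <- op$propose(st, op)
    sig <- st$sigma; sigp <- pr$state$sigma
    q_old <- plnorm(st$rates$values[nonroot], -0.5 * sig^2, sig)
    q_new <- plnorm(pr$state$rates$values[nonroot], -0.5 * sigp^2, sigp)
    expect_equal(q_new, q_old, tolerance = 1e-9)
    # worked case algebra: r = 1, sigma 0.6 -> 0.3 gives r' = exp(0.045)
    expect_equal(exp(-0.5 * 0.3^2 + (0.3 / 0.6) * (0 + 0.5 * 0.6^2)),
                 exp(0.045), tolerance = 1e-12)
    # full-map determinant equals the combined Hastings and Jacobian terms
    f <- sigp / sig
    n <- sum(nonroot)
    logdet <- log(f) +
      sum(log(f) + log(pr$state$rates$values[nonroot]) -
          log(st$rates$values[nonroot]))
    expect_equal(pr$log_hr + pr$log_jac, logdet, tolerance = 1e-9)
  }
})

test_that("cis-scale preserves rates in quant mode", {
  set.seed(63)
  st <- random_phylo_state(6, "quant")
  op <- op_cis_scale(kernel("bactrian", s = 0.4))
  nonroot <- !is.na(st$rates$values)
  for (i in 1:50) {
    pr <- op$propose(st, op)
    if (pr$reject) next
    r_old <- quant_rate(st$rates$values[nonroot], st$sigma)
    r_new <- quant_rate(pr$state$rates$values[nonroot], pr$state$sigma)
    expect_equal(r_new, r_old, tolerance = 1e-9)
  }
})

test_that("leaf AVMVN proposals use the learned covariance", {
  set.seed(64)
  # unavailable before enough samples accumulate
  env <- new.env(parent = emptyenv())
  op <- op_leaf_avmvn(env, min_samples = 50)
  st <- random_phylo_state(2, "real")
  expect_true(op$propose(st, op)$reject)
  # strongly correlated 2-leaf target
  n <- 4000
  Sig <- matrix(c(1, 0.9, 0.9, 1), 2)
  ch <- chol(Sig)
  for (i in seq_len(n)) relclock:::avmvn_record(env, drop(t(ch) %*% rnorm(2)))
  expect_false(op$propose(st, op)$reject)
  steps <- t(replicate(3000, {
    pr <- op$propose(st, op)
    log(pr$state$rates$values[1:2]) - log(st$rates$values[1:2])
  }))
  expect_equal(nrow(steps), 3000)
  expect_equal(ncol(steps), st$tree$N)   # proposal dimension is the leaf count
  expect_lt(abs(cor(steps)[1, 2] - 0.9 * (1 - op$beta)), 0.1)
  # beta = 1: proposal covariance proportional to the identity
  op_id <- op_leaf_avmvn(env, min_samples = 50, beta = 1)
  steps_id <- t(replicate(3000, {
    pr <- op_id$propose(st, op_id)
    log(pr$state$rates$values[1:2]) - log(st$rates$values[1:2])
  }))
  expect_lt(abs(cor(steps_id)[1, 2]), 0.1)
  # log transform Jacobian
  pr <- op$propose(st, op)
  expect_equal(pr$log_jac,
               sum(log(pr$state$rates$values[1:2]) -
                   log(st$rates$values[1:2])), tolerance = 1e-12)
})

test_that("single-operator prior chains recover their target marginals", {
  set.seed(65)
  # sigma under scale moves, with a rate-refresh companion so the sigma
  # marginal is the Gamma prior rather than the conditional given fixed rates
  st <- random_phylo_state(5, "real")
  op_s <- op_scale("sigma", kern = kernel("bactrian", s = 1))
  op_r <- op_sample_from_prior("rates", kern = kernel(s = 8))
  sig <- numeric(40000)
  lp <- log_posterior(st)
  for (i in seq_along(sig)) {
    op <- if (i %% 2) op_s else op_r
    pr <- op$propose(st, op)
    lpp <- log_posterior(pr$state)
    if (log(runif(1)) < lpp - lp + pr$log_hr + pr$log_jac) {
      st <- pr$state; lp <- lpp
    }
    sig[i] <- st$sigma
  }
  ks <- ks_mcmc(sig[-(1:5000)], function(q) pgamma(q, 0.5396, scale = 0.3819))
  expect_gt(ks$p.value, 0.01)
  # a quantile element under interval moves only
  st <- random_phylo_state(5, "quant")
  op2 <- op_interval(kern = kernel("bactrian", s = 2))
  qv <- numeric(20000)
  lp <- log_posterior(st)
  for (i in seq_along(qv)) {
    pr <- op2$propose(st, op2)
    if (!pr$reject) {
      lpp <- log_posterior(pr$state)
      if (log(runif(1)) < lpp - lp + pr$log_hr + pr$log_jac) {
        st <- pr$state; lp <- lpp
      }
    }
    qv[i] <- st$rates$values[1]
  }
  expect_gt(ks_mcmc(qv[-(1:5000)], punif)$p.value, 0.01)
})
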
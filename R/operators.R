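# MCMC proposal operators.  Every operator is a list with a `propose`
# function returning a proposal: the proposed state, the log Hastings ratio
# and the log Jacobian determinant (Green ratio) separately, or a reject
# sentinel for out-of-domain moves.

propose_reject <- function() {
  list(reject = TRUE, state = NULL, log_hr = -Inf, log_jac = 0)
}

propose_ok <- function(state, log_hr = 0, log_jac = 0) {
  list(reject = FALSE, state = state, log_hr = log_hr, log_jac = log_jac)
}

new_operator <- function(name, propose, kernel = NULL, modes = c("real", "cat", "quant"),
                         poi = "rates", weight = 1, available = NULL,
                         lik_invariant = NULL) {
  # lik_invariant: optional function(state) -> TRUE when a proposal from this
  # operator cannot change the tree likelihood (exact by construction), so
  # the chain driver can skip recomputing it
  structure(list(name = name, propose = propose, kernel = kernel,
                 modes = modes, poi = poi, weight = weight,
                 available = available, lik_invariant = lik_invariant),
            class = "mcmc_operator")
}

# node index helpers ----------------------------------------------------------

nodes_nonroot <- function(tr) setdiff(seq_len(tr$nnode), tr$root)

nodes_subset <- function(tr, subset = c("all", "leaf", "internal")) {
  subset <- match.arg(subset)
  switch(subset,
         all = nodes_nonroot(tr),
         leaf = seq_len(tr$N),
         internal = setdiff((tr$N + 1L):tr$nnode, tr$root))
}

state_knots <- function(state, sigma = state$sigma) {
  quant_knots(sigma, state$npieces)
}

# single-element operators on the rate vector or sigma ------------------------

#' Random-walk operator
#'
#' Moves one element of the target vector by `s * Sigma`; out-of-domain
#' proposals (negative rate or sigma, quantile outside (0,1), category out of
#' range) are rejected.  For `cat` the walk is an integer step of up to
#' `max(1, round(s))` in either direction.
#'
#' @param target `"rates"` or `"sigma"`.
#' @param subset node subset for rate targets (`"all"`, `"leaf"`, `"internal"`).
#' @param kern a [kernel()].
#' @return an operator.
#' @export
op_random_walk <- function(target = c("rates", "sigma"), subset = "all",
                           kern = kernel()) {
  target <- match.arg(target)
  propose <- function(state, op) {
    if (target == "sigma") {
      x <- state$sigma + op$kernel$s * kernel_draw(op$kernel)
      if (x <= 0) return(propose_reject())
      state$sigma <- x
      return(propose_ok(state))
    }
    idx <- nodes_subset(state$tree, subset)
    i <- idx[sample.int(length(idx), 1L)]
    x <- state$rates$values[i]
    if (state$rates$mode == "cat") {
      width <- max(1L, as.integer(round(op$kernel$s)))
      xp <- x + sample(c(-1L, 1L), 1L) * sample.int(width, 1L)
      if (xp < 0 || xp >= state$rates$ncat) return(propose_reject())
    } else {
      xp <- x + op$kernel$s * kernel_draw(op$kernel)
      if (state$rates$mode == "real" && xp <= 0) return(propose_reject())
      if (state$rates$mode == "quant" && (xp <= 0 || xp >= 1))
        return(propose_reject())
    }
    state$rates$values[i] <- xp
    propose_ok(state)
  }
  modes <- if (target == "sigma") c("real", "cat", "quant") else c("real", "cat")
  new_operator(paste0("RandomWalk(", target, ")"), propose, kern, modes,
               poi = target,
               lik_invariant = if (target == "sigma")
                 function(state) state$rates$mode == "real")
}

#' Scale operator (random walk on the log scale)
#'
#' `x' = x * exp(s * Sigma)`; the log Hastings ratio is `log(x'/x)` from the
#' change of variables.
#'
#' @inheritParams op_random_walk
#' @export
op_scale <- function(target = c("rates", "sigma"), subset = "all",
                     kern = kernel()) {
  target <- match.arg(target)
  propose <- function(state, op) {
    f <- exp(op$kernel$s * kernel_draw(op$kernel))
    if (target == "sigma") {
      state$sigma <- state$sigma * f
      return(propose_ok(state, log_hr = log(f)))
    }
    idx <- nodes_subset(state$tree, subset)
    i <- idx[sample.int(length(idx), 1L)]
    state$rates$values[i] <- state$rates$values[i] * f
    propose_ok(state, log_hr = log(f))
  }
  modes <- if (target == "sigma") c("real", "cat", "quant") else "real"
  new_operator(paste0("Scale(", target, ")"), propose, kern, modes,
               poi = target,
               lik_invariant = if (target == "sigma")
                 function(state) state$rates$mode == "real")
}

#' Interval operator (random walk on the logit scale)
#'
#' For quantile elements in (0,1): `q' = logistic(logit(q) + s*Sigma)` with
#' log Hastings ratio `log[q'(1-q')] - log[q(1-q)]`.
#'
#' @inheritParams op_random_walk
#' @export
op_interval <- function(subset = "all", kern = kernel()) {
  propose <- function(state, op) {
    idx <- nodes_subset(state$tree, subset)
    i <- idx[sample.int(length(idx), 1L)]
    q <- state$rates$values[i]
    z <- log(q / (1 - q)) + op$kernel$s * kernel_draw(op$kernel)
    qp <- 1 / (1 + exp(-z))
    if (qp <= 0 || qp >= 1) return(propose_reject())
    state$rates$values[i] <- qp
    propose_ok(state, log_hr = log(qp * (1 - qp)) - log(q * (1 - q)))
  }
  new_operator("Interval(rates)", propose, kern, modes = "quant", poi = "rates")
}

#' Swap operator
#'
#' Exchanges two distinct elements of the rate vector; self-inverse, so the
#' Hastings ratio is 1.
#'
#' @inheritParams op_random_walk
#' @export
op_swap <- function(subset = "all", kern = NULL) {
  propose <- function(state, op) {
    idx <- nodes_subset(state$tree, subset)
    if (length(idx) < 2L) return(propose_reject())
    ij <- idx[sample.int(length(idx), 2L)]
    v <- state$rates$values
    state$rates$values[ij] <- v[rev(ij)]
    propose_ok(state)
  }
  new_operator("Swap(rates)", propose, NULL, poi = "rates")
}

#' Uniform resampling operator
#'
#' Redraws one element from its flat prior: the category set `{0..n-1}` for
#' `cat`, Uniform(0,1) for `quant`.  An independence proposal from the flat
#' prior, so the Hastings ratio is 1.
#'
#' @inheritParams op_random_walk
#' @export
op_uniform_resample <- function(subset = "all", kern = NULL) {
  propose <- function(state, op) {
    if (state$rates$mode == "real")
      stop("uniform resampling applies to cat/quant parameterisations")
    idx <- nodes_subset(state$tree, subset)
    i <- idx[sample.int(length(idx), 1L)]
    state$rates$values[i] <- if (state$rates$mode == "cat")
      sample.int(state$rates$ncat, 1L) - 1L else stats::runif(1)
    propose_ok(state)
  }
  new_operator("Uniform(rates)", propose, NULL, modes = c("cat", "quant"),
               poi = "rates")
}

#' Sample-from-prior operator
#'
#' Resamples `psi ~ Binomial(n, p = s/n)` randomly chosen elements of the
#' target vector from their prior distributions (an independence proposal;
#' the Hastings ratio is the old/new prior density ratio of the redrawn
#' elements).  The tunable `s` controls the expected number of elements.
#'
#' @inheritParams op_random_walk
#' @export
op_sample_from_prior <- function(target = c("rates", "sigma"), subset = "all",
                                 kern = kernel(s = 1)) {
  target <- match.arg(target)
  propose <- function(state, op) {
    if (target == "sigma") {
      old <- state$sigma
      new <- stats::rgamma(1, shape = .hyper$sigma_shape,
                           scale = .hyper$sigma_scale)
      state$sigma <- new
      lhr <- stats::dgamma(old, .hyper$sigma_shape, scale = .hyper$sigma_scale,
                           log = TRUE) -
             stats::dgamma(new, .hyper$sigma_shape, scale = .hyper$sigma_scale,
                           log = TRUE)
      return(propose_ok(state, log_hr = lhr))
    }
    idx <- nodes_subset(state$tree, subset)
    n <- length(idx)
    p <- min(1, op$kernel$s / n)
    psi <- stats::rbinom(1, n, p)
    if (psi == 0L) return(propose_ok(state))
    pick <- idx[sample.int(n, psi)]
    old <- state$rates$values[pick]
    mode <- state$rates$mode
    if (mode == "real") {
      new <- stats::rlnorm(psi, -0.5 * state$sigma^2, state$sigma)
      lhr <- sum(lognormal_rate_logpdf(old, state$sigma)) -
             sum(lognormal_rate_logpdf(new, state$sigma))
    } else if (mode == "cat") {
      new <- sample.int(state$rates$ncat, psi, replace = TRUE) - 1L
      lhr <- 0
    } else {
      new <- stats::runif(psi)
      lhr <- 0
    }
    state$rates$values[pick] <- new
    propose_ok(state, log_hr = lhr)
  }
  new_operator(paste0("SampleFromPrior(", target, ")"), propose, kern,
               poi = target,
               lik_invariant = if (target == "sigma")
                 function(state) state$rates$mode == "real")
}

# constant-distance family ----------------------------------------------------

# Convert the three rates incident to internal node X under a height change
# tX -> tXp, keeping each incident genetic distance r * tau fixed.
# Returns NULL when any proposed rate is non-positive.
.cd_rates <- function(r, tauold, taunew) {
  rp <- r * tauold / taunew
  if (any(rp <= 0) || any(!is.finite(rp))) return(NULL)
  rp
}

# Shared quant-mode bookkeeping: convert changed quantiles to rates, apply
# `fn(rates) -> rates'`, map back, and accumulate the piecewise-map Jacobian
# factors d rhat/dq at the old and new quantiles.
.quant_wrap <- function(state, nodes, fn) {
  kn <- state_knots(state)
  q <- state$rates$values[nodes]
  r <- .quant_rate_kn(q, kn)
  out <- fn(r)
  if (is.null(out)) return(NULL)
  rp <- out$rates
  qp <- .quant_from_rate_kn(rp, kn)
  if (any(qp <= 0 | qp >= 1)) return(NULL)
  ljac <- out$log_jac + sum(log(.quant_rate_deriv_kn(q, kn))) -
          sum(log(.quant_rate_deriv_kn(qp, kn)))
  list(q = qp, log_jac = ljac)
}

#' Constant-distance operator
#'
#' Shifts an internal (non-root) node height by `s * Sigma` and recomputes
#' the three incident branch rates so that every incident genetic distance
#' r*tau is unchanged (and with it the likelihood).  The Green ratio in
#' `real` mode is the product of old/new branch duration ratios; `quant`
#' mode accumulates the piecewise quantile-map derivatives as well.
#'
#' @param subset restrict eligible nodes to those with at least one child of
#'   this class (`"all"`, `"leaf"`, `"internal"`).
#' @param kern a [kernel()].
#' @export
op_constant_distance <- function(subset = "all", kern = kernel()) {
  propose <- function(state, op) {
    tr <- state$tree
    cand <- setdiff((tr$N + 1L):tr$nnode, tr$root)
    if (subset == "leaf")
      cand <- cand[tr$child[1L, cand] <= tr$N | tr$child[2L, cand] <= tr$N]
    if (subset == "internal")
      cand <- cand[tr$child[1L, cand] > tr$N | tr$child[2L, cand] > tr$N]
    if (!length(cand)) return(propose_reject())
    X <- cand[sample.int(length(cand), 1L)]
    P <- tr$parent[X]
    C <- tr$child[, X]
    tX <- tr$height[X]
    tXp <- tX + op$kernel$s * kernel_draw(op$kernel)
    lo <- max(tr$height[C]); hi <- tr$height[P]
    if (tXp <= lo || tXp >= hi) return(propose_reject())
    nodes <- c(C, X)
    tauold <- c(tX - tr$height[C], hi - tX)
    taunew <- c(tXp - tr$height[C], hi - tXp)
    if (state$rates$mode == "real") {
      rp <- .cd_rates(state$rates$values[nodes], tauold, taunew)
      if (is.null(rp)) return(propose_reject())
      state$rates$values[nodes] <- rp
      ljac <- sum(log(tauold)) - sum(log(taunew))
    } else {
      res <- .quant_wrap(state, nodes, function(r) {
        rp <- .cd_rates(r, tauold, taunew)
        if (is.null(rp)) return(NULL)
        list(rates = rp, log_jac = sum(log(tauold)) - sum(log(taunew)))
      })
      if (is.null(res)) return(propose_reject())
      state$rates$values[nodes] <- res$q
      ljac <- res$log_jac
    }
    state$tree$height[X] <- tXp
    propose_ok(state, log_jac = ljac)
  }
  new_operator(paste0("ConstantDistance(", subset, ")"), propose, kern,
               modes = c("real", "quant"), poi = c("rates", "heights"),
               lik_invariant = function(state) TRUE)
}

#' Simple-distance operator (constant distance at the root)
#'
#' Walks the root height and rescales the two root-child rates so the
#' root-child genetic distances are unchanged.
#'
#' @inheritParams op_constant_distance
#' @export
op_simple_distance <- function(kern = kernel()) {
  propose <- function(state, op) {
    tr <- state$tree
    R <- tr$root
    C <- tr$child[, R]
    tR <- tr$height[R]
    tRp <- tR + op$kernel$s * kernel_draw(op$kernel)
    if (tRp <= max(tr$height[C])) return(propose_reject())
    tauold <- tR - tr$height[C]
    taunew <- tRp - tr$height[C]
    if (state$rates$mode == "real") {
      rp <- .cd_rates(state$rates$values[C], tauold, taunew)
      if (is.null(rp)) return(propose_reject())
      state$rates$values[C] <- rp
      ljac <- sum(log(tauold)) - sum(log(taunew))
    } else {
      res <- .quant_wrap(state, C, function(r) {
        rp <- .cd_rates(r, tauold, taunew)
        if (is.null(rp)) return(NULL)
        list(rates = rp, log_jac = sum(log(tauold)) - sum(log(taunew)))
      })
      if (is.null(res)) return(propose_reject())
      state$rates$values[C] <- res$q
      ljac <- res$log_jac
    }
    state$tree$height[R] <- tRp
    propose_ok(state, log_jac = ljac)
  }
  new_operator("SimpleDistance", propose, kern, modes = c("real", "quant"),
               poi = c("rates", "heights"),
               lik_invariant = function(state) TRUE)
}

#' Small-pulley operator
#'
#' Shifts genetic distance between the two root branches while keeping their
#' combined distance (and all node heights) constant: for root children with
#' distances d1, d2, proposes `d1' = d1 + s*Sigma` within (0, d1 + d2).  In
#' rate space this is a translation, so the Jacobian is 1.
#'
#' @inheritParams op_constant_distance
#' @export
op_small_pulley <- function(kern = kernel()) {
  propose <- function(state, op) {
    tr <- state$tree
    C <- tr$child[, tr$root]
    tau <- tr$height[tr$root] - tr$height[C]
    move <- function(r) {
      d <- r * tau
      d1p <- d[1L] + op$kernel$s * kernel_draw(op$kernel)
      if (d1p <= 0 || d1p >= sum(d)) return(NULL)
      rp <- c(d1p, sum(d) - d1p) / tau
      if (any(rp <= 0)) return(NULL)
      list(rates = rp, log_jac = 0)
    }
    if (state$rates$mode == "real") {
      out <- move(state$rates$values[C])
      if (is.null(out)) return(propose_reject())
      state$rates$values[C] <- out$rates
      ljac <- 0
    } else {
      res <- .quant_wrap(state, C, move)
      if (is.null(res)) return(propose_reject())
      state$rates$values[C] <- res$q
      ljac <- res$log_jac
    }
    propose_ok(state, log_jac = ljac)
  }
  new_operator("SmallPulley", propose, kern, modes = c("real", "quant"),
               poi = "rates", lik_invariant = function(state) TRUE)
}

#' Cis-scale operator (clock sd scaler preserving the clock-model space)
#'
#' Scales `sigma' = sigma * exp(s * Sigma)`.  In `real` mode every rate is
#' recomputed so that its log-normal quantile is unchanged
#' (`r' = Finv_{sigma'}(F_sigma(r))`); in `quant` mode every quantile is
#' recomputed through the piecewise maps so that its rate is unchanged.  The
#' log Hastings ratio carries the sigma scale term plus the per-element
#' change-of-variables terms.
#'
#' @inheritParams op_constant_distance
#' @export
op_cis_scale <- function(kern = kernel()) {
  propose <- function(state, op) {
    sig <- state$sigma
    f <- exp(op$kernel$s * kernel_draw(op$kernel))
    sigp <- sig * f
    nodes <- nodes_nonroot(state$tree)
    if (state$rates$mode == "real") {
      r <- state$rates$values[nodes]
      # quantile-preserving: log r' = mu' + (sigma'/sigma) (log r - mu)
      lrp <- -0.5 * sigp^2 + f * (log(r) + 0.5 * sig^2)
      rp <- exp(lrp)
      ljac <- sum(log(f) + lrp - log(r))
      state$rates$values[nodes] <- rp
    } else {
      knold <- state_knots(state, sig)
      knnew <- state_knots(state, sigp)
      q <- state$rates$values[nodes]
      r <- .quant_rate_kn(q, knold)
      qp <- .quant_from_rate_kn(r, knnew)
      if (any(qp <= 0 | qp >= 1)) return(propose_reject())
      ljac <- sum(log(.quant_rate_deriv_kn(q, knold))) -
              sum(log(.quant_rate_deriv_kn(qp, knnew)))
      state$rates$values[nodes] <- qp
    }
    state$sigma <- sigp
    propose_ok(state, log_hr = log(f), log_jac = ljac)
  }
  new_operator("CisScale", propose, kern, modes = c("real", "quant"),
               poi = "sigma",
               lik_invariant = function(state) state$rates$mode == "quant")
}

# adaptive-variance multivariate normal leaf-rate operator --------------------

#' Leaf-rate AVMVN operator
#'
#' Proposes all N leaf branch rates jointly from a multivariate normal
#' centred at the current transformed rates (log for `real`, logit for
#' `quant`) with covariance `c * ((1-beta) * SigmaN + beta * I)`, where
#' SigmaN is the leaf-rate covariance learned during the run, `beta = 0.05`
#' and `c = 2.38^2 / N`.  Symmetric in the transformed space, so the
#' Hastings ratio reduces to the transform Jacobians.  Unavailable until
#' enough samples have accumulated to estimate SigmaN.
#'
#' @param stats_env environment holding the streaming estimate (fields `n`,
#'   `mean`, `M2`); populated by the chain driver.
#' @param min_samples samples required before the operator becomes available.
#' @param beta identity-mixing fraction.
#' @export
op_leaf_avmvn <- function(stats_env = new.env(parent = emptyenv()),
                          min_samples = 200, beta = 0.05) {
  propose <- function(state, op) {
    N <- state$tree$N
    st <- op$stats_env
    if (is.null(st$n) || st$n < op$min_samples) return(propose_reject())
    Sn <- st$M2 / (st$n - 1)
    cc <- 2.38^2 / N
    cov <- cc * ((1 - op$beta) * Sn + op$beta * diag(N))
    Lc <- tryCatch(chol(cov), error = function(e) NULL)
    if (is.null(Lc)) return(propose_reject())
    leaf <- seq_len(N)
    v <- state$rates$values[leaf]
    if (state$rates$mode == "real") {
      x <- log(v)
      xp <- x + drop(t(Lc) %*% stats::rnorm(N))
      state$rates$values[leaf] <- exp(xp)
      ljac <- sum(xp - x)
    } else {
      x <- log(v / (1 - v))
      xp <- x + drop(t(Lc) %*% stats::rnorm(N))
      qp <- 1 / (1 + exp(-xp))
      if (any(qp <= 0 | qp >= 1)) return(propose_reject())
      state$rates$values[leaf] <- qp
      ljac <- sum(log(qp * (1 - qp)) - log(v * (1 - v)))
    }
    propose_ok(state, log_jac = ljac)
  }
  op <- new_operator("LeafAVMVN", propose, NULL, modes = c("real", "quant"),
                     poi = "rates",
                     available = function(op, state)
                       !is.null(op$stats_env$n) && op$stats_env$n >= op$min_samples)
  op$stats_env <- stats_env
  op$min_samples <- min_samples
  op$beta <- beta
  op
}

# Streaming mean/covariance update (Welford) for the AVMVN target.
avmvn_record <- function(st, x) {
  if (is.null(st$n)) {
    st$n <- 0L
    st$mean <- numeric(length(x))
    st$M2 <- matrix(0, length(x), length(x))
  }
  st$n <- st$n + 1L
  d <- x - st$mean
  st$mean <- st$mean + d / st$n
  st$M2 <- st$M2 + tcrossprod(d, x - st$mean)
  invisible(st)
}

# plumbing operators for the remaining state dimensions ------------------------

#' Uniform internal-node height operator
#'
#' Redraws one internal (non-root) node height uniformly between its oldest
#' child and its parent; the interval is unchanged by the move, so the
#' proposal is symmetric.
#' @inheritParams op_constant_distance
#' @export
op_uniform_height <- function(kern = NULL) {
  propose <- function(state, op) {
    tr <- state$tree
    cand <- setdiff((tr$N + 1L):tr$nnode, tr$root)
    if (!length(cand)) return(propose_reject())
    X <- cand[sample.int(length(cand), 1L)]
    lo <- max(tr$height[tr$child[, X]])
    hi <- tr$height[tr$parent[X]]
    state$tree$height[X] <- stats::runif(1, lo, hi)
    propose_ok(state)
  }
  new_operator("UniformHeight", propose, NULL, poi = "heights")
}

#' Root-height scale operator
#' @inheritParams op_constant_distance
#' @export
op_root_scale <- function(kern = kernel(s = 0.2)) {
  propose <- function(state, op) {
    tr <- state$tree
    f <- exp(op$kernel$s * kernel_draw(op$kernel))
    tRp <- tr$height[tr$root] * f
    if (tRp <= max(tr$height[tr$child[, tr$root]])) return(propose_reject())
    state$tree$height[tr$root] <- tRp
    propose_ok(state, log_hr = log(f))
  }
  new_operator("RootScale", propose, kern, poi = "heights")
}

#' Substitution-model scale operator (kappa or lambda)
#' @param field `"kappa"` or `"lambda"`.
#' @param partition partition index for kappa.
#' @inheritParams op_constant_distance
#' @export
op_param_scale <- function(field = c("kappa", "lambda"), partition = 1L,
                           kern = kernel(s = 0.5)) {
  field <- match.arg(field)
  propose <- function(state, op) {
    f <- exp(op$kernel$s * kernel_draw(op$kernel))
    if (field == "lambda") state$lambda <- state$lambda * f
    else state$subst[[partition]]$kappa <- state$subst[[partition]]$kappa * f
    propose_ok(state, log_hr = log(f))
  }
  new_operator(paste0("Scale(", field, if (field == "kappa")
    paste0(".", partition) else "", ")"), propose, kern, poi = field,
               lik_invariant = if (field == "lambda") function(state) TRUE)
}

#' Base-frequency exchange operator
#'
#' Moves probability mass `delta ~ s * |Sigma|` between two random
#' frequencies of one partition, keeping the simplex constraint; symmetric.
#' @inheritParams op_param_scale
#' @export
op_freq_exchange <- function(partition = 1L, kern = kernel(s = 0.05)) {
  propose <- function(state, op) {
    fr <- state$subst[[partition]]$freqs
    ij <- sample.int(4L, 2L)
    delta <- op$kernel$s * kernel_draw(op$kernel)
    fr[ij] <- fr[ij] + c(delta, -delta)
    if (any(fr <= 0 | fr >= 1)) return(propose_reject())
    state$subst[[partition]]$freqs <- fr
    propose_ok(state)
  }
  new_operator(paste0("FreqExchange.", partition), propose, kern,
               poi = "freqs")
}

#' Weighted delta-exchange operator on relative clock rates
#'
#' Moves mass between the muC of two partitions, weighted by partition site
#' counts so the weighted mean stays exactly 1.  Only meaningful for P >= 2.
#' @param site_counts sites per partition.
#' @inheritParams op_param_scale
#' @export
op_muc_exchange <- function(site_counts, kern = kernel(s = 0.1)) {
  propose <- function(state, op) {
    P <- length(state$subst)
    ij <- sample.int(P, 2L)
    delta <- op$kernel$s * kernel_draw(op$kernel)
    wi <- site_counts[ij[1L]]; wj <- site_counts[ij[2L]]
    mi <- state$subst[[ij[1L]]]$muC + delta
    mj <- state$subst[[ij[2L]]]$muC - delta * wi / wj
    if (mi <= 0 || mj <= 0) return(propose_reject())
    state$subst[[ij[1L]]]$muC <- mi
    state$subst[[ij[2L]]]$muC <- mj
    propose_ok(state)
  }
  new_operator("MuCExchange", propose, kern, poi = "muC")
}
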
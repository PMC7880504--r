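# AdaptiveOperatorSampler: a meta-operator that learns the weights of its
# sub-operators during MCMC.  Three phases: burn-in (uniform sampling, no
# bookkeeping), learn-in (uniform sampling, statistics accumulate), sampling
# (operators drawn proportionally to accepted squared scaled distance per
# unit cost, mixed with a uniform floor Omega so every operator stays
# reachable and the chain remains ergodic).

#' Squared scaled distance between a state and its accepted proposal
#'
#' For a tree parameter the distance is the squared Robinson-Foulds distance;
#' for a numerical parameter `p` it is `(1/|p|) * (||x - x'|| / sigma_p)^2`
#' where `|p|` is the parameter's dimension and `sigma_p` its running sample
#' standard deviation (a zero `sigma_p` contributes 0: the parameter is not
#' yet varying).
#'
#' @param poi parameter-of-interest names (`"tree"` alone, or a set of
#'   numerical parameters such as `c("rates", "heights")`).
#' @param old,new the states before and after the accepted proposal.
#' @param sigma_p named vector of running standard deviations.
#' @return non-negative scalar.
#' @export
proposal_distance <- function(poi, old, new, sigma_p = NULL) {
  if (identical(poi, "tree"))
    return(robinson_foulds(old$tree, new$tree)^2)
  tot <- 0
  for (p in poi) {
    x <- poi_value(old, p); xp <- poi_value(new, p)
    sp <- if (is.null(sigma_p)) 1 else sigma_p[[p]]
    if (is.null(sp) || !is.finite(sp) || sp <= 0) next
    tot <- tot + sum(((x - xp) / sp)^2) / length(x)
  }
  tot
}

# Extract the numeric value vector of a named parameter of interest.
poi_value <- function(state, p) {
  switch(p,
         sigma = state$sigma,
         rates = state$rates$values[!is.na(state$rates$values)],
         rates_leaf = state$rates$values[seq_len(state$tree$N)],
         rates_int = state$rates$values[setdiff(
           (state$tree$N + 1L):state$tree$nnode, state$tree$root)],
         heights = state$tree$height,
         lambda = state$lambda,
         kappa = vapply(state$subst, `[[`, numeric(1), "kappa"),
         muC = vapply(state$subst, `[[`, numeric(1), "muC"),
         freqs = unlist(lapply(state$subst, `[[`, "freqs")),
         stop("unknown parameter of interest: ", p))
}

#' Create an AdaptiveOperatorSampler meta-operator
#'
#' @param name display name.
#' @param sub_ops list of sub-operators.
#' @param poi parameters of interest: `"tree"` or a vector of numerical
#'   parameter names (never both; the distance function differs).
#' @param omega uniform mixture floor (default 0.01).
#' @return object of classes `adaptive_operator`, `mcmc_operator`.
#' @export
adaptive_operator <- function(name, sub_ops, poi, omega = 0.01) {
  stopifnot(length(sub_ops) >= 1)
  st <- new.env(parent = emptyenv())
  K <- length(sub_ops)
  st$T <- numeric(K)
  st$dist <- numeric(K)
  st$proposed <- integer(K)
  st$accepted <- integer(K)
  # pooled Welford accumulators per numerical POI
  st$welford <- lapply(stats::setNames(poi, poi), function(p)
    list(n = 0, mean = 0, M2 = 0))
  op <- new_operator(name, propose = NULL, kernel = NULL,
                     modes = c("real", "cat", "quant"), poi = poi)
  op$sub_ops <- sub_ops
  op$stats <- st
  op$omega <- omega
  class(op) <- c("adaptive_operator", class(op))
  op
}

#' Operator statistics of an adaptive sampler
#'
#' @param op an [adaptive_operator()].
#' @return data frame with per-sub-operator cumulative cost `T`, accepted
#'   squared-distance sums, counts, and the current sampling probabilities.
#' @export
operator_stats <- function(op) {
  st <- op$stats
  data.frame(operator = vapply(op$sub_ops, `[[`, character(1), "name"),
             proposed = st$proposed, accepted = st$accepted,
             T = st$T, dist_sum = st$dist,
             prob = sample_operator_probs(op),
             stringsAsFactors = FALSE)
}

# Eq-11 sampling distribution over sub-operators (availability-filtered).
sample_operator_probs <- function(op, state = NULL) {
  st <- op$stats
  K <- length(op$sub_ops)
  avail <- vapply(seq_len(K), function(i) {
    f <- op$sub_ops[[i]]$available
    is.null(f) || f(op$sub_ops[[i]], state)
  }, logical(1))
  if (!any(avail)) avail <- rep(TRUE, K)
  score <- ifelse(st$T > 0, st$dist / st$T, 0)
  score[!avail] <- 0
  unif <- avail / sum(avail)
  if (sum(score) == 0) return(unif)
  op$omega * unif + (1 - op$omega) * score / sum(score)
}

#' Sample a sub-operator index from an adaptive sampler
#'
#' Burn-in and learn-in phases sample uniformly among available operators;
#' the sampling phase uses the learned distribution: with probability Omega
#' uniform, otherwise proportional to accepted squared scaled distance per
#' unit cumulative cost.
#'
#' @param op an [adaptive_operator()].
#' @param phase `"burnin"`, `"learnin"` or `"sampling"`.
#' @param state current state (for availability checks).
#' @return integer index into `op$sub_ops`.
#' @export
sample_operator <- function(op, phase = "sampling", state = NULL) {
  K <- length(op$sub_ops)
  avail <- vapply(seq_len(K), function(i) {
    f <- op$sub_ops[[i]]$available
    is.null(f) || is.null(state) || f(op$sub_ops[[i]], state)
  }, logical(1))
  if (!any(avail)) avail <- rep(TRUE, K)
  if (phase %in% c("burnin", "learnin")) {
    idx <- which(avail)
    return(idx[sample.int(length(idx), 1L)])
  }
  probs <- sample_operator_probs(op, state)
  sample.int(K, 1L, prob = probs)
}

#' Record the outcome of one sub-operator invocation
#'
#' Cost accumulates on every proposal; the distance sum only on acceptance.
#' Nothing is recorded during burn-in.
#'
#' @param op an [adaptive_operator()].
#' @param i sub-operator index.
#' @param accepted logical.
#' @param dist accepted-move squared scaled distance (ignored on rejection).
#' @param elapsed cost of the proposal (seconds, or a unit count).
#' @param phase current phase.
#' @export
record_outcome <- function(op, i, accepted, dist, elapsed, phase = "sampling") {
  if (phase == "burnin") return(invisible(op))
  st <- op$stats
  st$T[i] <- st$T[i] + elapsed
  st$proposed[i] <- st$proposed[i] + 1L
  if (accepted) {
    st$accepted[i] <- st$accepted[i] + 1L
    st$dist[i] <- st$dist[i] + dist
  }
  invisible(op)
}

# Update the pooled running sd of each numerical POI from the current state
# (batch Welford merge: exact pooled mean and M2 across the two samples).
adaptive_update_sigma_p <- function(op, state) {
  if (identical(op$poi, "tree")) return(invisible(op))
  st <- op$stats
  for (p in op$poi) {
    w <- st$welford[[p]]
    x <- poi_value(state, p)
    k <- length(x)
    mb <- sum(x) / k
    m2b <- sum((x - mb)^2)
    n <- w$n + k
    delta <- mb - w$mean
    w$M2 <- w$M2 + m2b + delta^2 * w$n * k / n
    w$mean <- w$mean + delta * k / n
    w$n <- n
    st$welford[[p]] <- w
  }
  invisible(op)
}

adaptive_sigma_p <- function(op) {
  vapply(op$stats$welford, function(w)
    if (w$n > 1) sqrt(w$M2 / (w$n - 1)) else 0, numeric(1))
}

#' Build the adaptive meta-operator rosters for a parameterisation
#'
#' Rosters follow the operator groupings of the adaptive scheme: a sigma
#' sampler, an all-rates sampler, a root sampler (constant-distance root
#' operators), leaf and internal samplers (the leaf one carrying the AVMVN
#' operator), and an NER sampler over the null and {DAE,DBE,DCE} variants
#' with the tree as its parameter of interest.  Operators incompatible with
#' the parameterisation are dropped, not errors.
#'
#' @param mode `"real"`, `"cat"` or `"quant"`.
#' @param kern_family kernel family for tunable sub-operators.
#' @param avmvn_env shared environment for the AVMVN covariance estimate.
#' @return named list of [adaptive_operator()]s (`sigma`, `rates`, `root`,
#'   `leaf`, `internal`, `ner`); entries with no applicable sub-operator are
#'   dropped.
#' @export
build_groupings <- function(mode = c("real", "cat", "quant"),
                            kern_family = "bactrian",
                            avmvn_env = new.env(parent = emptyenv())) {
  mode <- match.arg(mode)
  kk <- function(s = 1) kernel(kern_family, s = s)
  filt <- function(ops) Filter(function(o) mode %in% o$modes, ops)
  mk <- function(name, ops, poi) {
    ops <- filt(ops)
    if (!length(ops)) return(NULL)
    adaptive_operator(name, ops, poi)
  }
  rate_ops <- function(subset) list(
    op_constant_distance(subset, kk(0.2)),
    op_random_walk("rates", subset, kk(0.3)),
    op_scale("rates", subset, kk(0.5)),
    op_interval(subset, kk(0.5)),
    op_swap(subset),
    op_sample_from_prior("rates", subset, kk(2)))
  out <- list(
    sigma = mk("AdaptiveOperatorSampler(sigma)", list(
      op_cis_scale(kk(0.3)),
      op_random_walk("sigma", kern = kk(0.1)),
      op_scale("sigma", kern = kk(0.3)),
      op_sample_from_prior("sigma", kern = kk())), poi = "sigma"),
    rates = mk("AdaptiveOperatorSampler(rates)", rate_ops("all"),
               poi = c("rates", "heights")),
    root = mk("AdaptiveOperatorSampler(root)", list(
      op_simple_distance(kk(0.2)),
      op_small_pulley(kk(0.1))), poi = c("rates", "heights")),
    leaf = mk("AdaptiveOperatorSampler(leaf)", c(
      list(op_leaf_avmvn(avmvn_env)), rate_ops("leaf")),
      poi = c("rates_leaf", "heights")),
    internal = mk("AdaptiveOperatorSampler(internal)", rate_ops("internal"),
                  poi = c("rates_int", "heights")),
    ner = if (mode %in% c("real", "quant"))
      adaptive_operator("AdaptiveOperatorSampler(NER)", list(
        op_narrow_exchange(),
        op_ner(c("DAE", "DBE", "DCE"))), poi = "tree")
  )
  out[!vapply(out, is.null, logical(1))]
}
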
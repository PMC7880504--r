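# Synthetic data generation and the experimental harnesses: NER variant
# screening by acceptance rate, configuration benchmarking by ESS per state,
# and well-calibrated coverage studies.

#' Simulate a Yule time tree with contemporaneous tips
#'
#' Waiting-time construction matching [yule_log_prior()]: going down from the
#' root, the interval with k extant lineages lasts Exp(k * lambda) and a
#' uniformly chosen lineage splits, until N lineages reach the present.
#'
#' @param N taxon count (>= 2).
#' @param lambda birth rate.
#' @param labels tip labels (default `t1..tN`).
#' @return a [timetree()].
#' @export
sim_yule_tree <- function(N, lambda = 1, labels = paste0("t", seq_len(N))) {
  stopifnot(N >= 2, lambda > 0)
  w <- stats::rexp(N - 1L, rate = (2:N) * lambda)
  ev_height <- rev(cumsum(rev(w)))   # height of split event i (root = 1st)
  nnode <- 2L * N - 1L
  parent <- rep(NA_integer_, nnode)
  height <- numeric(nnode)
  root <- N + 1L
  height[root] <- ev_height[1L]
  next_id <- N + 2L
  # track lineages as the multiset of dangling child positions (parents with
  # fewer than two children attached)
  dangling <- c(root, root)
  for (i in seq_len(N - 1L)[-1L]) {
    j <- sample.int(length(dangling), 1L)
    p <- dangling[j]
    id <- next_id; next_id <- next_id + 1L
    parent[id] <- p
    height[id] <- ev_height[i]
    dangling <- c(dangling[-j], id, id)
  }
  tips <- sample.int(N)             # random assignment of labels to slots
  for (k in seq_len(N)) {
    parent[tips[k]] <- dangling[k]
    height[tips[k]] <- 0
  }
  timetree(parent, height, labels)
}

#' Simulate branch rates under the relaxed clock
#'
#' Node-indexed rates (root entry `NA`), iid Log-normal(-sigma^2/2, sigma);
#' `sigma = 0` is the strict-clock limit with every rate exactly 1.
#'
#' @param tr a [timetree()].
#' @param sigma clock standard deviation (>= 0).
#' @return numeric vector of real rates.
#' @export
sim_branch_rates <- function(tr, sigma) {
  r <- rep(NA_real_, tr$nnode)
  nonroot <- setdiff(seq_len(tr$nnode), tr$root)
  r[nonroot] <- if (sigma == 0) 1
                else stats::rlnorm(length(nonroot), -0.5 * sigma^2, sigma)
  r
}

#' Evolve a nucleotide alignment down a time tree
#'
#' HKY simulation (Jukes-Cantor when `kappa = 1` with equal frequencies):
#' the root sequence is drawn from the stationary frequencies and each branch
#' applies its transition matrix at distance `muC * r_i * tau_i`.
#'
#' @param tr a [timetree()].
#' @param rates node-indexed real branch rates.
#' @param L sites.
#' @param kappa transition/transversion ratio.
#' @param freqs stationary frequencies.
#' @param muC overall clock rate multiplier.
#' @return an [alignment()].
#' @export
sim_alignment <- function(tr, rates, L, kappa = 1, freqs = rep(0.25, 4),
                          muC = 1) {
  seqs <- matrix(NA_integer_, tr$nnode, L)
  seqs[tr$root, ] <- sample.int(4L, L, replace = TRUE, prob = freqs)
  tau <- tt_branch_lengths(tr)
  for (u in rev(tr$postorder)) {
    if (u == tr$root) next
    P <- hky_transition_probs(muC * rates[u] * tau[u], kappa, freqs)
    par <- seqs[tr$parent[u], ]
    out <- integer(L)
    for (s in 1:4) {
      idx <- which(par == s)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    seqs[u, ] <- out
  }
  alignment(tr$tip.label, seqs[seq_len(tr$N), , drop = FALSE])
}

#' Simulate a complete relaxed-clock dataset
#'
#' Yule tree, iid log-normal branch rates, HKY-evolved alignment.
#'
#' @param N taxa; `L` sites; `sigma` clock sd; `lambda` birth rate.
#' @param L,sigma,lambda,kappa,freqs see above.
#' @param seed optional RNG seed.
#' @return list with `tree`, `rates` (node-indexed real rates), `aln`, and
#'   the generating parameters.
#' @export
simulate_dataset <- function(N, L, sigma, lambda = 1, kappa = 1,
                             freqs = rep(0.25, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- sim_yule_tree(N, lambda)
  r <- sim_branch_rates(tr, sigma)
  aln <- sim_alignment(tr, r, L, kappa, freqs)
  list(tree = tr, rates = r, aln = aln,
       params = list(N = N, L = L, sigma = sigma, lambda = lambda,
                     kappa = kappa, freqs = freqs))
}

#' Draw an initial state from the model priors
#'
#' @param N taxa (or use `tree` to fix the tree).
#' @param mode parameterisation.
#' @param P partitions.
#' @param tree optional fixed starting tree; drawn from the Yule prior
#'   otherwise.
#' @param npieces `quant` piece count.
#' @return a [phylo_state()].
#' @export
init_state_from_prior <- function(N, mode = "real", P = 1L, tree = NULL,
                                  npieces = 100) {
  h <- .hyper
  lambda <- stats::rlnorm(1, h$lambda_meanlog, h$lambda_sdlog)
  if (is.null(tree)) tree <- sim_yule_tree(N, lambda)
  sigma <- stats::rgamma(1, shape = h$sigma_shape, scale = h$sigma_scale)
  nonroot <- setdiff(seq_len(tree$nnode), tree$root)
  v <- rep(NA_real_, tree$nnode)
  v[nonroot] <- switch(mode,
    real  = stats::rlnorm(length(nonroot), -0.5 * sigma^2, sigma),
    cat   = sample.int(length(nonroot), length(nonroot), replace = TRUE) - 1L,
    quant = stats::runif(length(nonroot)))
  rates <- branch_rates(v, mode, ncat = if (mode == "cat") length(nonroot))
  subst <- lapply(seq_len(P), function(p) list(
    kappa = stats::rlnorm(1, h$kappa_meanlog, h$kappa_sdlog),
    freqs = { g <- stats::rgamma(4, shape = h$freqs_alpha); g / sum(g) },
    muC = 1))
  phylo_state(tree, rates, sigma, subst, lambda, npieces)
}

# pooled two-proportion one-sided z statistic (x1/n1 vs x2/n2, H1: p1 > p2)
two_proportion_z <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(0)
  (x1 / n1 - x2 / n2) / se
}

#' Screen NER variants against the null operator by acceptance rate
#'
#' Runs one MCMC chain per dataset in which every screened variant (plus the
#' null operator NER{}) participates with equal weight alongside a standard
#' clock-operator schedule with fixed (untuned) kernels so acceptance rates
#' are comparable.  Each variant's accept/propose counts are compared with
#' NER{} by one-sided two-proportion z-tests in both directions.
#'
#' @param variants list of constraint subsets (character vectors) or a
#'   character vector of labels like `"NER{DAE,DBE,DCE}"`; `walk = TRUE`
#'   entries can be given as `list(S = ..., walk = TRUE)`.
#' @param datasets list of [simulate_dataset()] results.
#' @param chain_length proposals per dataset.
#' @param alpha significance level of the z-tests (default 0.001).
#' @param mode parameterisation (`real` or `quant`).
#' @return list with `per_dataset` (counts and z statistics) and `summary`
#'   (per variant: fraction of datasets significantly better/worse than the
#'   null operator).
#' @export
screen_ner_variants <- function(variants, datasets, chain_length = 4000,
                                alpha = 0.001, mode = "real") {
  norm_var <- function(v) {
    if (is.character(v) && length(v) == 1L && grepl("^NERw?\\{", v)) {
      walk <- startsWith(v, "NERw")
      S <- strsplit(gsub("^NERw?\\{|\\}$", "", v), ",")[[1]]
      list(S = S[nzchar(S)], walk = walk)
    } else if (is.list(v) && !is.null(v$S)) v
    else list(S = as.character(v), walk = FALSE)
  }
  vars <- lapply(variants, norm_var)
  labels <- vapply(vars, function(v)
    if (v$walk) sub("^NER", "NERw", ner_label(v$S)) else ner_label(v$S),
    character(1))
  if (!"NER{}" %in% labels) {
    vars <- c(list(list(S = character(0), walk = FALSE)), vars)
    labels <- c("NER{}", labels)
  }
  per <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    sig0 <- max(ds$params$sigma, 0.05)
    v <- ds$rates
    if (mode == "quant") {
      ok <- !is.na(v)
      v[ok] <- quant_from_rate(v[ok], sig0)
    }
    state <- phylo_state(
      ds$tree, branch_rates(v, mode), sigma = sig0,
      subst = list(list(kappa = ds$params$kappa, freqs = ds$params$freqs,
                        muC = 1)),
      lambda = ds$params$lambda)
    cfg <- chain_config(chain_length, log_interval = chain_length,
                        mode = mode, configuration = "cons",
                        tuning = FALSE)
    ner_ops <- lapply(vars, function(v)
      op_ner(v$S, walk = v$walk, kern = kernel(s = 0.05)))
    res <- run_chain_with_extra_ops(state, ds$aln, cfg, ner_ops,
                                    extra_weight = 30)
    counts <- res$operators[match(labels, res$operators$operator), ]
    null_row <- counts[counts$operator == "NER{}", ]
    counts$z_better <- vapply(seq_len(nrow(counts)), function(i)
      two_proportion_z(counts$accepted[i], counts$proposed[i],
                       null_row$accepted, null_row$proposed), numeric(1))
    counts$z_worse <- -counts$z_better
    counts$dataset <- di
    per[[di]] <- counts
  }
  all <- do.call(rbind, per)
  zcrit <- stats::qnorm(1 - alpha)
  summary <- do.call(rbind, lapply(setdiff(labels, "NER{}"), function(lb) {
    sub <- all[all$operator == lb, ]
    data.frame(operator = lb,
               mean_accept = mean(sub$accept_rate, na.rm = TRUE),
               frac_better = mean(sub$z_better > zcrit),
               frac_worse = mean(sub$z_worse > zcrit),
               stringsAsFactors = FALSE)
  }))
  list(per_dataset = all, summary = summary)
}

# A chain run whose schedule is augmented with extra operators sharing
# `extra_weight` equally; reuses run_chain by temporarily injecting the
# operators through a bespoke configuration hook.
run_chain_with_extra_ops <- function(state, aln, config, extra_ops,
                                     extra_weight = 30) {
  patterns <- compress_site_patterns(aln)
  P <- aln$P
  site_counts <- as.numeric(table(factor(aln$partition, levels = seq_len(P))))
  sched <- build_schedule(config, state$tree$N, P, site_counts)
  # drop the default topology operator so the variants compete on equal terms
  keep <- vapply(sched, function(e)
    !e$op$name %in% c("NarrowExchange", "AdaptiveOperatorSampler(NER)"),
    logical(1))
  sched <- sched[keep]
  for (op in extra_ops)
    sched[[length(sched) + 1L]] <- list(op = op,
                                        weight = extra_weight / length(extra_ops))
  run_schedule(state, aln, patterns, sched, config)
}

# Minimal fixed-schedule chain: no adaptivity, optional tuning, returns the
# operator report and final state.
run_schedule <- function(state, aln, patterns, sched, config) {
  weights <- vapply(sched, `[[`, numeric(1), "weight")
  ops <- lapply(sched, `[[`, "op")
  parts <- log_posterior_parts(state, aln, patterns)
  if (!is.finite(parts$posterior)) stop("initial state has -Inf posterior")
  nms <- vapply(ops, `[[`, character(1), "name")
  prop_count <- acc_count <- stats::setNames(numeric(length(ops)), nms)
  for (it in seq_len(config$chain_length)) {
    oi <- sample.int(length(ops), 1L, prob = weights)
    op <- ops[[oi]]
    prop <- op$propose(state, op)
    accepted <- FALSE
    if (!prop$reject) {
      new_parts <- log_posterior_parts(prop$state, aln, patterns)
      alpha <- accept_probability(new_parts$posterior, parts$posterior,
                                  prop$log_hr, prop$log_jac)
      accepted <- stats::runif(1) < alpha
      if (accepted) { state <- prop$state; parts <- new_parts }
    }
    if (config$tuning && !is.null(op$kernel)) {
      op$kernel <- tune_scale(op$kernel, as.integer(accepted), 1L)
      ops[[oi]] <- op
    }
    prop_count[oi] <- prop_count[oi] + 1
    acc_count[oi] <- acc_count[oi] + as.integer(accepted)
  }
  list(operators = data.frame(operator = nms,
                              proposed = as.integer(prop_count),
                              accepted = as.integer(acc_count),
                              accept_rate = ifelse(prop_count > 0,
                                                   acc_count / prop_count, NA),
                              stringsAsFactors = FALSE),
       final_state = state)
}

#' Benchmark operator configurations by ESS per state
#'
#' @param configs character vector of configuration names (see
#'   [chain_config()]).
#' @param dataset a [simulate_dataset()] result.
#' @param replicates chains per configuration.
#' @param chain_length proposals per chain.
#' @param mode parameterisation.
#' @param seed RNG seed.
#' @return data frame: configuration x parameter mean ESS/state and its
#'   standard error across replicates; replicates with ESS below 50 for the
#'   posterior are flagged.
#' @export
benchmark_configurations <- function(configs, dataset, replicates = 3,
                                     chain_length = 20000, mode = "real",
                                     seed = 1) {
  keys <- c("likelihood", "prior", "tree.length", "mean.rate", "sigma",
            "kappa.1")
  rows <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cf <- configs[ci]
    esss <- matrix(NA_real_, replicates, length(keys),
                   dimnames = list(NULL, keys))
    flagged <- logical(replicates)
    for (rp in seq_len(replicates)) {
      set.seed(seed + 1000 * rp)
      st <- init_state_from_prior(dataset$params$N, mode,
                                  tree = dataset$tree)
      cfg <- chain_config(chain_length, log_interval = max(1, chain_length %/% 2000),
                          mode = mode, configuration = cf)
      tr <- run_chain(st, dataset$aln, cfg)
      e <- trace_ess(tr)
      esss[rp, ] <- e[keys]
      flagged[rp] <- e["posterior"] < 50
    }
    rows[[ci]] <- data.frame(
      configuration = cf, run = ci, parameter = keys,
      ess_per_state = colMeans(esss) / chain_length,
      se = apply(esss, 2, stats::sd) / sqrt(replicates) / chain_length,
      flagged_replicates = sum(flagged), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Well-calibrated coverage study
#'
#' Draws truths from the priors, simulates an alignment, runs the chain, and
#' scores 95\% credible-interval coverage of the clock standard deviation,
#' the tree length, and kappa.
#'
#' @param nrep replicates.
#' @param N,L taxa and sites.
#' @param chain_length proposals per replicate.
#' @param mode,configuration chain settings.
#' @param seed RNG seed.
#' @return list with per-replicate results and coverage proportions.
#' @export
coverage_study <- function(nrep = 50, N = 8, L = 500, chain_length = 20000,
                           mode = "real", configuration = "adapt", seed = 1) {
  rows <- list()
  for (i in seq_len(nrep)) {
    set.seed(seed + i)
    truth <- init_state_from_prior(N, mode = "real")
    r <- truth$rates$values
    aln <- sim_alignment(truth$tree, r, L, truth$subst[[1]]$kappa,
                         truth$subst[[1]]$freqs)
    st0 <- init_state_from_prior(N, mode, tree = truth$tree)
    cfg <- chain_config(chain_length,
                        log_interval = max(1, chain_length %/% 2000),
                        mode = mode, configuration = configuration,
                        cost = "count")
    tr <- run_chain(st0, aln, cfg)
    sm <- tr$samples[-seq_len(floor(nrow(tr$samples) * 0.1)), ]
    ci <- function(x) stats::quantile(x, c(0.025, 0.975))
    inci <- function(x, truthv) {
      q <- ci(x); truthv >= q[1] && truthv <= q[2]
    }
    rows[[i]] <- data.frame(
      rep = i,
      sigma_cover = inci(sm$sigma, truth$sigma),
      length_cover = inci(sm$tree.length, tree_length(truth$tree)),
      kappa_cover = inci(sm$kappa.1, truth$subst[[1]]$kappa))
  }
  res <- do.call(rbind, rows)
  list(results = res,
       coverage = c(sigma = mean(res$sigma_cover),
                    tree_length = mean(res$length_cover),
                    kappa = mean(res$kappa_cover)),
       nrep = nrep)
}
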
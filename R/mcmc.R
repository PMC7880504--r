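# Metropolis-Hastings-Green chain driver, operator schedules, trace logging
# and ESS diagnostics.

#' Metropolis-Hastings-Green acceptance probability
#'
#' `min(1, exp(delta_logpost + log HR + log |J|))`; a reject-sentinel
#' proposal (log HR or log |J| of -Inf) has probability 0.
#'
#' @param logpost_new,logpost_old log posterior densities.
#' @param log_hr log Hastings ratio.
#' @param log_jac log Jacobian determinant (Green ratio).
#' @return acceptance probability in `[0, 1]`.
#' @export
accept_probability <- function(logpost_new, logpost_old, log_hr = 0,
                               log_jac = 0) {
  if (!is.finite(logpost_old)) stop("current state has non-finite posterior")
  lr <- logpost_new - logpost_old + log_hr + log_jac
  if (!is.finite(lr) && lr > 0) return(1)
  if (is.nan(lr) || lr == -Inf) return(0)
  min(1, exp(lr))
}

#' Chain configuration
#'
#' @param chain_length number of proposals.
#' @param log_interval states between trace rows.
#' @param mode parameterisation: `"real"`, `"cat"` or `"quant"`.
#' @param configuration clock-operator configuration: `"nocons"`, `"cons"`,
#'   `"adapt"` or `"avmvn"`.
#' @param topology `"ner-null"` (classic narrow exchange, weight 15) or
#'   `"ner-adaptive"` (adaptive sampler over NER{} and NER{DAE,DBE,DCE}).
#' @param kernel_family `"bactrian"` or `"uniform"` for all tunable kernels.
#' @param seed RNG seed (set at chain start when non-NULL).
#' @param burnin_frac,learnin_frac phase boundaries for adaptive sampling and
#'   kernel-tuning freeze, as fractions of the chain.
#' @param cost `"wall"` (Eq-11 cost is wall time) or `"count"` (proposal
#'   counts; makes equal-seed runs bit-identical).
#' @param log_trees keep sampled trees as newick strings.
#' @param tuning enable step-size auto-tuning.
#' @return list of class `chainconfig`.
#' @export
chain_config <- function(chain_length = 10000, log_interval = 10,
                         mode = c("real", "cat", "quant"),
                         configuration = c("adapt", "nocons", "cons", "avmvn"),
                         topology = c("ner-null", "ner-adaptive"),
                         kernel_family = c("bactrian", "uniform"),
                         seed = NULL, burnin_frac = 0.1, learnin_frac = 0.1,
                         cost = c("wall", "count"), log_trees = FALSE,
                         tuning = TRUE) {
  structure(list(chain_length = as.integer(chain_length),
                 log_interval = as.integer(log_interval),
                 mode = match.arg(mode),
                 configuration = match.arg(configuration),
                 topology = match.arg(topology),
                 kernel_family = match.arg(kernel_family),
                 seed = seed, burnin_frac = burnin_frac,
                 learnin_frac = learnin_frac, cost = match.arg(cost),
                 log_trees = log_trees, tuning = tuning),
            class = "chainconfig")
}

# Operator schedule per the named configurations.  Clock-operator weights:
# within each configuration the weight behind the branch-rate vector sums to
# 30, sigma carries 10, and the narrow-exchange weight is 15; node-set
# operators are weighted by leaf count N.
build_schedule <- function(config, N, P, site_counts,
                           avmvn_env = new.env(parent = emptyenv())) {
  kf <- config$kernel_family
  kk <- function(s = 1) kernel(kf, s = s)
  mode <- config$mode
  two <- 2 * N - 2
  ent <- function(op, w) if (is.null(op) || !(mode %in% op$modes)) NULL
                         else list(op = op, weight = w)
  sched <- list()
  add <- function(e) if (!is.null(e)) sched[[length(sched) + 1L]] <<- e
  if (config$configuration == "nocons") {
    add(ent(op_random_walk("rates", kern = kk(0.3)), 10))
    add(ent(op_scale("rates", kern = kk(0.5)), 10))
    add(ent(op_uniform_resample(), 10))
    add(ent(op_interval(kern = kk(0.5)), 10))
    add(ent(op_swap(), 10))
    add(ent(op_scale("sigma", kern = kk(0.3)), 10))
  } else if (config$configuration == "cons") {
    if (mode == "cat") stop("the cons configuration requires real or quant")
    add(ent(op_constant_distance("all", kk(0.2)), 20 * two / (two + 1)))
    add(ent(op_simple_distance(kk(0.2)), 10 / (two + 1)))
    add(ent(op_small_pulley(kk(0.1)), 10 / (two + 1)))
    add(ent(op_random_walk("rates", kern = kk(0.3)), 5))
    add(ent(op_scale("rates", kern = kk(0.5)), 2.5))
    add(ent(op_uniform_resample(), 5))
    add(ent(op_interval(kern = kk(0.5)), 2.5))
    add(ent(op_swap(), 2.5))
    if (mode == "real") add(ent(op_cis_scale(kk(0.3)), 10))
    else add(ent(op_scale("sigma", kern = kk(0.3)), 10))
  } else {
    gr <- build_groupings(mode, kf, avmvn_env)
    add(list(op = gr$sigma, weight = 10))
    if (config$configuration == "adapt") {
      if (mode == "cat") add(list(op = gr$rates, weight = 30))
      else {
        add(list(op = gr$rates, weight = 30 * two / (two + 1)))
        add(list(op = gr$root, weight = 30 / (two + 1)))
      }
    } else {  # avmvn
      if (mode == "cat") stop("the AVMVN configuration requires real or quant")
      add(list(op = gr$leaf, weight = 30 * N / (two + 1)))
      add(list(op = gr$internal, weight = 30 * (N - 2) / (two + 1)))
      add(list(op = gr$root, weight = 30 / (two + 1)))
    }
  }
  # topology operators
  if (config$topology == "ner-adaptive" && mode != "cat") {
    gr_ner <- build_groupings(mode, kf)$ner
    add(list(op = gr_ner, weight = 15))
  } else {
    add(list(op = op_narrow_exchange(), weight = 15))
  }
  add(list(op = op_uniform_height(), weight = 15))
  add(list(op = op_root_scale(kk(0.2)), weight = 3))
  for (p in seq_len(P)) {
    add(list(op = op_param_scale("kappa", p, kk(0.5)), weight = 1))
    add(list(op = op_freq_exchange(p, kk(0.1)), weight = 1))
  }
  if (P > 1) add(list(op = op_muc_exchange(site_counts, kk(0.1)), weight = 2))
  add(list(op = op_param_scale("lambda", kern = kk(0.5)), weight = 1))
  sched
}

chain_phase <- function(iter, config) {
  f <- iter / config$chain_length
  if (f <= config$burnin_frac) "burnin"
  else if (f <= config$burnin_frac + config$learnin_frac) "learnin"
  else "sampling"
}

#' Run a Metropolis-Hastings-Green chain
#'
#' Operators are drawn by weight from the configuration's schedule; adaptive
#' meta-operators learn sub-operator weights after their learn-in phase;
#' step-size tuning runs until the sampling phase begins and is then frozen
#' so learned weights stay meaningful.  With `aln = NULL` the likelihood is
#' omitted and the chain samples the prior.
#'
#' @param state0 initial [phylo_state()] (finite posterior required).
#' @param aln an [alignment()] or `NULL`.
#' @param config a [chain_config()].
#' @return object of class `mcmctrace`: `samples` (data frame), `trees`
#'   (newick strings or `NULL`), `operators` (report data frame),
#'   `adaptive` (per-meta-operator learned statistics), `config`.
#' @export
run_chain <- function(state0, aln = NULL, config = chain_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  patterns <- if (!is.null(aln)) {
    pp <- compress_site_patterns(aln)
    perm <- match(state0$tree$tip.label, aln$labels)
    pp <- lapply(pp, function(e) {
      e$pat <- e$pat[perm, , drop = FALSE]
      e
    })
    attr(pp, "tip_order") <- state0$tree$tip.label
    pp
  }
  P <- if (is.null(aln)) length(state0$subst) else aln$P
  site_counts <- if (is.null(aln)) rep(1, P) else
    as.numeric(table(factor(aln$partition, levels = seq_len(P))))
  avmvn_env <- new.env(parent = emptyenv())
  sched <- build_schedule(config, state0$tree$N, P, site_counts, avmvn_env)
  weights <- vapply(sched, `[[`, numeric(1), "weight")
  ops <- lapply(sched, `[[`, "op")
  nop <- length(ops)
  wall <- identical(config$cost, "wall")

  state <- state0
  parts <- log_posterior_parts(state, aln, patterns)
  if (!is.finite(parts$posterior))
    stop("initial state has log posterior -Inf")

  nlog <- floor(config$chain_length / config$log_interval) + 1L
  scalars <- c("state", "posterior", "likelihood", "prior", "tree.length",
               "mean.rate", "rate.1", "sigma", "lambda", "root.height",
               paste0("kappa.", seq_len(P)), paste0("muC.", seq_len(P)))
  samples <- matrix(NA_real_, nlog, length(scalars),
                    dimnames = list(NULL, scalars))
  trees <- if (config$log_trees) character(nlog)
  log_row <- function(k, it) {
    r <- state_rates(state)
    samples[k, ] <<- c(it, parts$posterior, parts$likelihood, parts$prior,
                       tree_length(state$tree), mean(r, na.rm = TRUE),
                       r[1L], state$sigma, state$lambda,
                       state$tree$height[state$tree$root],
                       vapply(state$subst, `[[`, numeric(1), "kappa"),
                       vapply(state$subst, `[[`, numeric(1), "muC"))
    if (config$log_trees) trees[k] <<- write_newick(state$tree)
  }
  log_row(1L, 0L)

  prop_count <- acc_count <- stats::setNames(numeric(nop), vapply(
    ops, `[[`, character(1), "name"))
  k <- 1L
  for (it in seq_len(config$chain_length)) {
    phase <- chain_phase(it, config)
    oi <- sample.int(nop, 1L, prob = weights)
    op <- ops[[oi]]
    t0 <- if (wall) proc.time()[[3L]]
    if (inherits(op, "adaptive_operator")) {
      if (phase != "burnin") adaptive_update_sigma_p(op, state)
      si <- sample_operator(op, phase, state)
      sub <- op$sub_ops[[si]]
      prop <- sub$propose(state, sub)
    } else {
      prop <- op$propose(state, op)
    }
    cur_op <- if (inherits(op, "adaptive_operator")) sub else op
    accepted <- FALSE
    if (!prop$reject) {
      inv <- !is.null(aln) && !is.null(cur_op$lik_invariant) &&
             cur_op$lik_invariant(state)
      new_parts <- if (inv) {
        np <- log_posterior_parts(prop$state, NULL)
        list(posterior = np$prior + parts$likelihood,
             likelihood = parts$likelihood, prior = np$prior)
      } else {
        log_posterior_parts(prop$state, aln, patterns)
      }
      alpha <- accept_probability(new_parts$posterior, parts$posterior,
                                  prop$log_hr, prop$log_jac)
      accepted <- stats::runif(1) < alpha
    }
    elapsed <- if (wall) proc.time()[[3L]] - t0 else 1
    if (inherits(op, "adaptive_operator")) {
      d <- if (accepted)
        proposal_distance(op$poi, state, prop$state,
                          adaptive_sigma_p(op)) else 0
      record_outcome(op, si, accepted, d, elapsed, phase)
      if (config$tuning && phase != "sampling" && !is.null(sub$kernel)) {
        sub$kernel <- tune_scale(sub$kernel, as.integer(accepted), 1L)
        op$sub_ops[[si]]$kernel <- sub$kernel
        ops[[oi]] <- op
      }
      nm <- op$name
    } else {
      if (config$tuning && phase != "sampling" && !is.null(op$kernel)) {
        op$kernel <- tune_scale(op$kernel, as.integer(accepted), 1L)
        ops[[oi]] <- op
      }
      nm <- op$name
    }
    if (accepted) {
      state <- prop$state
      parts <- new_parts
    }
    prop_count[nm] <- prop_count[nm] + 1
    acc_count[nm] <- acc_count[nm] + as.integer(accepted)
    # AVMVN covariance training on the transformed leaf rates
    if (config$configuration == "avmvn" && phase != "burnin" &&
        state$rates$mode %in% c("real", "quant")) {
      v <- state$rates$values[seq_len(state$tree$N)]
      x <- if (state$rates$mode == "real") log(v) else log(v / (1 - v))
      avmvn_record(avmvn_env, x)
    }
    if (it %% config$log_interval == 0L) {
      k <- k + 1L
      log_row(k, it)
    }
  }

  # operator report (sub-operators of adaptive samplers expanded)
  rep_rows <- list()
  for (oi in seq_len(nop)) {
    op <- ops[[oi]]
    if (inherits(op, "adaptive_operator")) {
      stt <- operator_stats(op)
      stt$meta <- op$name
      rep_rows[[length(rep_rows) + 1L]] <- stt
    }
  }
  operators <- data.frame(operator = names(prop_count),
                          proposed = as.integer(prop_count),
                          accepted = as.integer(acc_count),
                          accept_rate = ifelse(prop_count > 0,
                                               acc_count / prop_count, NA),
                          stringsAsFactors = FALSE)
  structure(list(samples = as.data.frame(samples), trees = trees,
                 operators = operators,
                 adaptive = if (length(rep_rows)) do.call(rbind, rep_rows),
                 config = config, final_state = state),
            class = "mcmctrace")
}

#' @export
print.mcmctrace <- function(x, ...) {
  cat("mcmctrace:", nrow(x$samples), "samples,",
      x$config$chain_length, "states,", x$config$configuration,
      paste0("(", x$config$mode, ")"), "\n")
  invisible(x)
}

#' Effective sample size of a scalar trace
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule on paired autocorrelations.  A constant
#' series returns `n` with attribute `degenerate = TRUE`.
#'
#' @param x numeric series (length >= 10).
#' @return positive real.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short for ESS estimation")
  if (stats::var(x) == 0) return(structure(as.numeric(n), degenerate = TRUE))
  lag_max <- min(n - 1L, max(50L, floor(10 * sqrt(n))))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    gamma <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (gamma <= 0 && m > 0L) break
    s <- s + gamma
    m <- m + 1L
  }
  max(n / (1 + 2 * s), 1)
}

#' Per-column ESS of a trace
#' @param trace an [run_chain()] result.
#' @param burnin_frac fraction of rows discarded first.
#' @return named vector of ESS values.
#' @export
trace_ess <- function(trace, burnin_frac = 0.1) {
  sm <- trace$samples
  sm <- sm[-seq_len(floor(nrow(sm) * burnin_frac)), , drop = FALSE]
  cols <- setdiff(colnames(sm), "state")
  vapply(cols, function(cn) effective_sample_size(sm[[cn]]), numeric(1))
}

#' Write a trace's scalar samples as TSV
#' @param trace an [run_chain()] result.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sampled trees as a NEXUS tree log
#' @param trace an [run_chain()] result produced with `log_trees = TRUE`.
#' @param path output file.
#' @export
write_tree_log <- function(trace, path) {
  if (is.null(trace$trees)) stop("trace has no sampled trees")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "Begin trees;"), con)
  for (i in seq_along(trace$trees))
    writeLines(sprintf("tree STATE_%d = %s",
                       as.integer(trace$samples$state[i]), trace$trees[i]), con)
  writeLines("End;", con)
  invisible(path)
}
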
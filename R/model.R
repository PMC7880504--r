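# Posterior components: HKY/JC tree likelihood by Felsenstein pruning over
# compressed site patterns (compiled kernel in src/likelihood.cpp), the Yule
# tree prior, and the hyperpriors of the relaxed-clock model.

#' Nucleotide alignment container
#'
#' @param labels taxon labels (length N).
#' @param data N x L integer matrix of codes: 1..4 = A,C,G,T, 0 = gap or
#'   ambiguity (treated as missing data in the likelihood).
#' @param partition integer vector of length L assigning each site to one of
#'   P partitions (default: one partition).
#' @return object of class `alignment` with fields `labels`, `data`,
#'   `partition`, `L`, `P`.
#' @export
alignment <- function(labels, data, partition = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (nrow(data) != length(labels)) stop("one row per taxon required")
  if (is.null(partition)) partition <- rep(1L, ncol(data))
  if (length(partition) != ncol(data)) stop("partition map must cover all sites")
  if (any(data < 0L | data > 4L)) stop("codes must lie in 0..4")
  structure(list(labels = labels, data = data,
                 partition = as.integer(partition),
                 L = ncol(data), P = max(as.integer(partition))),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$labels), "taxa,", x$L, "sites,", x$P,
      "partition(s)\n")
  invisible(x)
}

.nuc_codes <- c(a = 1L, c = 2L, g = 3L, t = 4L, u = 4L)

#' Read an aligned nucleotide FASTA file
#'
#' Characters other than ACGT/U (gaps, Ns, IUPAC ambiguities) become missing
#' data.  Partitions are given as 1-based inclusive site ranges.
#'
#' @param path FASTA file path.
#' @param partitions optional list of `c(from, to)` ranges covering all sites.
#' @return an [alignment()].
#' @export
read_fasta <- function(path, partitions = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- ape::read.FASTA(path)
  chr <- as.character(seqs)
  L <- unique(lengths(chr))
  if (length(L) != 1L) stop("sequences have unequal lengths; not an alignment")
  m <- do.call(rbind, lapply(chr, function(s) {
    code <- .nuc_codes[tolower(s)]
    code[is.na(code)] <- 0L
    code
  }))
  part <- rep(1L, L)
  if (!is.null(partitions)) {
    part <- rep(NA_integer_, L)
    for (i in seq_along(partitions)) {
      rg <- partitions[[i]]
      part[rg[1L]:rg[2L]] <- i
    }
    if (anyNA(part)) stop("partition ranges do not cover every site")
  }
  alignment(names(seqs), m, part)
}

#' Write an alignment to FASTA
#' @param aln an [alignment()].
#' @param path output file path.
#' @export
write_fasta <- function(aln, path) {
  letters <- c("-", "A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$labels)) {
    writeLines(paste0(">", aln$labels[i]), con)
    writeLines(paste(letters[aln$data[i, ] + 1L], collapse = ""), con)
  }
  invisible(path)
}

#' Compress alignment columns into unique site patterns
#'
#' @param aln an [alignment()].
#' @return a list with one entry per partition, each holding `pat`
#'   (N x n_patterns code matrix) and `w` (pattern weights); weights sum to
#'   the partition's site count.
#' @export
compress_site_patterns <- function(aln) {
  lapply(seq_len(aln$P), function(p) {
    cols <- which(aln$partition == p)
    sub <- aln$data[, cols, drop = FALSE]
    key <- apply(sub, 2L, paste, collapse = ",")
    w <- table(factor(key, levels = unique(key)))
    pat <- sub[, !duplicated(key), drop = FALSE]
    list(pat = pat, w = as.numeric(w))
  })
}

#' HKY transition probability matrix
#'
#' Matrix exponential of the frequency-normalised HKY rate matrix, evaluated
#' in closed form.  `d` is the branch length in expected substitutions per
#' site.  Base order A, C, G, T; rows are the parent state.
#'
#' @param d expected substitutions (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param freqs stationary base frequencies, summing to 1.
#' @return a 4 x 4 stochastic matrix.
#' @export
hky_transition_probs <- function(d, kappa, freqs) {
  if (d < 0) stop("negative branch distance")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  .cpp_hky_pmat(d, kappa, as.numeric(freqs))
}

#' Full MCMC state of the relaxed-clock phylogenetic model
#'
#' @param tree a [timetree()].
#' @param rates a [branch_rates()] (node-indexed, root entry `NA`).
#' @param sigma clock standard deviation (> 0).
#' @param subst list with one entry per partition, each a list with `kappa`,
#'   `freqs` (length-4 simplex) and `muC` (relative clock rate).
#' @param lambda Yule birth rate (> 0).
#' @param npieces `quant` piece count (default 100).
#' @return object of class `phylostate`.
#' @export
phylo_state <- function(tree, rates, sigma, subst, lambda, npieces = 100) {
  stopifnot(inherits(tree, "timetree"), inherits(rates, "branchrates"),
            sigma > 0, lambda > 0)
  structure(list(tree = tree, rates = rates, sigma = sigma, subst = subst,
                 lambda = lambda, npieces = npieces),
            class = "phylostate")
}

#' @export
print.phylostate <- function(x, ...) {
  cat("phylostate:", x$tree$N, "taxa, mode", x$rates$mode,
      sprintf("sigma=%.4g lambda=%.4g\n", x$sigma, x$lambda))
  invisible(x)
}

# Real branch rates of a state (node-indexed; root NA).
state_rates <- function(state) {
  branch_rate_values(state$rates, state$sigma, state$npieces)
}

#' Tree log likelihood under the relaxed clock
#'
#' Felsenstein pruning over compressed site patterns, summed over partitions.
#' The expected number of substitutions on the parental branch of node i is
#' `muC * r_i * tau_i` for the partition's relative clock rate muC.
#'
#' @param state a [phylo_state()].
#' @param aln an [alignment()]; taxon labels must match the tree's tips.
#' @param patterns optional precomputed [compress_site_patterns()] output.
#' @return log likelihood.
#' @export
tree_log_likelihood <- function(state, aln, patterns = NULL) {
  tr <- state$tree
  if (is.null(patterns)) patterns <- compress_site_patterns(aln)
  # pattern rows may be pre-permuted into tree tip order (chain hot path)
  preordered <- identical(attr(patterns, "tip_order"), tr$tip.label)
  if (!preordered && !setequal(tr$tip.label, aln$labels))
    stop("alignment taxa do not match tree tips")
  perm <- if (preordered) NULL else match(tr$tip.label, aln$labels)
  tau <- tt_branch_lengths(tr)
  r <- state_rates(state)
  ll <- 0
  for (p in seq_along(patterns)) {
    sp <- state$subst[[p]]
    d <- sp$muC * r * tau
    d[tr$root] <- 0
    pat <- if (preordered) patterns[[p]]$pat
           else patterns[[p]]$pat[perm, , drop = FALSE]
    ll <- ll + .cpp_hky_loglik(tr$child, tr$postorder, tr$root, d,
                               sp$kappa, as.numeric(sp$freqs), pat,
                               patterns[[p]]$w)
  }
  ll
}

#' Yule log prior on a time tree
#'
#' Labelled-history waiting-time form: going down from the root, each of the
#' k extant lineages splits independently at rate lambda, so the k-lineage
#' interval of duration w contributes `log(lambda) - k*lambda*w` plus the
#' 1/k splitter choice; for a fixed topology this collapses to
#' `(N-1)*log(lambda) - lambda * tree_length`.
#'
#' @param tr an ultrametric [timetree()].
#' @param lambda birth rate (> 0).
#' @return log density (up to a topology-only constant).
#' @export
yule_log_prior <- function(tr, lambda) {
  if (lambda <= 0) return(-Inf)
  if (!tt_is_ultrametric(tr)) stop("Yule prior requires an ultrametric tree")
  (tr$N - 1) * log(lambda) - lambda * tree_length(tr)
}

# log Dirichlet density
.ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-9) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Hyperprior settings (clock sd Gamma given as shape/scale).
.hyper <- list(
  sigma_shape = 0.5396, sigma_scale = 0.3819,
  kappa_meanlog = 1, kappa_sdlog = 1.25,
  freqs_alpha = c(10, 10, 10, 10),
  muC_meanlog = -0.18, muC_sdlog = 0.6,
  lambda_meanlog = 1, lambda_sdlog = 1.25)

#' Sum of hyperprior log densities of a state
#'
#' sigma ~ Gamma(0.5396, scale 0.3819); per partition kappa ~
#' Log-normal(1, 1.25), frequencies ~ Dirichlet(10,10,10,10), relative clock
#' rate muC ~ Log-normal(-0.18, 0.6); Yule birth rate lambda ~
#' Log-normal(1, 1.25).  Log-normal(a, b) means log-space mean a and sd b.
#'
#' @param state a [phylo_state()].
#' @return log density; `-Inf` outside the support.
#' @export
hyperprior_log_densities <- function(state) {
  h <- .hyper
  if (state$sigma <= 0 || state$lambda <= 0) return(-Inf)
  lp <- stats::dgamma(state$sigma, shape = h$sigma_shape,
                      scale = h$sigma_scale, log = TRUE) +
        stats::dlnorm(state$lambda, h$lambda_meanlog, h$lambda_sdlog,
                      log = TRUE)
  for (sp in state$subst) {
    if (sp$kappa <= 0 || sp$muC <= 0) return(-Inf)
    lp <- lp + stats::dlnorm(sp$kappa, h$kappa_meanlog, h$kappa_sdlog,
                             log = TRUE) +
          .ddirichlet_log(sp$freqs, h$freqs_alpha) +
          stats::dlnorm(sp$muC, h$muC_meanlog, h$muC_sdlog, log = TRUE)
  }
  lp
}

#' Log posterior density (unnormalised)
#'
#' Tree likelihood (omitted when `aln` is `NULL`: sampling the prior) plus
#' Yule tree prior, branch-rate prior given sigma (mode-dependent), and the
#' hyperpriors.
#'
#' @inheritParams tree_log_likelihood
#' @param aln an [alignment()] or `NULL` for prior-only runs.
#' @return list with `posterior`, `likelihood`, `prior` log densities.
#' @export
log_posterior_parts <- function(state, aln = NULL, patterns = NULL) {
  prior <- yule_log_prior(state$tree, state$lambda) +
           branch_rate_logprior(state$rates, state$sigma) +
           hyperprior_log_densities(state)
  lik <- if (is.null(aln)) 0 else {
    if (is.finite(prior)) tree_log_likelihood(state, aln, patterns) else -Inf
  }
  list(posterior = prior + lik, likelihood = lik, prior = prior)
}

#' @rdname log_posterior_parts
#' @export
log_posterior <- function(state, aln = NULL, patterns = NULL) {
  log_posterior_parts(state, aln, patterns)$posterior
}
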
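# Proposal step-size kernels and acceptance-rate auto-tuning.
#
# A kernel draws a symmetric, zero-mean deviate Sigma; proposals apply a step
# s * Sigma for the tunable scale s.  The Bactrian(m) kernel is the equal
# mixture Normal(-m, sd = sqrt(1 - m^2)) + Normal(+m, sd = sqrt(1 - m^2)),
# which has unit variance for any modality m; m = 0 recovers Normal(0, 1).

#' Create a step-size kernel
#'
#' @param family `"uniform"` (deviate ~ Uniform(-1, 1)) or `"bactrian"`.
#' @param m Bactrian modality in `[0, 1)` (default 0.95).
#' @param s initial tunable scale (> 0).
#' @param target target acceptance rate for auto-tuning; defaults to 0.234
#'   for uniform kernels and 0.3 for Bactrian kernels.
#' @return object of class `kernel`.
#' @export
kernel <- function(family = c("bactrian", "uniform"), m = 0.95, s = 1,
                   target = NULL) {
  family <- match.arg(family)
  if (family == "bactrian" && (m < 0 || m >= 1))
    stop("Bactrian modality m must lie in [0, 1)")
  if (is.null(target)) target <- if (family == "bactrian") 0.3 else 0.234
  structure(list(family = family, m = m, s = s, target = target,
                 batch_accept = 0L, batch_count = 0L, batch_index = 0L,
                 batch_size = 50L, frozen = FALSE),
            class = "kernel")
}

#' Draw one deviate from a Bactrian(m) kernel
#' @param m modality in `[0, 1)`.
#' @param n number of draws.
#' @return numeric draws with mean 0 and variance 1.
#' @export
bactrian_draw <- function(m, n = 1) {
  if (m < 0 || m >= 1) stop("Bactrian modality m must lie in [0, 1)")
  sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  sgn * m + stats::rnorm(n, 0, sqrt(1 - m^2))
}

# One deviate from a kernel (unscaled).
kernel_draw <- function(k) {
  switch(k$family,
         uniform  = stats::runif(1, -1, 1),
         bactrian = bactrian_draw(k$m, 1))
}

#' Diminishing-adaptation update of a kernel's scale
#'
#' Robbins-Monro style batch update: after each batch of proposals,
#' `log s <- log s + (observed rate - target) / sqrt(batch index)`.
#' Updates stop once the kernel is frozen (see [run_chain()]: tuning is
#' frozen when the adaptive sampler's learn-in phase ends).
#'
#' @param k a [kernel()].
#' @param accepted,proposed counts since the last update (typically 0/1 per
#'   call; batching is internal).
#' @return the updated kernel.
#' @export
tune_scale <- function(k, accepted, proposed) {
  if (proposed <= 0) stop("proposed count must be positive")
  if (k$frozen) return(k)
  k$batch_accept <- k$batch_accept + accepted
  k$batch_count <- k$batch_count + proposed
  if (k$batch_count >= k$batch_size) {
    k$batch_index <- k$batch_index + 1L
    rate <- k$batch_accept / k$batch_count
    k$s <- exp(log(k$s) + (rate - k$target) / sqrt(k$batch_index))
    k$batch_accept <- 0L
    k$batch_count <- 0L
  }
  k
}
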
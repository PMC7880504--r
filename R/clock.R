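# The uncorrelated log-normal relaxed clock: branch rates are iid
# Log-normal(mu = -0.5 sigma^2, sigma) so that the prior mean rate is 1.
# Three parameterisations of the branch-rate vector are supported:
#   real  - the rates themselves (positive reals),
#   cat   - integer bin indices 0..n-1 into an n-bin discretisation,
#   quant - rate quantiles in (0,1), mapped through a piecewise i-CDF.

#' Log-normal clock model
#'
#' @param sigma clock standard deviation (log-space, dimensionless, > 0).
#' @param npieces number of pieces in the `quant` i-CDF approximation.
#' @return object of class `clockmodel` with `sigma`, `meanlog = -sigma^2/2`.
#' @export
clock_model <- function(sigma, npieces = 100) {
  stopifnot(sigma > 0, npieces >= 2)
  structure(list(sigma = sigma, meanlog = -0.5 * sigma^2, npieces = npieces),
            class = "clockmodel")
}

#' Branch-rate vector container
#'
#' Values are indexed by node (1..2N-1) with the root entry `NA`: every
#' non-root node carries the rate (or abstraction) of its parental branch,
#' giving the 2N-2 relaxed-clock dimensions.
#'
#' @param values numeric vector, length 2N-1, root entry `NA`.
#' @param mode one of `"real"`, `"cat"`, `"quant"`.
#' @param ncat category count for `cat` (default 2N-2).
#' @export
branch_rates <- function(values, mode = c("real", "cat", "quant"), ncat = NULL) {
  mode <- match.arg(mode)
  n <- sum(!is.na(values))
  if (mode == "cat" && is.null(ncat)) ncat <- n
  v <- values[!is.na(values)]
  if (mode == "real" && any(v <= 0)) stop("real rates must be positive")
  if (mode == "quant" && any(v <= 0 | v >= 1)) stop("quantiles must lie in (0,1)")
  if (mode == "cat" && any(v != floor(v) | v < 0 | v >= ncat))
    stop("categories must be integers in 0..n-1")
  structure(list(values = values, mode = mode, ncat = ncat),
            class = "branchrates")
}

#' Identity transform of the real parameterisation
#' @param R a [branch_rates()] with mode `"real"`.
#' @return the rate vector (same indexing).
#' @export
real_rates <- function(R) {
  if (R$mode != "real") stop("real_rates applies to mode 'real'")
  R$values
}

#' Log density of a branch rate under the mean-one log-normal clock prior
#' @param r rate(s), positive.
#' @param sigma clock standard deviation.
#' @return log density; `-Inf` for non-positive rates.
#' @export
lognormal_rate_logpdf <- function(r, sigma) {
  out <- rep(-Inf, length(r))
  ok <- r > 0
  out[ok] <- stats::dlnorm(r[ok], meanlog = -0.5 * sigma^2, sdlog = sigma,
                           log = TRUE)
  out
}

#' Rate of a discrete clock category
#'
#' Bin `i` (0-based) of an `n`-bin discretisation takes the median rate of its
#' bin: the `(i + 0.5)/n` quantile of the underlying log-normal.
#'
#' @param i 0-based bin index (vectorised).
#' @param n bin count.
#' @param sigma clock standard deviation.
#' @export
cat_rate <- function(i, n, sigma) {
  if (any(i < 0 | i >= n | i != floor(i))) stop("category index out of range 0..n-1")
  stats::qlnorm((i + 0.5) / n, meanlog = -0.5 * sigma^2, sdlog = sigma)
}

# Knot table for the piecewise quantile map at a given sigma: exact i-CDF
# values at q = 1/np, 2/np, ..., (np-1)/np.  The first and final pieces use
# the exact i-CDF; interior pieces interpolate linearly in rate space.
quant_knots <- function(sigma, npieces = 100) {
  q <- seq_len(npieces - 1L) / npieces
  list(q = q, r = stats::qlnorm(q, -0.5 * sigma^2, sigma), np = npieces,
       sigma = sigma)
}

#' Piecewise-approximate i-CDF mapping rate quantiles to rates
#'
#' The unit interval is split into `npieces` equal-width pieces.  The first
#' and final pieces evaluate the exact log-normal i-CDF; interior pieces use
#' linear interpolation between the exact knot values.
#'
#' @param q quantile(s) strictly in (0,1).
#' @param sigma clock standard deviation.
#' @param npieces piece count (default 100).
#' @export
quant_rate <- function(q, sigma, npieces = 100) {
  if (any(q <= 0 | q >= 1)) stop("quantile outside (0,1)")
  kn <- quant_knots(sigma, npieces)
  .quant_rate_kn(q, kn)
}

.quant_rate_kn <- function(q, kn) {
  np <- kn$np
  out <- numeric(length(q))
  j <- floor(q * np)            # piece index 0..np-1
  edge <- j == 0L | j == np - 1L
  if (any(edge))
    out[edge] <- stats::qlnorm(q[edge], -0.5 * kn$sigma^2, kn$sigma)
  if (any(!edge)) {
    ji <- j[!edge]
    lo <- kn$r[ji]; hi <- kn$r[ji + 1L]
    w <- q[!edge] * np - ji
    out[!edge] <- lo + w * (hi - lo)
  }
  out
}

# d r / d q of the piecewise map (needed for quant-mode Jacobians).
.quant_rate_deriv_kn <- function(q, kn) {
  np <- kn$np
  out <- numeric(length(q))
  j <- floor(q * np)
  edge <- j == 0L | j == np - 1L
  if (any(edge)) {
    r <- stats::qlnorm(q[edge], -0.5 * kn$sigma^2, kn$sigma)
    out[edge] <- 1 / stats::dlnorm(r, -0.5 * kn$sigma^2, kn$sigma)
  }
  if (any(!edge)) {
    ji <- j[!edge]
    out[!edge] <- (kn$r[ji + 1L] - kn$r[ji]) * np
  }
  out
}

#' Derivative of the piecewise quantile-to-rate map
#' @inheritParams quant_rate
#' @export
quant_rate_deriv <- function(q, sigma, npieces = 100) {
  if (any(q <= 0 | q >= 1)) stop("quantile outside (0,1)")
  .quant_rate_deriv_kn(q, quant_knots(sigma, npieces))
}

# Exact functional inverse of the piecewise map (rate -> quantile), so that
# composing the two is the identity and operators built on them are exactly
# reversible.
.quant_from_rate_kn <- function(r, kn) {
  np <- kn$np
  out <- numeric(length(r))
  lo1 <- kn$r[1L]; hiL <- kn$r[np - 1L]
  edge <- r < lo1 | r > hiL
  if (any(edge))
    out[edge] <- stats::plnorm(r[edge], -0.5 * kn$sigma^2, kn$sigma)
  if (any(!edge)) {
    ri <- r[!edge]
    ji <- findInterval(ri, kn$r, rightmost.closed = TRUE)
    ji <- pmin(pmax(ji, 1L), np - 2L)
    lo <- kn$r[ji]; hi <- kn$r[ji + 1L]
    out[!edge] <- (ji + (ri - lo) / (hi - lo)) / np
  }
  out
}

#' Inverse of the piecewise quantile map (rate to quantile)
#' @param r positive rate(s).
#' @inheritParams quant_rate
#' @export
quant_from_rate <- function(r, sigma, npieces = 100) {
  if (any(r <= 0)) stop("rate must be positive")
  .quant_from_rate_kn(r, quant_knots(sigma, npieces))
}

#' Transform a branch-rate abstraction into real rates
#'
#' @param R a [branch_rates()].
#' @param sigma clock standard deviation.
#' @param npieces `quant` piece count.
#' @return rate vector with the same node indexing (root entry `NA`).
#' @export
branch_rate_values <- function(R, sigma, npieces = 100) {
  v <- R$values
  ok <- !is.na(v)
  out <- v
  out[ok] <- switch(R$mode,
    real  = v[ok],
    cat   = cat_rate(v[ok], R$ncat, sigma),
    quant = quant_rate(v[ok], sigma, npieces))
  out
}

# Log prior density of the abstraction vector given sigma.
branch_rate_logprior <- function(R, sigma) {
  v <- R$values[!is.na(R$values)]
  switch(R$mode,
    real  = sum(lognormal_rate_logpdf(v, sigma)),
    cat   = -length(v) * log(R$ncat),
    quant = if (all(v > 0 & v < 1)) 0 else -Inf)
}
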
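# Exact multivariate polynomial arithmetic over the ten symbols used by the
# narrow-exchange-rate constraint systems:
#   t_A, t_B, t_C, t_D, t_E, t'_D, r_A, r_B, r_C, r_D
# Coefficients remain integers under all operations used here (the constraint
# systems have unit coefficients and elimination is fraction-free), so double
# storage is exact and identity checks are exact.
#
# A polynomial is a list(coef = numeric k, expo = integer k x 10 matrix).
# The zero polynomial has k = 0.

.ner_vars <- c("tA", "tB", "tC", "tD", "tE", "tDp", "rA", "rB", "rC", "rD")
.NV <- 10L

p_zero <- function() list(coef = numeric(0), expo = matrix(0L, 0L, .NV))

p_const <- function(c) {
  if (c == 0) return(p_zero())
  list(coef = c, expo = matrix(0L, 1L, .NV))
}

p_var <- function(name) {
  i <- match(name, .ner_vars)
  if (is.na(i)) stop("unknown symbol: ", name)
  e <- matrix(0L, 1L, .NV)
  e[1L, i] <- 1L
  list(coef = 1, expo = e)
}

# Combine duplicate monomials and drop zero coefficients.  Monomials are
# keyed by an exact base-32 encoding of the exponent vector (exponents in the
# constraint systems stay far below 32, and 32^10 < 2^53, so keys are exact).
.p_key_base <- 32^(0:(10 - 1))

p_canon <- function(p) {
  k <- length(p$coef)
  if (k == 0L) return(p)
  if (any(p$expo >= 32L)) stop("monomial degree overflow")
  key <- c(p$expo %*% .p_key_base)
  coef <- rowsum(p$coef, key, reorder = FALSE)[, 1L]
  expo <- p$expo[!duplicated(key), , drop = FALSE]
  keep <- coef != 0
  list(coef = unname(coef[keep]), expo = expo[keep, , drop = FALSE])
}

p_add <- function(a, b) {
  p_canon(list(coef = c(a$coef, b$coef), expo = rbind(a$expo, b$expo)))
}

p_neg <- function(a) list(coef = -a$coef, expo = a$expo)

p_sub <- function(a, b) p_add(a, p_neg(b))

p_mul <- function(a, b) {
  ka <- length(a$coef); kb <- length(b$coef)
  if (ka == 0L || kb == 0L) return(p_zero())
  ia <- rep(seq_len(ka), each = kb)
  ib <- rep(seq_len(kb), times = ka)
  p_canon(list(coef = a$coef[ia] * b$coef[ib],
               expo = a$expo[ia, , drop = FALSE] + b$expo[ib, , drop = FALSE]))
}

p_scale <- function(a, c) {
  if (c == 0) return(p_zero())
  list(coef = a$coef * c, expo = a$expo)
}

p_deriv <- function(a, name) {
  i <- match(name, .ner_vars)
  k <- length(a$coef)
  if (k == 0L) return(p_zero())
  e <- a$expo[, i]
  keep <- e > 0L
  if (!any(keep)) return(p_zero())
  coef <- a$coef[keep] * e[keep]
  expo <- a$expo[keep, , drop = FALSE]
  expo[, i] <- expo[, i] - 1L
  p_canon(list(coef = coef, expo = expo))
}

p_is_zero <- function(a) length(p_canon(a)$coef) == 0L

# Evaluate at a named numeric vector over .ner_vars.
p_eval <- function(a, vals) {
  k <- length(a$coef)
  if (k == 0L) return(0)
  v <- vals[.ner_vars]
  m <- a$coef
  for (j in seq_len(.NV)) {
    e <- a$expo[, j]
    if (any(e > 0L)) m <- m * v[[j]]^e
  }
  sum(m)
}

# Largest total degree; used only for sanity reporting.
p_degree <- function(a) if (length(a$coef) == 0L) -Inf else max(rowSums(a$expo))

# Render as a human-readable string (census reports).
p_format <- function(a) {
  a <- p_canon(a)
  k <- length(a$coef)
  if (k == 0L) return("0")
  terms <- vapply(seq_len(k), function(i) {
    e <- a$expo[i, ]
    vars <- .ner_vars[e > 0L]
    pow <- e[e > 0L]
    sym <- paste(ifelse(pow > 1L, paste0(vars, "^", pow), vars), collapse = "*")
    cf <- a$coef[i]
    if (sym == "") as.character(cf)
    else if (cf == 1) sym
    else if (cf == -1) paste0("-", sym)
    else paste0(cf, "*", sym)
  }, character(1))
  out <- terms[1L]
  for (t in terms[-1L]) {
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2L))
           else paste0(out, " + ", t)
  }
  out
}

# ---- rational functions p/q --------------------------------------------------

rat <- function(num, den = p_const(1)) list(num = num, den = den)

rat_from_poly <- function(p) rat(p)

rat_add <- function(a, b) {
  rat(p_add(p_mul(a$num, b$den), p_mul(b$num, a$den)), p_mul(a$den, b$den))
}

rat_neg <- function(a) rat(p_neg(a$num), a$den)

rat_sub <- function(a, b) rat_add(a, rat_neg(b))

rat_mul <- function(a, b) rat(p_mul(a$num, b$num), p_mul(a$den, b$den))

rat_mul_poly <- function(a, p) rat(p_mul(a$num, p), a$den)

rat_div_poly <- function(a, p) rat(a$num, p_mul(a$den, p))

rat_is_zero <- function(a) p_is_zero(a$num)

rat_eval <- function(a, vals) p_eval(a$num, vals) / p_eval(a$den, vals)

rat_format <- function(a) {
  den <- p_canon(a$den)
  if (length(den$coef) == 1L && all(den$expo == 0L) && den$coef == 1)
    p_format(a$num)
  else paste0("(", p_format(a$num), ") / (", p_format(den), ")")
}
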
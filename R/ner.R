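# Narrow-exchange and narrow-exchange-rate (NER) operators.
#
# A narrow exchange relocates an uncle branch so that a nephew and uncle swap
# places (heights unchanged; always RF distance 1).  NER variants additionally
# propose the four incident branch rates so that a chosen subset of the six
# pairwise genetic-distance constraints D_ij between nodes A, B, C, E is
# conserved.  The constraint systems are linear in the proposed rates; they
# are solved exactly, once per session, by the in-package symbolic engine
# (R/poly.R), which also derives each solution's Jacobian determinant.
#
# Node labelling, before -> after:
#   before: E has children D (taller) and C; D has children A and B
#   after:  E has children D and A; D has children B and C

.ner_names <- c("DAB", "DAC", "DAE", "DBC", "DBE", "DCE")

.pd <- function(a, b) p_sub(p_var(a), p_var(b))
.pm <- function(r, d) p_mul(p_var(r), d)

# The six constraint equations, each A.x = b with x = (r'_A, r'_B, r'_C, r'_D):
# coefficient polynomials in the heights, right-hand side the pre-move
# genetic-distance path.
ner_equations <- function() {
  z <- p_zero()
  eq <- function(cA, cB, cC, cD, rhs) list(A = list(cA, cB, cC, cD), rhs = rhs)
  list(
    DAB = eq(.pd("tE", "tA"), .pd("tDp", "tB"), z, .pd("tE", "tDp"),
             p_add(.pm("rA", .pd("tD", "tA")), .pm("rB", .pd("tD", "tB")))),
    DAC = eq(.pd("tE", "tA"), z, .pd("tDp", "tC"), .pd("tE", "tDp"),
             p_add(p_add(.pm("rA", .pd("tD", "tA")), .pm("rD", .pd("tE", "tD"))),
                   .pm("rC", .pd("tE", "tC")))),
    DAE = eq(.pd("tE", "tA"), z, z, z,
             p_add(.pm("rA", .pd("tD", "tA")), .pm("rD", .pd("tE", "tD")))),
    DBC = eq(z, .pd("tDp", "tB"), .pd("tDp", "tC"), z,
             p_add(p_add(.pm("rB", .pd("tD", "tB")), .pm("rD", .pd("tE", "tD"))),
                   .pm("rC", .pd("tE", "tC")))),
    DBE = eq(z, .pd("tDp", "tB"), z, .pd("tE", "tDp"),
             p_add(.pm("rB", .pd("tD", "tB")), .pm("rD", .pd("tE", "tD")))),
    DCE = eq(z, z, .pd("tDp", "tC"), .pd("tE", "tDp"),
             .pm("rC", .pd("tE", "tC")))
  )
}

#' Enumerate all subsets of the six distance constraints
#'
#' @return a list of 64 character vectors in canonical order (by size, then
#'   lexicographically in the fixed constraint ordering DAB..DCE).
#' @export
enumerate_constraint_sets <- function() {
  out <- list(character(0))
  for (k in 1:6)
    out <- c(out, utils::combn(.ner_names, k, simplify = FALSE))
  out
}

ner_label <- function(S) paste0("NER{", paste(S, collapse = ","), "}")

#' Solve one NER constraint subset symbolically
#'
#' Performs exact fraction-free Gauss-Jordan elimination of the linear system
#' in the four proposed rates (coefficients are polynomials in the node
#' heights), with the convention that unconstrained rates keep their current
#' values.  A subset is `unsolvable` when elimination leaves a residual that
#' is not identically zero (the system is inconsistent for generic inputs),
#' and `zero-jacobian` when the determinant of the proposal map's Jacobian
#' (the 4x4 block of d r'_i / d r_j; the height row of the full 5x5 matrix
#' is (0,0,0,0,1)) vanishes identically.
#'
#' @param S character vector of constraint names (subset of DAB..DCE).
#' @return object of class `ner_solution`: `constraints`, `status` (one of
#'   `"unsolvable"`, `"zero-jacobian"`, `"valid"`), `exprs` (four rational
#'   functions for r'_A..r'_D) and `jac` (rational Jacobian determinant).
#' @export
solve_constraint_set <- function(S) {
  stopifnot(all(S %in% .ner_names))
  S <- .ner_names[.ner_names %in% S]
  eqs <- ner_equations()[S]
  rows <- lapply(eqs, function(e) e)
  nr <- length(rows)
  pivot_row <- rep(NA_integer_, 4L)   # pivot row for each unknown column
  used <- logical(nr)
  for (col in 1:4) {
    pr <- NA_integer_
    for (i in seq_len(nr)) {
      if (!used[i] && !p_is_zero(rows[[i]]$A[[col]])) { pr <- i; break }
    }
    if (is.na(pr)) next
    used[pr] <- TRUE
    pivot_row[col] <- pr
    piv <- rows[[pr]]$A[[col]]
    for (j in seq_len(nr)) {
      if (j == pr) next
      a <- rows[[j]]$A[[col]]
      if (p_is_zero(a)) next
      rows[[j]]$A <- lapply(1:4, function(c2)
        p_sub(p_mul(rows[[j]]$A[[c2]], piv), p_mul(rows[[pr]]$A[[c2]], a)))
      rows[[j]]$rhs <- p_sub(p_mul(rows[[j]]$rhs, piv), p_mul(rows[[pr]]$rhs, a))
    }
  }
  # rows never used as pivots must have reduced to 0 = 0
  for (i in seq_len(nr)) {
    if (used[i]) next
    if (!all(vapply(rows[[i]]$A, p_is_zero, logical(1))))
      stop("internal error: unpivoted row with nonzero coefficients")
    if (!p_is_zero(rows[[i]]$rhs))
      return(structure(list(constraints = S, label = ner_label(S),
                            status = "unsolvable", exprs = NULL, jac = NULL),
                       class = "ner_solution"))
  }
  rvars <- c("rA", "rB", "rC", "rD")
  exprs <- lapply(rvars, function(v) rat(p_var(v)))   # free: keep current rate
  for (col in 1:4) {
    pr <- pivot_row[col]
    if (is.na(pr)) next
    num <- rows[[pr]]$rhs
    for (f in setdiff(1:4, col)) {
      cf <- rows[[pr]]$A[[f]]
      if (!p_is_zero(cf)) {
        if (!is.na(pivot_row[f]))
          stop("internal error: residual pivot-column entry after elimination")
        num <- p_sub(num, p_mul(cf, p_var(rvars[f])))
      }
    }
    exprs[[col]] <- rat(num, rows[[pr]]$A[[col]])
  }
  names(exprs) <- c("rpA", "rpB", "rpC", "rpD")
  # Jacobian: solutions are linear in the current rates with height-only
  # denominators, so det(dr'/dr) = det(d num / d r) / prod(denominators).
  Mnum <- lapply(1:4, function(i)
    lapply(rvars, function(v) p_deriv(exprs[[i]]$num, v)))
  detnum <- .p_det(Mnum)
  den <- Reduce(p_mul, lapply(exprs, `[[`, "den"))
  status <- if (p_is_zero(detnum)) "zero-jacobian" else "valid"
  structure(list(constraints = S, label = ner_label(S), status = status,
                 exprs = exprs, jac = rat(detnum, den)),
            class = "ner_solution")
}

#' @export
print.ner_solution <- function(x, ...) {
  cat(x$label, "-", x$status, "\n")
  if (!is.null(x$exprs)) {
    for (nm in names(x$exprs)) cat(" ", nm, "=", rat_format(x$exprs[[nm]]), "\n")
    cat("  |J| =", rat_format(x$jac), "\n")
  }
  invisible(x)
}

# determinant of a k x k matrix of polynomials (cofactor expansion)
.p_det <- function(M) {
  k <- length(M)
  if (k == 1L) return(M[[1L]][[1L]])
  acc <- p_zero()
  for (j in seq_len(k)) {
    a <- M[[1L]][[j]]
    if (p_is_zero(a)) next
    minor <- lapply(M[-1L], function(row) row[-j])
    term <- p_mul(a, .p_det(minor))
    acc <- if (j %% 2L == 1L) p_add(acc, term) else p_sub(acc, term)
  }
  acc
}

#' Verify a NER solution symbolically
#'
#' Substitutes the cached rational-function solutions back into each claimed
#' constraint equation and checks that the residual numerator simplifies to
#' the identically zero polynomial (exact integer arithmetic).
#'
#' @param sol a solvable [solve_constraint_set()] result.
#' @return `TRUE` when every constraint residual vanishes identically.
#' @export
ner_verify_solution <- function(sol) {
  if (sol$status == "unsolvable") stop(sol$label, " has no generic solution")
  eqs <- ner_equations()[sol$constraints]
  dens <- lapply(sol$exprs, `[[`, "den")
  den_all <- Reduce(p_mul, dens, p_const(1))
  for (e in eqs) {
    # residual * prod(dens) = sum_c A_c * num_c * prod(dens[-c]) - b * prod(dens)
    acc <- p_neg(p_mul(e$rhs, den_all))
    for (cc in 1:4) {
      if (p_is_zero(e$A[[cc]])) next
      term <- p_mul(e$A[[cc]], sol$exprs[[cc]]$num)
      for (c2 in setdiff(1:4, cc)) term <- p_mul(term, dens[[c2]])
      acc <- p_add(acc, term)
    }
    if (!p_is_zero(acc)) return(FALSE)
  }
  TRUE
}

# session cache: all 64 solutions, computed once
.ner_cache <- new.env(parent = emptyenv())

#' All 64 NER constraint-subset solutions (cached)
#' @return named list of [solve_constraint_set()] results in canonical order.
#' @export
ner_solutions <- function() {
  if (is.null(.ner_cache$solutions)) {
    sets <- enumerate_constraint_sets()
    sols <- lapply(sets, solve_constraint_set)
    names(sols) <- vapply(sols, `[[`, character(1), "label")
    .ner_cache$solutions <- sols
  }
  .ner_cache$solutions
}

#' Census of the NER operator family
#'
#' Enumerates all 64 constraint subsets, solves each, and tabulates the
#' counts: solvable systems, solvable systems with identically zero Jacobian,
#' valid operators, and total NER/NERw variants (each valid subset with and
#' without the t_D random walk).
#'
#' @return list with `counts` and a per-subset `table` data frame.
#' @export
classify_all_solutions <- function() {
  sols <- ner_solutions()
  status <- vapply(sols, `[[`, character(1), "status")
  counts <- list(
    total = length(sols),
    solvable = sum(status != "unsolvable"),
    zero_jacobian = sum(status == "zero-jacobian"),
    valid = sum(status == "valid"),
    variants = 2L * sum(status == "valid"),
    variants_excluding_null = 2L * sum(status == "valid") - 2L)
  tab <- data.frame(
    label = names(sols),
    size = vapply(sols, function(s) length(s$constraints), integer(1)),
    status = status,
    jacobian = vapply(sols, function(s)
      if (is.null(s$jac)) NA_character_ else rat_format(s$jac), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, table = tab)
}

# numeric evaluation of a solution at named heights/rates ---------------------

# Instantiate the constraint equations at numeric heights/rates: coefficient
# matrix A (k x 4), right-hand side b (k), and its rate gradient Br (k x 4).
ner_eq_numeric <- function(S, v) {
  row <- function(nm) switch(nm,
    DAB = list(A = c(v[["tE"]] - v[["tA"]], v[["tDp"]] - v[["tB"]], 0,
                     v[["tE"]] - v[["tDp"]]),
               Br = c(v[["tD"]] - v[["tA"]], v[["tD"]] - v[["tB"]], 0, 0)),
    DAC = list(A = c(v[["tE"]] - v[["tA"]], 0, v[["tDp"]] - v[["tC"]],
                     v[["tE"]] - v[["tDp"]]),
               Br = c(v[["tD"]] - v[["tA"]], 0, v[["tE"]] - v[["tC"]],
                      v[["tE"]] - v[["tD"]])),
    DAE = list(A = c(v[["tE"]] - v[["tA"]], 0, 0, 0),
               Br = c(v[["tD"]] - v[["tA"]], 0, 0, v[["tE"]] - v[["tD"]])),
    DBC = list(A = c(0, v[["tDp"]] - v[["tB"]], v[["tDp"]] - v[["tC"]], 0),
               Br = c(0, v[["tD"]] - v[["tB"]], v[["tE"]] - v[["tC"]],
                      v[["tE"]] - v[["tD"]])),
    DBE = list(A = c(0, v[["tDp"]] - v[["tB"]], 0, v[["tE"]] - v[["tDp"]]),
               Br = c(0, v[["tD"]] - v[["tB"]], 0, v[["tE"]] - v[["tD"]])),
    DCE = list(A = c(0, 0, v[["tDp"]] - v[["tC"]], v[["tE"]] - v[["tDp"]]),
               Br = c(0, 0, v[["tE"]] - v[["tC"]], 0)))
  rows <- lapply(S, row)
  r <- v[c("rA", "rB", "rC", "rD")]
  A <- do.call(rbind, lapply(rows, `[[`, "A"))
  Br <- do.call(rbind, lapply(rows, `[[`, "Br"))
  list(A = A, b = drop(Br %*% r), Br = Br)
}

# Structured numeric solve mirroring the symbolic elimination: Gauss-Jordan
# with column preference A,B,C,D, first-nonzero pivot rows, free rates kept
# at their current values.  Returns the proposed rates and the 4x4 rate map
# M = d r' / d r whose determinant is the Jacobian.
ner_solve_numeric <- function(S, vals) {
  r <- vals[c("rA", "rB", "rC", "rD")]
  if (!length(S))
    return(list(rates = stats::setNames(unname(r),
                                        c("rpA", "rpB", "rpC", "rpD")),
                M = diag(4)))
  eq <- ner_eq_numeric(S, vals)
  A <- eq$A; b <- eq$b; Br <- eq$Br
  k <- nrow(A)
  scale <- max(abs(A))
  used <- logical(k)
  pivot <- rep(NA_integer_, 4L)
  for (col in 1:4) {
    pr <- which(!used & abs(A[, col]) > 1e-10 * scale)[1L]
    if (is.na(pr)) next
    used[pr] <- TRUE
    pivot[col] <- pr
    for (j in seq_len(k)) {
      if (j == pr || A[j, col] == 0) next
      f <- A[j, col] / A[pr, col]
      A[j, ] <- A[j, ] - f * A[pr, ]
      b[j] <- b[j] - f * b[pr]
      Br[j, ] <- Br[j, ] - f * Br[pr, ]
    }
  }
  x <- unname(r)
  M <- diag(4)
  free <- which(is.na(pivot))
  for (col in which(!is.na(pivot))) {
    pr <- pivot[col]
    num <- b[pr]
    g <- Br[pr, ]
    for (f in free) {
      if (A[pr, f] != 0) {
        num <- num - A[pr, f] * r[[f]]
        g[f] <- g[f] - A[pr, f]
      }
    }
    x[col] <- num / A[pr, col]
    M[col, ] <- g / A[pr, col]
  }
  list(rates = stats::setNames(x, c("rpA", "rpB", "rpC", "rpD")), M = M)
}

#' Evaluate a NER solution numerically
#'
#' The default path instantiates the constraint system at the given heights
#' and rates and solves it directly (numerically exact; same pivot and
#' free-variable convention as the symbolic solver); `method = "symbolic"`
#' evaluates the cached closed-form expressions instead, which serves as the
#' cross-validation route.
#'
#' @param sol a valid [solve_constraint_set()] result.
#' @param vals named vector with `tA,tB,tC,tD,tE,tDp,rA,rB,rC,rD`.
#' @param method `"numeric"` (default) or `"symbolic"`.
#' @return list with `rates` (r'_A..r'_D) and `jac` (the signed determinant
#'   of the rate map; proposals use its absolute value).
#' @export
ner_evaluate <- function(sol, vals, method = c("numeric", "symbolic")) {
  method <- match.arg(method)
  if (sol$status == "unsolvable") stop(sol$label, " has no generic solution")
  if (method == "symbolic") {
    rates <- vapply(sol$exprs, rat_eval, numeric(1), vals = vals)
    names(rates) <- c("rpA", "rpB", "rpC", "rpD")
    return(list(rates = rates, jac = rat_eval(sol$jac, vals)))
  }
  ns <- ner_solve_numeric(sol$constraints, vals)
  list(rates = ns$rates, jac = det(ns$M))
}

# topology move ----------------------------------------------------------------

#' Sample a narrow-exchange configuration from a tree
#'
#' Samples a grandparent node E uniformly among internal nodes with at least
#' one internal child, takes D as E's taller child and C as its sibling,
#' rejects if D is a leaf or the child heights tie, and labels D's children
#' A and B at random.
#'
#' @param tr a [timetree()].
#' @return list with node indices `E`, `D`, `C`, `A`, `B`, or `NULL` on
#'   rejection.
#' @export
narrow_exchange_topology <- function(tr) {
  if (tr$N < 3L) return(NULL)
  internals <- (tr$N + 1L):tr$nnode
  eligible <- internals[tr$child[1L, internals] > tr$N |
                        tr$child[2L, internals] > tr$N]
  if (!length(eligible)) return(NULL)
  E <- eligible[sample.int(length(eligible), 1L)]
  ch <- tr$child[, E]
  h <- tr$height[ch]
  if (h[1L] == h[2L]) return(NULL)                 # degenerate tie
  D <- ch[which.max(h)]; C <- ch[which.min(h)]
  if (D <= tr$N) return(NULL)                      # taller child is a leaf
  AB <- tr$child[, D]
  if (stats::runif(1) < 0.5) AB <- rev(AB)
  list(E = E, D = D, C = C, A = AB[1L], B = AB[2L])
}

# Apply the branch relocation: A and C exchange parents.
ner_apply_topology <- function(tr, sel) {
  tr$parent[sel$A] <- sel$E
  tr$parent[sel$C] <- sel$D
  tr$child[, sel$D] <- c(sel$B, sel$C)
  tr$child[, sel$E] <- c(sel$D, sel$A)
  tr$postorder <- tt_postorder(tr)
  tr
}

#' Propose a narrow-exchange-rate move
#'
#' Executes the topology relocation, optionally embarks t_D on a random walk
#' (NERw), evaluates the cached rate solution for constraint subset `S`, and
#' returns the proposal with its log Jacobian.  Rejections: no eligible
#' configuration, any proposed rate non-positive, or
#' `t'_D` outside `(max(t_B, t_C), t_E)`.
#'
#' @param state a [phylo_state()] with mode `real` or `quant`.
#' @param sol a [solve_constraint_set()] result (or constraint subset vector).
#' @param walk optional [kernel()]: when supplied, `t'_D = t_D + s*Sigma`.
#' @return a proposal (see operators).
#' @export
ner_propose <- function(state, sol, walk = NULL) {
  if (is.character(sol)) sol <- ner_solutions()[[ner_label(sol)]]
  if (sol$status != "valid") stop(sol$label, " is not a valid operator")
  if (length(sol$constraints) && !state$rates$mode %in% c("real", "quant"))
    stop("NER rate updates apply to the real and quant parameterisations")
  tr <- state$tree
  sel <- narrow_exchange_topology(tr)
  if (is.null(sel)) return(propose_reject())
  nodes <- c(sel$A, sel$B, sel$C, sel$D)
  tD <- tr$height[sel$D]
  tDp <- if (is.null(walk)) tD else tD + walk$s * kernel_draw(walk)
  if (tDp <= max(tr$height[c(sel$B, sel$C)]) || tDp >= tr$height[sel$E])
    return(propose_reject())
  if (!length(sol$constraints)) {
    # null operator: pure branch rearrangement, |J| = 1
    state$tree <- ner_apply_topology(tr, sel)
    state$tree$height[sel$D] <- tDp
    return(propose_ok(state))
  }
  vals <- c(tA = tr$height[sel$A], tB = tr$height[sel$B],
            tC = tr$height[sel$C], tD = tD, tE = tr$height[sel$E], tDp = tDp)
  quant <- state$rates$mode == "quant"
  kn <- if (quant) state_knots(state) else NULL
  cur <- state$rates$values[nodes]
  r <- if (quant) .quant_rate_kn(cur, kn) else cur
  vals <- c(vals, rA = r[1L], rB = r[2L], rC = r[3L], rD = r[4L])
  ev <- ner_evaluate(sol, vals)
  if (any(ev$rates <= 0) || !is.finite(ev$jac) || ev$jac == 0)
    return(propose_reject())
  ev$jac <- abs(ev$jac)   # Green ratio uses |det J|
  if (quant) {
    qp <- .quant_from_rate_kn(ev$rates, kn)
    if (any(qp <= 0 | qp >= 1)) return(propose_reject())
    ljac <- log(ev$jac) + sum(log(.quant_rate_deriv_kn(cur, kn))) -
            sum(log(.quant_rate_deriv_kn(qp, kn)))
    state$rates$values[nodes] <- qp
  } else {
    ljac <- log(ev$jac)
    state$rates$values[nodes] <- ev$rates
  }
  state$tree <- ner_apply_topology(tr, sel)
  state$tree$height[sel$D] <- tDp
  propose_ok(state, log_jac = ljac)
}

#' NER operator constructor
#'
#' @param S constraint subset (character vector; empty = classic narrow
#'   exchange, which leaves all rates unchanged and has |J| = 1).
#' @param walk `TRUE` for the NERw variant (random walk on t_D).
#' @param kern kernel used for the NERw walk.
#' @export
op_ner <- function(S = character(0), walk = FALSE, kern = kernel(s = 0.05)) {
  label <- if (walk) sub("^NER", "NERw", ner_label(S)) else ner_label(S)
  propose <- function(state, op) {
    sol <- ner_solutions()[[ner_label(op$S)]]
    ner_propose(state, sol, walk = if (op$walk) op$kernel else NULL)
  }
  op <- new_operator(label, propose, if (walk) kern else NULL,
                     modes = c("real", "quant", if (!length(S)) "cat"),
                     poi = "tree")
  op$S <- S
  op$walk <- walk
  op
}

#' Classic narrow-exchange operator (NER with no constraints)
#' @export
op_narrow_exchange <- function() {
  op <- op_ner(character(0))
  op$name <- "NarrowExchange"
  op
}
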
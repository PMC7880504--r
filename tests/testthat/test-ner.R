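# Narrow-exchange-rate family: constraint enumeration, symbolic solutions,
# Jacobians and proposal execution.

test_that("constraint subsets enumerate completely and canonically", {
  sets <- enumerate_constraint_sets()
  expect_length(sets, 64L)
  labels <- vapply(sets, function(s) paste(s, collapse = ","), character(1))
  expect_false(anyDuplicated(labels) > 0)
  expect_true("" %in% labels)
  expect_true("DAB,DAC,DAE,DBC,DBE,DCE" %in% labels)
})

test_that("the empty subset is the identity operator", {
  sol <- solve_constraint_set(character(0))
  expect_equal(sol$status, "valid")
  vals <- random_ner_vals()
  ev <- ner_evaluate(sol, vals)
  expect_equal(unname(ev$rates), unname(vals[c("rA", "rB", "rC", "rD")]))
  expect_equal(ev$jac, 1)
})

test_that("the full constraint set is unsolvable", {
  sol <- solve_constraint_set(relclock:::.ner_names)
  expect_equal(sol$status, "unsolvable")
  expect_error(ner_evaluate(sol, random_ner_vals()), "no generic solution")
})

test_that("the benchmark solution reproduces the published update rules", {
  sol <- ner_solutions()[["NER{DAE,DBE,DCE}"]]
  expect_equal(sol$status, "valid")
  set.seed(71)
  for (i in 1:20) {
    v <- random_ner_vals()
    ev <- ner_evaluate(sol, v)
    expect_equal(ev$rates[["rpA"]],
                 (v[["rA"]] * (v[["tD"]] - v[["tA"]]) +
                  v[["rD"]] * (v[["tE"]] - v[["tD"]])) /
                 (v[["tE"]] - v[["tA"]]), tolerance = 1e-12)
    expect_equal(ev$rates[["rpB"]],
                 (v[["rB"]] * (v[["tD"]] - v[["tB"]]) +
                  v[["rD"]] * (v[["tDp"]] - v[["tD"]])) /
                 (v[["tDp"]] - v[["tB"]]), tolerance = 1e-12)
    expect_equal(ev$rates[["rpC"]],
                 (v[["rC"]] * (v[["tE"]] - v[["tC"]]) -
                  v[["rD"]] * (v[["tE"]] - v[["tDp"]])) /
                 (v[["tDp"]] - v[["tC"]]), tolerance = 1e-12)
    expect_equal(ev$rates[["rpD"]], v[["rD"]])
    expect_equal(ev$jac,
                 ((v[["tD"]] - v[["tA"]]) * (v[["tD"]] - v[["tB"]]) *
                  (v[["tE"]] - v[["tC"]])) /
                 ((v[["tE"]] - v[["tA"]]) * (v[["tDp"]] - v[["tB"]]) *
                  (v[["tDp"]] - v[["tC"]])), tolerance = 1e-12)
  }
})

test_that("the census finds 54 solvable subsets, 6 with zero Jacobian", {
  cen <- classify_all_solutions()
  expect_equal(cen$counts$total, 64L)
  expect_equal(cen$counts$solvable, 54L)
  expect_equal(cen$counts$zero_jacobian, 6L)
  expect_equal(cen$counts$valid, 48L)
  expect_equal(cen$counts$variants, 96L)
})

test_that("every claimed distance constraint holds at random states", {
  # pre/post genetic-distance paths for each constraint
  pre <- list(
    DAB = function(v, r) v[["rA"]] * (v[["tD"]] - v[["tA"]]) +
                         v[["rB"]] * (v[["tD"]] - v[["tB"]]),
    DAC = function(v, r) v[["rA"]] * (v[["tD"]] - v[["tA"]]) +
                         v[["rD"]] * (v[["tE"]] - v[["tD"]]) +
                         v[["rC"]] * (v[["tE"]] - v[["tC"]]),
    DAE = function(v, r) v[["rA"]] * (v[["tD"]] - v[["tA"]]) +
                         v[["rD"]] * (v[["tE"]] - v[["tD"]]),
    DBC = function(v, r) v[["rB"]] * (v[["tD"]] - v[["tB"]]) +
                         v[["rD"]] * (v[["tE"]] - v[["tD"]]) +
                         v[["rC"]] * (v[["tE"]] - v[["tC"]]),
    DBE = function(v, r) v[["rB"]] * (v[["tD"]] - v[["tB"]]) +
                         v[["rD"]] * (v[["tE"]] - v[["tD"]]),
    DCE = function(v, r) v[["rC"]] * (v[["tE"]] - v[["tC"]]))
  post <- list(
    DAB = function(v, r) r[["rpA"]] * (v[["tE"]] - v[["tA"]]) +
                         r[["rpD"]] * (v[["tE"]] - v[["tDp"]]) +
                         r[["rpB"]] * (v[["tDp"]] - v[["tB"]]),
    DAC = function(v, r) r[["rpA"]] * (v[["tE"]] - v[["tA"]]) +
                         r[["rpD"]] * (v[["tE"]] - v[["tDp"]]) +
                         r[["rpC"]] * (v[["tDp"]] - v[["tC"]]),
    DAE = function(v, r) r[["rpA"]] * (v[["tE"]] - v[["tA"]]),
    DBC = function(v, r) r[["rpB"]] * (v[["tDp"]] - v[["tB"]]) +
                         r[["rpC"]] * (v[["tDp"]] - v[["tC"]]),
    DBE = function(v, r) r[["rpB"]] * (v[["tDp"]] - v[["tB"]]) +
                         r[["rpD"]] * (v[["tE"]] - v[["tDp"]]),
    DCE = function(v, r) r[["rpC"]] * (v[["tDp"]] - v[["tC"]]) +
                         r[["rpD"]] * (v[["tE"]] - v[["tDp"]]))
  set.seed(72)
  sols <- Filter(function(s) s$status == "valid", ner_solutions())
  for (sol in sols) {
    for (i in 1:10) {
      v <- random_ner_vals()
      ev <- ner_evaluate(sol, v)
      for (cn in sol$constraints)
        expect_equal(post[[cn]](v, ev$rates), pre[[cn]](v, ev$rates),
                     tolerance = 1e-10)
    }
  }
})

test_that("Jacobians match finite differences; both solve routes agree", {
  set.seed(73)
  sols <- Filter(function(s) s$status == "valid", ner_solutions())
  for (sol in sols) {
    for (i in 1:4) {
      v <- random_ner_vals()
      ev <- ner_evaluate(sol, v)
      expect_equal(fd_ner_jacobian(sol, v), ev$jac, tolerance = 1e-6)
      # closed-form rate expressions against the direct numeric solve
      evs <- ner_evaluate(sol, v, method = "symbolic")
      expect_equal(evs$rates, ev$rates, tolerance = 1e-6)
    }
    # the expanded determinant polynomial cancels catastrophically at
    # generic points for the largest systems, so compare the two routes at
    # small-integer coordinates where polynomial evaluation is exact
    for (vi in list(c(tA = 1, tB = 2, tC = 1, tD = 3, tE = 5, tDp = 4,
                      rA = 1, rB = 2, rC = 3, rD = 4),
                    c(tA = 2, tB = 1, tC = 3, tD = 4, tE = 7, tDp = 5,
                      rA = 3, rB = 1, rC = 2, rD = 5))) {
      expect_equal(ner_evaluate(sol, vi, method = "symbolic")$jac,
                   ner_evaluate(sol, vi)$jac, tolerance = 1e-5)
    }
    # exactness of the closed forms, checked in integer polynomial arithmetic
    expect_true(ner_verify_solution(sol))
  }
  # zero-Jacobian solutions really have vanishing determinants
  zsols <- Filter(function(s) s$status == "zero-jacobian", ner_solutions())
  expect_length(zsols, 6L)
  for (sol in zsols) {
    v <- random_ner_vals()
    expect_lt(abs(fd_ner_jacobian(sol, v)), 1e-8)
  }
})

test_that("narrow-exchange topology sampling follows the step rules", {
  set.seed(74)
  for (i in 1:20) {
    tr <- sim_yule_tree(8)
    sel <- narrow_exchange_topology(tr)
    if (is.null(sel)) next
    expect_equal(tr$parent[sel$D], sel$E)
    expect_equal(tr$parent[sel$C], sel$E)
    expect_equal(sort(tr$child[, sel$D]), sort(c(sel$A, sel$B)))
    expect_gt(tr$height[sel$D], tr$height[sel$C])
    expect_gt(sel$D, tr$N)    # D is internal
  }
  # a 3-taxon tree: the root's taller child is internal, its sibling a leaf
  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  sel <- narrow_exchange_topology(tr3)
  expect_false(is.null(sel))
  # when the taller child of the only eligible node is a leaf, the proposal
  # is rejected (a non-ultrametric tree with a high-sitting tip)
  rej_tr <- timetree(parent = c(4L, 4L, 5L, 5L, NA),
                     height = c(0, 0, 2, 1, 3),
                     tip.label = c("B", "C", "A"))
  for (i in 1:20) expect_null(narrow_exchange_topology(rej_tr))
})

test_that("one narrow-exchange move changes the topology by RF 1", {
  set.seed(75)
  done <- 0
  while (done < 30) {
    tr <- sim_yule_tree(10)
    st <- phylo_state(tr, branch_rates(sim_branch_rates(tr, 0.5), "real"),
                      0.5, list(list(kappa = 1, freqs = rep(0.25, 4),
                                     muC = 1)), 1)
    pr <- ner_propose(st, ner_solutions()[["NER{}"]])
    if (pr$reject) next
    expect_equal(robinson_foulds(tr, pr$state$tree), 1)
    expect_equal(pr$state$rates$values, st$rates$values)  # null: rates fixed
    expect_identical(pr$log_jac, 0)                       # |J| = 1
    done <- done + 1
  }
})

test_that("NER proposals conserve their distances and accept reversibly", {
  set.seed(76)
  sol <- ner_solutions()[["NER{DAE,DBE,DCE}"]]
  done <- 0
  while (done < 30) {
    tr <- sim_yule_tree(8)
    st <- phylo_state(tr, branch_rates(sim_branch_rates(tr, 0.8), "real"),
                      0.8, list(list(kappa = 1, freqs = rep(0.25, 4),
                                     muC = 1)), 1)
    d0 <- sum(branch_distances(st))
    pr <- ner_propose(st, sol)
    if (pr$reject) next
    # total tree distance is conserved: the three constraints cover all the
    # rate changes and heights are untouched
    expect_equal(sum(branch_distances(pr$state)), d0, tolerance = 1e-9)
    expect_gt(min(pr$state$rates$values, na.rm = TRUE), 0)
    done <- done + 1
  }
})

test_that("forward and reverse evaluations have reciprocal Jacobians", {
  set.seed(77)
  sol <- ner_solutions()[["NER{DAE,DBE,DCE}"]]
  for (i in 1:20) {
    v <- random_ner_vals()
    ev <- ner_evaluate(sol, v)
    # reverse labelling: after the move D's children are B and the old
    # sibling C while A hangs from E, so the reverse move labels A <- C,
    # B <- B, C <- A and swaps t_D with t'_D
    vr <- c(tA = v[["tC"]], tB = v[["tB"]], tC = v[["tA"]],
            tD = v[["tDp"]], tE = v[["tE"]], tDp = v[["tD"]],
            rA = ev$rates[["rpC"]], rB = ev$rates[["rpB"]],
            rC = ev$rates[["rpA"]], rD = ev$rates[["rpD"]])
    evr <- ner_evaluate(sol, vr)
    expect_equal(evr$rates[["rpA"]], v[["rC"]], tolerance = 1e-9)
    expect_equal(evr$rates[["rpB"]], v[["rB"]], tolerance = 1e-9)
    expect_equal(evr$rates[["rpC"]], v[["rA"]], tolerance = 1e-9)
    expect_equal(evr$rates[["rpD"]], v[["rD"]], tolerance = 1e-9)
    expect_equal(ev$jac * evr$jac, 1, tolerance = 1e-9)
  }
})

test_that("quant-mode NER proposals carry the quantile-map Jacobian", {
  set.seed(78)
  sol <- ner_solutions()[["NER{DAE,DBE,DCE}"]]
  done <- 0
  while (done < 10) {
    tr <- sim_yule_tree(8)
    r <- sim_branch_rates(tr, 0.6)
    q <- r; ok <- !is.na(q); q[ok] <- quant_from_rate(r[ok], 0.6)
    st <- phylo_state(tr, branch_rates(q, "quant"), 0.6,
                      list(list(kappa = 1, freqs = rep(0.25, 4), muC = 1)), 1)
    d0 <- sum(branch_distances(st))
    pr <- ner_propose(st, sol)
    if (pr$reject) next
    expect_equal(sum(branch_distances(pr$state)), d0, tolerance = 1e-8)
    expect_true(is.finite(pr$log_jac))
    done <- done + 1
  }
})
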
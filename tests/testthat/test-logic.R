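test_that("infer_rules follows the activity-flow convention", {
  net <- parse_sif(c("A -> C", "B -| C"))
  m <- infer_rules(net)
  tt <- rule_truth_table(m$rules[["C"]], c("A", "B", "C"))
  want <- rule_truth_table(quote(A & !B), c("A", "B", "C"))
  expect_identical(tt, want)

  net <- signed_network("X")
  m <- infer_rules(net)
  expect_equal(model_inputs(m), "X")

  net <- parse_sif(c("A -| C"))
  m <- infer_rules(net)
  expect_identical(rule_truth_table(m$rules[["C"]], c("A", "C")),
                   rule_truth_table(quote(!A), c("A", "C")))

  expect_error(infer_rules(parse_sif("A COREGULATION B")), "COREGULATION")

  # with at least one activator, the rule is off when all activators are off
  for (seed in 1:5) {
    net <- random_connected_network(12, seed)
    m <- infer_rules(net)
    for (v in m$variables) {
      acts <- net$edges$source[net$edges$target == v &
                               net$edges$sign == "ACTIVATION"]
      if (length(acts) == 0) next
      env <- stats::setNames(as.list(rep(TRUE, length(m$variables))),
                             m$variables)
      env[acts] <- FALSE
      expect_false(as.logical(eval(m$rules[[v]], envir = env)))
    }
  }
})

test_that("apply_perturbation clamps without touching rules", {
  m <- ra_model()
  ko <- apply_perturbation(m, c(MAPK14 = 0L))
  expect_equal(ko$clamps[["MAPK14"]], 0L)
  expect_identical(ko$rules, m$rules)
  expect_identical(apply_perturbation(m, integer()), m)
  expect_error(apply_perturbation(m, c(MAPK14 = 0L, MAPK14 = 1L)),
               "conflicting")
  expect_error(apply_perturbation(m, c(NOPE = 0L)), "NOPE")

  # every fixed point of a perturbed model honours the clamps
  for (seed in 1:5) {
    m <- gen_random_model(8, seed = seed)
    pert <- c(V01 = 0L, V05 = 1L)
    fps <- stable_states(apply_perturbation(m, pert))
    if (nrow(fps)) {
      expect_true(all(fps$V01 == 0L))
      expect_true(all(fps$V05 == 1L))
    }
  }
})

test_that("stable_states matches brute force and handles edge cases", {
  m <- logical_model(list(X = quote(!X)))
  expect_equal(nrow(stable_states(m)), 0)

  for (seed in 1:40) {
    m <- gen_random_model(sample(2:10, 1, prob = rep(1, 9)),
                          max_regulators = 3, seed = seed)
    expect_same_states(stable_states(m), brute_stable_states(m))
  }
  # clamped models agree with the naive path too
  for (seed in 1:10) {
    m <- gen_random_model(7, seed = seed)
    m2 <- apply_perturbation(m, c(V02 = 1L, V06 = 0L))
    expect_same_states(stable_states(m2), brute_stable_states(m2))
  }

  big <- logical_model(stats::setNames(
    lapply(sprintf("V%02d", 1:30), as.symbol), sprintf("V%02d", 1:30)))
  expect_error(stable_states(big), "reduce_model")
})

test_that("async_attractors classifies terminal SCCs", {
  osc <- logical_model(list(A = quote(!B), B = quote(A)))
  res <- async_attractors(osc)
  expect_equal(nrow(res$fixed_points), 0)
  expect_equal(length(res$complex_attractors), 1)
  expect_equal(nrow(res$complex_attractors[[1]]), 4)

  # fixed points agree with stable_states on random models
  for (seed in 1:15) {
    m <- gen_random_model(7, seed = seed)
    res <- async_attractors(m)
    expect_same_states(res$fixed_points, stable_states(m))
  }
})

test_that("reduce_model substitutes rules and preserves fixed points", {
  m <- parse_bnet("A, A\nB, A\nC, B")
  red <- reduce_model(m, "B")
  expect_equal(red$variables, c("A", "C"))
  expect_identical(rule_truth_table(red$rules[["C"]], c("A", "C")),
                   rule_truth_table(quote(A), c("A", "C")))

  expect_identical(reduce_model(m, character()), m)
  auto <- parse_bnet("A, A | B\nB, A")
  expect_error(reduce_model(auto, "A"), "autoregulated")
  clamped <- apply_perturbation(m, c(B = 0L))
  expect_error(reduce_model(clamped, "B"), "clamped")

  # projected fixed points unchanged, extended states recover originals
  for (seed in 1:20) {
    m <- gen_random_model(8, seed = seed + 500)
    cand <- Filter(function(v) !(v %in% all.vars(m$rules[[v]])),
                   m$variables)
    if (length(cand) == 0) next
    drop <- sample(cand, 1)
    red <- reduce_model(m, drop)
    fp_full <- stable_states(m)
    fp_red <- stable_states(red)
    expect_same_states(fp_full[, red$variables, drop = FALSE], fp_red)
    expect_same_states(extend_states(fp_red, red), fp_full)
  }
})

test_that("constraint solver handles degenerate cases", {
  # single unregulated node: both states are fixed points of an input
  topo <- signed_network("X")
  tab <- state_constraint_table(data.frame(X = c(0, 1)))
  m <- solve_rules_from_constraints(topo, list(tab))
  expect_identical(m$rules[["X"]], quote(X))

  # simple forced rule
  topo <- parse_sif("A -> X")
  tab <- state_constraint_table(data.frame(A = c(0, 1), X = c(0, 1)))
  m <- solve_rules_from_constraints(topo, list(tab))
  expect_identical(rule_truth_table(m$rules[["X"]], c("A", "X")),
                   rule_truth_table(quote(A), c("A", "X")))

  # contradictory requirements on identical regulator rows
  bad <- state_constraint_table(data.frame(A = c(0, 0), X = c(0, 1)))
  expect_error(solve_rules_from_constraints(topo, list(bad)),
               "infeasible.*X")
})

test_that("state_constraint_table validates its rows", {
  expect_error(state_constraint_table(data.frame(X = 2)), "0/1")
  expect_error(state_constraint_table(data.frame(X = 1),
                                      input_clamps = c(X = 0L)),
               "contradicts")
})
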
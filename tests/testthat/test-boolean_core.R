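test_that("rule-space size follows the 2^(2^k - 1) - 1 closed form", {
  regs <- function(k) data.frame(gene = LETTERS[seq_len(k)],
                                 sign = rep(1L, k))
  expect_length(enumerate_rule_space(regs(1)), 1L)
  expect_length(enumerate_rule_space(regs(2)), 7L)
  expect_length(enumerate_rule_space(regs(3)), 127L)
  # all rules distinct by clause-set identity
  keys <- vapply(enumerate_rule_space(regs(3)), function(r)
    paste(vapply(r$clauses, paste, "", collapse = ","), collapse = "|"), "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(enumerate_rule_space(regs(0)), "1 to 3")
  expect_error(enumerate_rule_space(data.frame(gene = LETTERS[1:4],
                                               sign = rep(1L, 4))), "1 to 3")
})

test_that("evaluate_rule matches truth-table semantics and the eval oracle", {
  # A OR B, state A=0, B=1 -> 1
  r_or <- boolean_rule("T", data.frame(gene = c("A", "B"), sign = c(1L, 1L)),
                       list(1L, 2L))
  expect_equal(evaluate_rule(r_or, c(A = 0L, B = 1L)), 1L)
  # (not A) AND B with A inhibitory, state A=1, B=1 -> 0
  r_and <- boolean_rule("T", data.frame(gene = c("A", "B"), sign = c(-1L, 1L)),
                        list(c(1L, 2L)))
  expect_equal(evaluate_rule(r_and, c(A = 1L, B = 1L)), 0L)
  expect_error(evaluate_rule(r_and, c(A = 1L)), "missing regulator")

  # exhaustive agreement with the independent eval() oracle, k = 1..3,
  # all sign patterns, every rule, every input state
  for (k in 1:3) {
    for (sign_mask in 0:(2^k - 1)) {
      signs <- ifelse(bitwAnd(sign_mask, 2^(seq_len(k) - 1)) > 0, -1L, 1L)
      regs <- data.frame(gene = LETTERS[seq_len(k)], sign = signs)
      for (rule in enumerate_rule_space(regs)) {
        for (idx in 0:(2^k - 1)) {
          state <- setNames(bitwAnd(bitwShiftR(idx, seq_len(k) - 1), 1L),
                            LETTERS[seq_len(k)])
          expect_identical(evaluate_rule(rule, state),
                           oracle_eval_rule(rule, state))
        }
      }
    }
  }
})

test_that("synchronous simulation finds hand-checked fixed points and cycles", {
  # 1 node, no edges: constant
  nw1 <- signed_network("one", "A")
  m1 <- network_model(nw1, list())
  traj <- simulate_synchronous(m1, c(A = 1L), steps = 5)
  expect_true(all(traj[, "A"] == 1L))

  # mutual inhibition A -| B, B -| A from (1, 0): fixed point (1, 0)
  nw2 <- signed_network("toggle", c("A", "B"),
                        make_edges(list("A", "B", -1), list("B", "A", -1)))
  rules2 <- list(
    A = boolean_rule("A", data.frame(gene = "B", sign = -1L), list(1L)),
    B = boolean_rule("B", data.frame(gene = "A", sign = -1L), list(1L)))
  m2 <- network_model(nw2, rules2)
  traj2 <- simulate_synchronous(m2, c(A = 1L, B = 0L), steps = 8)
  expect_true(all(traj2[, "A"] == 1L) && all(traj2[, "B"] == 0L))

  # negative feedback A -| B, B -> A from (1, 1): limit cycle, deterministic
  nw3 <- signed_network("osc", c("A", "B"),
                        make_edges(list("A", "B", -1), list("B", "A", 1)))
  rules3 <- list(
    A = boolean_rule("A", data.frame(gene = "B", sign = 1L), list(1L)),
    B = boolean_rule("B", data.frame(gene = "A", sign = -1L), list(1L)))
  m3 <- network_model(nw3, rules3)
  t1 <- simulate_synchronous(m3, c(A = 1L, B = 1L), steps = 12)
  t2 <- simulate_synchronous(m3, c(A = 1L, B = 1L), steps = 12)
  expect_identical(t1, t2)
  # the 4-state transition graph gives a period-4 cycle here
  expect_identical(t1[1, ], t1[5, ])
  expect_identical(t1[2, ], t1[6, ])
})

test_that("steady_state averages the trailing window", {
  traj <- matrix(rep(c(0L, 1L), 6), ncol = 1, dimnames = list(NULL, "A"))
  expect_equal(unname(steady_state(traj, window = 4)), 0.5)
  fixed <- matrix(1L, nrow = 10, ncol = 1, dimnames = list(NULL, "A"))
  expect_equal(unname(steady_state(fixed, window = 3)), 1)
  expect_error(steady_state(traj, window = 0), ">= 1")
  expect_error(steady_state(traj, window = 99), "exceeds")
})

test_that("compiled steady path agrees with exhaustive attractor analysis", {
  # random models up to 8 nodes: trajectory-based steady state, the compiled
  # C-level path, and the independent state-graph oracle must all agree once
  # steps exceed the state-space bound 2^n
  for (seed in 1:6) {
    truth <- generate_ground_truth(n_nodes = 5 + (seed %% 4), seed = 900 + seed)
    model <- truth$model
    nodes <- model$network$nodes
    n <- length(nodes)
    set.seed(seed)
    init <- setNames(sample(0:1, n, replace = TRUE), nodes)
    steps <- 2^n + 8
    window <- 8L   # multiple of every cycle length reachable here
    traj <- simulate_synchronous(model, init, steps = steps)
    via_traj <- steady_state(traj, window = window)
    cm <- boolomics:::compile_model(model)
    via_cpp <- setNames(boolomics:::steady_from_compiled(
      cm, init[cm$nodes], steps = steps, window = window), cm$nodes)
    oracle <- oracle_attractor_mean(model, init)
    expect_equal(via_traj, via_cpp, tolerance = 1e-12)
    expect_equal(via_traj, oracle[names(via_traj)], tolerance = 1e-12)
    # invariant to extending the run once the cycle is entered
    longer <- steady_state(simulate_synchronous(model, init, steps = steps + 16),
                           window = window)
    expect_equal(via_traj, longer, tolerance = 1e-12)
  }
})

test_that("cyclic models also match the state-graph oracle", {
  # feedback loops (not covered by the acyclic generator)
  nw <- signed_network("loop3", c("A", "B", "C"),
                       make_edges(list("A", "B", 1), list("B", "C", 1),
                                  list("C", "A", -1)))
  rules <- list(
    A = boolean_rule("A", data.frame(gene = "C", sign = -1L), list(1L)),
    B = boolean_rule("B", data.frame(gene = "A", sign = 1L), list(1L)),
    C = boolean_rule("C", data.frame(gene = "B", sign = 1L), list(1L)))
  model <- network_model(nw, rules)
  for (idx in 0:7) {
    init <- setNames(bitwAnd(bitwShiftR(idx, 0:2), 1L), c("A", "B", "C"))
    traj <- simulate_synchronous(model, init, steps = 56)
    got <- steady_state(traj, window = 48)   # 48 is a multiple of period 6
    oracle <- oracle_attractor_mean(model, init)
    expect_equal(got, oracle[names(got)], tolerance = 1e-12)
  }
})

test_that("in-degree truncation keeps the best-correlated regulators", {
  nw <- signed_network("hub", c("R1", "R2", "R3", "R4", "T"),
                       make_edges(list("R1", "T", 1), list("R2", "T", 1),
                                  list("R3", "T", 1), list("R4", "T", 1)))
  # T tracks R1, R2, R3 exactly; R4 is anticorrelated-free noise
  bits <- list(
    c(R1 = 0L, R2 = 0L, R3 = 0L, R4 = 1L, T = 0L),
    c(R1 = 1L, R2 = 1L, R3 = 1L, R4 = 1L, T = 1L),
    c(R1 = 0L, R2 = 0L, R3 = 0L, R4 = 0L, T = 0L),
    c(R1 = 1L, R2 = 1L, R3 = 1L, R4 = 0L, T = 1L))
  st <- states_from_bits(bits)
  trimmed <- prepare_network(nw, st)
  expect_equal(max(node_indegree(trimmed)), 3L)
  expect_setequal(trimmed$edges$source, c("R1", "R2", "R3"))
})
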
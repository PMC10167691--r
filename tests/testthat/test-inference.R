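test_that("fitness is zero for a model reproducing its training bits", {
  model <- chain_model()
  st <- states_from_bits(list(c(A = 0L, B = 0L), c(A = 1L, B = 1L)))
  rep <- fitness(model, st)
  expect_equal(rep$total, 0)
  expect_equal(unname(rep$per_node), c(0, 0))
  # B observed opposite to A: B's error is 1 in each state
  st_bad <- states_from_bits(list(c(A = 0L, B = 1L), c(A = 1L, B = 0L)))
  rep_bad <- fitness(model, st_bad)
  expect_equal(rep_bad$per_node[["B"]], 1)
  expect_true(all(rep_bad$per_node >= 0 & rep_bad$per_node <= 1))
  expect_equal(rep_bad$total, sum(rep_bad$per_node))
  expect_error(fitness(model, states_from_bits(list())), "no training states")
})

test_that("mask-aware fitness ignores unmeasured nodes", {
  model <- chain_model()
  # B never measured: its error cannot be counted
  st <- states_from_bits(list(c(A = 1L), c(A = 0L)))
  rep <- fitness(model, st)
  expect_equal(rep$per_node[["B"]], 0)
  expect_equal(rep$total, 0)
})

test_that("GA finds the consistent model on a noise-free chain and is seeded", {
  nw <- signed_network("chain", c("A", "B"), make_edges(list("A", "B", 1)))
  st <- states_from_bits(list(c(A = 0L, B = 0L), c(A = 1L, B = 1L)))
  cfg <- ga_config(population_size = 6, generations = 5, seed = 11)
  m1 <- ga_search(nw, st, cfg)
  expect_equal(attr(m1, "fitness")$total, 0)
  m2 <- ga_search(nw, st, cfg)
  expect_identical(attr(m1, "assignment"), attr(m2, "assignment"))
  # elite fitness never increases across generations
  log <- attr(m1, "log")
  expect_true(all(diff(log$best_fitness) <= 0))
})

test_that("GA beats a random-assignment baseline on a synthetic pathway", {
  truth <- generate_ground_truth(8, seed = 41)
  fx <- generate_multiomics(truth, noise_sd = 0, seed = 41)
  ga_model <- ga_search(truth$network, fx$states,
                        ga_config(population_size = 12, generations = 12, seed = 5))
  ga_fit <- attr(ga_model, "fitness")$total
  # median fitness of 20 uniformly random rule assignments
  indeg <- node_indegree(truth$network)
  rule_nodes <- names(indeg)[indeg >= 1]
  spaces <- lapply(rule_nodes, function(nd)
    enumerate_rule_space(boolomics:::node_regulators(truth$network, nd),
                         target = nd))
  names(spaces) <- rule_nodes
  set.seed(99)
  rand_fits <- replicate(20, {
    rules <- lapply(spaces, function(sp) sp[[sample.int(length(sp), 1)]])
    fitness(network_model(truth$network, rules), fx$states)$total
  })
  expect_lte(ga_fit, median(rand_fits))
  # GA non-increasing elite also holds on the harder instance
  expect_true(all(diff(attr(ga_model, "log")$best_fitness) <= 0))
})

test_that("local search returns exact-tie equivalent rule sets", {
  # constant-0 target with one constant-0 activator: the single k=1 rule ties
  nw <- signed_network("c0", c("A", "B"), make_edges(list("A", "B", 1)))
  st <- states_from_bits(list(c(A = 0L, B = 0L), c(A = 0L, B = 0L)))
  inc <- ga_search(nw, st, ga_config(population_size = 2, generations = 1, seed = 1))
  out <- local_search(nw, st, inc)
  expect_length(out$ers$B$rules, 1L)
  expect_equal(out$ers$B$fitness, 0)

  # noise-free data from a known k=2 rule: the true rule is in the ERS,
  # and every ERS is bounded by the k=3 maximum of 127
  truth <- generate_ground_truth(9, seed = 13)
  fx <- generate_multiomics(truth, noise_sd = 0, seed = 13)
  inf <- infer_rules(truth$network, fx$states, ga_config(seed = 2))
  for (nd in names(truth$rules)) {
    expect_lte(length(inf$ers[[nd]]$rules), 127L)
    k <- nrow(truth$rules[[nd]]$regulators)
    if (k == 2) {
      hit <- any(vapply(inf$ers[[nd]]$rules, function(r)
        identical(r$clauses, truth$rules[[nd]]$clauses), TRUE))
      expect_true(hit)
    }
  }
  # the replaced incumbent achieves the ERS fitness on every node
  rep <- fitness(out$model, st)
  expect_equal(rep$per_node[["B"]], out$ers$B$fitness)
})

test_that("ERS size summaries restrict to high in-degree and average sizes", {
  truth <- generate_ground_truth(10, edge_density = 0.8, seed = 21)
  fx <- generate_multiomics(truth, noise_sd = 0, seed = 21)
  inf <- infer_rules(truth$network, fx$states, ga_config(seed = 3))
  tab <- ers_size_summary(inf$ers, truth$network, min_indegree = 3)
  expect_true(all(tab$indegree >= 3))
  expect_equal(attr(tab, "mean"), mean(tab$ers_size))
  expect_equal(attr(tab, "median"), median(tab$ers_size))
  # arithmetic sanity on a constructed pair of sizes
  fake <- list(X = list(target = "X", rules = vector("list", 1), fitness = 0),
               Y = list(target = "Y", rules = vector("list", 127), fitness = 0))
  nw <- signed_network(
    "f", c("A", "B", "C", "X", "Y"),
    make_edges(list("A", "X", 1), list("B", "X", 1), list("C", "X", 1),
               list("A", "Y", 1), list("B", "Y", 1), list("C", "Y", 1)))
  tab2 <- ers_size_summary(fake, nw, min_indegree = 3)
  expect_equal(attr(tab2, "mean"), 64)
  expect_equal(attr(tab2, "median"), 64)
})

test_that("rule files list every candidate with its shared error", {
  truth <- generate_ground_truth(6, seed = 31)
  fx <- generate_multiomics(truth, noise_sd = 0, seed = 31)
  inf <- infer_rules(truth$network, fx$states, ga_config(seed = 4))
  f <- withr::local_tempfile(fileext = ".txt")
  write_ers(inf$ers, f)
  lines <- readLines(f)
  n_rules <- sum(vapply(inf$ers, function(e) length(e$rules), 0L))
  expect_equal(sum(grepl("^# node ", lines)), length(inf$ers))
  expect_equal(sum(grepl("\\* = ", lines)), n_rules)
})
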
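# Rule inference: mask-aware fitness, genetic algorithm, and node-local
# exhaustive search returning equivalent rule sets (ERS).

#' Genetic algorithm configuration
#'
#' Defaults are pathway-scale: population 24, 50 generations, crossover 0.6,
#' per-node mutation 0.3, tournament size 3, one elite.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_prob Probability a selected pair undergoes uniform
#'   per-node crossover.
#' @param mutation_prob Per-node probability of resampling that node's rule.
#' @param tournament_size Tournament size for selection.
#' @param seed Integer seed; the search is fully reproducible given it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 24L, generations = 50L,
                      crossover_prob = 0.6, mutation_prob = 0.3,
                      tournament_size = 3L, seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Internal search context: per-node enumerated rule spaces with precomputed
# truth tables, plus training states mapped onto the network's node order.
build_search_context <- function(network, states) {
  if (!length(states$states)) stop("no training states", call. = FALSE)
  nodes <- network$nodes
  indeg <- node_indegree(network)
  rule_nodes <- names(indeg)[indeg >= 1L]
  spaces <- lapply(rule_nodes, function(node) {
    regs <- node_regulators(network, node)
    rules <- enumerate_rule_space(regs, target = node)
    list(rules = rules,
         reg_idx = match(regs$gene, nodes) - 1L,
         tables = lapply(rules, rule_truth_table))
  })
  names(spaces) <- rule_nodes
  # per training state: init bits over node order (unmeasured -> 0) + mask
  train <- lapply(states$states, function(st) {
    bits <- st$bits[nodes]
    mask <- !is.na(bits)
    bits[!mask] <- 0L
    list(init = as.integer(bits), mask = mask, observed = as.integer(bits))
  })
  list(nodes = nodes, rule_nodes = rule_nodes, spaces = spaces, train = train)
}

# Fitness of an assignment (named integer vector of rule indices per rule
# node) inside a search context: per-node mean |steady - observed| over the
# states where the node is measured.
assignment_fitness <- function(ctx, assignment, steps = 100L, window = 20L) {
  n <- length(ctx$nodes)
  reg_idx <- rep(list(integer()), n)
  truth <- rep(list(integer()), n)
  for (node in ctx$rule_nodes) {
    i <- match(node, ctx$nodes)
    sp <- ctx$spaces[[node]]
    reg_idx[[i]] <- sp$reg_idx
    truth[[i]] <- sp$tables[[assignment[[node]]]]
  }
  err_sum <- numeric(n)
  err_cnt <- numeric(n)
  for (tr in ctx$train) {
    ss <- steady_sim_cpp(reg_idx, truth, tr$init, as.integer(steps),
                         as.integer(window), -1L, 0L)
    m <- tr$mask
    err_sum[m] <- err_sum[m] + abs(ss[m] - tr$observed[m])
    err_cnt[m] <- err_cnt[m] + 1
  }
  per_node <- ifelse(err_cnt > 0, err_sum / err_cnt, 0)
  names(per_node) <- ctx$nodes
  list(per_node = per_node, total = sum(per_node))
}

#' Fitness of a network model against binarized training states
#'
#' Each (layer, sample) state initializes the network (genes unmeasured in
#' that layer start at 0), which is simulated to steady state; the per-node
#' error is the mean absolute difference between steady value and observed
#' bit over the states in which the node is measured. Unmeasured entries
#' never contribute (mask-aware fitness).
#'
#' @param model A [network_model()].
#' @param states A [binarize()] result.
#' @param steps,window Simulation settings (see [steady_state()]).
#' @return List with `per_node` (named errors in `[0, 1]`) and `total`
#'   (their sum).
#' @export
fitness <- function(model, states, steps = 100L, window = 20L) {
  if (!length(states$states)) stop("no training states", call. = FALSE)
  cm <- compile_model(model)
  n <- length(cm$nodes)
  err_sum <- numeric(n)
  err_cnt <- numeric(n)
  for (st in states$states) {
    bits <- st$bits[cm$nodes]
    mask <- !is.na(bits)
    bits[!mask] <- 0L
    ss <- steady_sim_cpp(cm$reg_idx, cm$truth, as.integer(bits),
                         as.integer(steps), as.integer(window), -1L, 0L)
    err_sum[mask] <- err_sum[mask] + abs(ss[mask] - bits[mask])
    err_cnt[mask] <- err_cnt[mask] + 1
  }
  per_node <- setNames(ifelse(err_cnt > 0, err_sum / err_cnt, 0), cm$nodes)
  list(per_node = per_node, total = sum(per_node))
}

#' Genetic-algorithm search for a well-fitting rule assignment
#'
#' A generational GA over rule assignments (one rule index per rule-bearing
#' node): tournament selection, uniform per-node crossover, per-node
#' rule-resampling mutation, one elite carried over unchanged. The best-ever
#' individual is returned; its fitness is non-increasing across generations.
#'
#' @param network A prepared [signed_network()] (in-degree <= 3).
#' @param states A [binarize()] result.
#' @param config A [ga_config()].
#' @param steps,window Simulation settings.
#' @return A [network_model()] carrying attributes `fitness` (the
#'   [fitness()] report) and `log` (data frame of generation, best_fitness).
#' @export
ga_search <- function(network, states, config = ga_config(),
                      steps = 100L, window = 20L) {
  ctx <- build_search_context(network, states)
  space_sizes <- vapply(ctx$spaces, function(sp) length(sp$rules), 0L)

  assignment_to_model <- function(asg) {
    rules <- lapply(ctx$rule_nodes, function(node)
      ctx$spaces[[node]]$rules[[asg[[node]]]])
    names(rules) <- ctx$rule_nodes
    network_model(network, rules)
  }

  if (!length(ctx$rule_nodes)) {
    model <- network_model(network, list())
    attr(model, "fitness") <- fitness(model, states, steps, window)
    attr(model, "log") <- data.frame(generation = integer(), best_fitness = numeric())
    return(model)
  }

  with_seed(config$seed, {
    rand_asg <- function() {
      setNames(as.list(vapply(space_sizes, function(sz) sample.int(sz, 1L), 0L)),
               ctx$rule_nodes)
    }
    pop <- replicate(config$population_size, rand_asg(), simplify = FALSE)
    fits <- vapply(pop, function(a) assignment_fitness(ctx, a, steps, window)$total, 0)
    best_i <- which.min(fits)
    best <- pop[[best_i]]
    best_fit <- fits[best_i]
    log <- data.frame(generation = 0L, best_fitness = best_fit)

    for (gen in seq_len(config$generations)) {
      if (best_fit == 0) break  # nothing left to improve
      tournament <- function() {
        idx <- sample.int(length(pop), config$tournament_size, replace = TRUE)
        pop[[idx[which.min(fits[idx])]]]
      }
      children <- list(best)  # elitism
      while (length(children) < config$population_size) {
        p1 <- tournament()
        p2 <- tournament()
        if (runif(1) < config$crossover_prob) {
          swap <- runif(length(ctx$rule_nodes)) < 0.5
          tmp <- p1
          p1[swap] <- p2[swap]
          p2[swap] <- tmp[swap]
        }
        for (child in list(p1, p2)) {
          mut <- runif(length(ctx$rule_nodes)) < config$mutation_prob
          for (j in which(mut)) {
            child[[j]] <- sample.int(space_sizes[[j]], 1L)
          }
          if (length(children) < config$population_size) {
            children[[length(children) + 1L]] <- child
          }
        }
      }
      pop <- children
      fits <- vapply(pop, function(a) assignment_fitness(ctx, a, steps, window)$total, 0)
      gi <- which.min(fits)
      if (fits[gi] < best_fit) {
        best_fit <- fits[gi]
        best <- pop[[gi]]
      }
      log <- rbind(log, data.frame(generation = gen, best_fitness = best_fit))
    }

    model <- assignment_to_model(best)
    attr(model, "fitness") <- fitness(model, states, steps, window)
    attr(model, "log") <- log
    attr(model, "assignment") <- best
    model
  })
}

#' Node-local exhaustive search: equivalent rule sets
#'
#' For each rule-bearing node independently, every rule in its enumerated
#' space (at most 127) is evaluated while all other nodes keep the
#' incumbent's rules; the ERS is the set of rules achieving the minimal node
#' error (ties exact to 12 decimal places). The incumbent's rule is replaced
#' by the first minimal-error rule in enumeration order.
#'
#' @param network A prepared [signed_network()].
#' @param states A [binarize()] result.
#' @param incumbent A [network_model()], typically from [ga_search()].
#' @param steps,window Simulation settings.
#' @return List with `ers` (named list of `equivalent_rule_set`: `target`,
#'   `rules`, `indices`, `fitness`) and `model` (updated incumbent).
#' @export
local_search <- function(network, states, incumbent, steps = 100L, window = 20L) {
  ctx <- build_search_context(network, states)
  nodes <- ctx$nodes
  n <- length(nodes)

  # incumbent assignment as truth tables over node order
  base_reg <- rep(list(integer()), n)
  base_truth <- rep(list(integer()), n)
  for (node in ctx$rule_nodes) {
    i <- match(node, nodes)
    base_reg[[i]] <- ctx$spaces[[node]]$reg_idx
    base_truth[[i]] <- rule_truth_table(incumbent$rules[[node]])
  }

  ers <- list()
  new_rules <- incumbent$rules
  for (node in ctx$rule_nodes) {
    i <- match(node, nodes)
    sp <- ctx$spaces[[node]]
    errs <- vapply(seq_along(sp$rules), function(r) {
      truth <- base_truth
      truth[[i]] <- sp$tables[[r]]
      e_sum <- 0
      e_cnt <- 0L
      for (tr in ctx$train) {
        if (!tr$mask[i]) next
        ss <- steady_sim_cpp(base_reg, truth, tr$init, as.integer(steps),
                             as.integer(window), -1L, 0L)
        e_sum <- e_sum + abs(ss[i] - tr$observed[i])
        e_cnt <- e_cnt + 1L
      }
      if (e_cnt > 0L) e_sum / e_cnt else 0
    }, 0)
    rerrs <- round(errs, 12L)
    idx <- which(rerrs == min(rerrs))
    ers[[node]] <- structure(list(target = node, rules = sp$rules[idx],
                                  indices = idx, fitness = min(rerrs)),
                             class = "equivalent_rule_set")
    new_rules[[node]] <- sp$rules[[idx[1L]]]
    base_truth[[i]] <- sp$tables[[idx[1L]]]  # incumbent updated in place
  }
  list(ers = ers, model = network_model(network, new_rules))
}

#' Infer rules for one pathway: GA followed by local search
#'
#' Convenience wrapper running [ga_search()] then [local_search()].
#'
#' @inheritParams ga_search
#' @return As [local_search()], plus `ga_log`.
#' @export
infer_rules <- function(network, states, config = ga_config(),
                        steps = 100L, window = 20L) {
  incumbent <- ga_search(network, states, config, steps, window)
  out <- local_search(network, states, incumbent, steps, window)
  out$ga_log <- attr(incumbent, "log")
  out
}

#' Summarize ERS sizes as an uncertainty proxy
#'
#' The size of a node's equivalent rule set is a proxy for the uncertainty of
#' rule determination: a singleton means the data pin down the logic, 127 (the
#' k = 3 maximum) means the data say nothing. The summary is restricted to
#' nodes with in-degree >= `min_indegree` (low in-degree nodes have tiny rule
#' spaces and would dilute the comparison).
#'
#' @param ers Named list of equivalent rule sets (from [local_search()]).
#' @param network The [signed_network()] the rules belong to.
#' @param min_indegree Minimum in-degree to include (default 3).
#' @return Data frame (node, indegree, ers_size) with attributes `mean` and
#'   `median`.
#' @export
ers_size_summary <- function(ers, network, min_indegree = 3L) {
  indeg <- node_indegree(network)
  tab <- data.frame(node = names(ers),
                    indegree = indeg[names(ers)],
                    ers_size = vapply(ers, function(e) length(e$rules), 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[tab$indegree >= min_indegree, , drop = FALSE]
  attr(tab, "mean") <- if (nrow(tab)) mean(tab$ers_size) else NA_real_
  attr(tab, "median") <- if (nrow(tab)) median(tab$ers_size) else NA_real_
  tab
}

#' Write equivalent rule sets to a human-readable text file
#'
#' One block per node: every candidate rule in `TARGET* = ...` form plus the
#' shared error.
#'
#' @param ers Named list of equivalent rule sets.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ers <- function(ers, path) {
  lines <- character()
  for (node in names(ers)) {
    e <- ers[[node]]
    lines <- c(lines,
               sprintf("# node %s: %d equivalent rule(s), error %.6g",
                       node, length(e$rules), e$fitness),
               vapply(e$rules, format_rule, ""))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}
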
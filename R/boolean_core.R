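# Boolean rule representation, rule-space enumeration and synchronous
# simulation with steady-state extraction.

#' Construct a Boolean regulatory rule
#'
#' A rule is an OR-of-AND formula over a node's signed regulators: the node
#' becomes 1 when at least one clause is satisfied, where a clause is the AND
#' of its member inputs and an inhibitory regulator contributes its negated
#' state. Clause sets are stored as given (no absorption-law reduction), so
#' rule identity is clause-set identity and the enumerable space size is exact.
#'
#' @param target Target gene.
#' @param regulators Data frame with columns `gene`, `sign` (ordered; at most
#'   3 rows).
#' @param clauses List of integer vectors indexing rows of `regulators`; each
#'   clause nonempty, the set nonempty.
#' @return A `boolean_rule`.
#' @export
boolean_rule <- function(target, regulators, clauses) {
  k <- nrow(regulators)
  stopifnot(k >= 1L, k <= 3L, length(clauses) >= 1L)
  clauses <- lapply(clauses, function(cl) sort(unique(as.integer(cl))))
  if (any(vapply(clauses, length, 0L) == 0L) ||
      any(unlist(clauses) < 1L) || any(unlist(clauses) > k)) {
    stop("clauses must be nonempty subsets of the regulator index set", call. = FALSE)
  }
  # canonical clause order for reproducible equality
  key <- vapply(clauses, function(cl) paste(cl, collapse = ","), "")
  clauses <- clauses[order(key)]
  clauses <- clauses[!duplicated(key[order(key)])]
  structure(list(target = target, regulators = regulators, clauses = clauses),
            class = "boolean_rule")
}

#' Human-readable form of a rule, e.g. `B* = (A and not C) or C`
#' @param rule A [boolean_rule()].
#' @return A single string.
#' @export
format_rule <- function(rule) {
  lit <- function(i) {
    g <- rule$regulators$gene[i]
    if (rule$regulators$sign[i] < 0) paste("not", g) else g
  }
  cl_txt <- vapply(rule$clauses, function(cl) {
    txt <- paste(vapply(cl, lit, ""), collapse = " and ")
    if (length(cl) > 1L) paste0("(", txt, ")") else txt
  }, "")
  paste0(rule$target, "* = ", paste(cl_txt, collapse = " or "))
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Enumerate the full rule space for a set of regulators
#'
#' For k regulators there are `2^k - 1` possible AND clauses (nonempty
#' regulator subsets) and hence `2^(2^k - 1) - 1` distinct OR-of-AND rules
#' (nonempty sets of clauses): 1 for k = 1, 7 for k = 2, and 127 for k = 3,
#' the most complex in-degree considered.
#'
#' @param regulators Data frame with columns `gene`, `sign`; 1-3 rows.
#' @param target Target gene label (default `"?"`; purely descriptive).
#' @return List of [boolean_rule()] objects.
#' @export
enumerate_rule_space <- function(regulators, target = "?") {
  k <- nrow(regulators)
  if (is.null(k) || k < 1L || k > 3L) {
    stop("rule enumeration requires 1 to 3 regulators (got ",
         if (is.null(k)) 0L else k, ")", call. = FALSE)
  }
  subsets <- lapply(seq_len(2L^k - 1L), function(m) which(bitwAnd(m, 2L^(seq_len(k) - 1L)) > 0L))
  n_subsets <- length(subsets)
  lapply(seq_len(2L^n_subsets - 1L), function(m) {
    chosen <- subsets[bitwAnd(m, 2L^(seq_len(n_subsets) - 1L)) > 0L]
    boolean_rule(target, regulators, chosen)
  })
}

#' Evaluate a rule on a network state
#'
#' Inputs are the regulator states, negated for inhibitors; the result is the
#' OR over clauses of the AND over clause inputs.
#'
#' @param rule A [boolean_rule()].
#' @param state Named 0/1 vector defining at least the rule's regulators.
#' @return A single bit (0 or 1).
#' @export
evaluate_rule <- function(rule, state) {
  bits <- state[rule$regulators$gene]
  if (anyNA(bits)) {
    stop("state missing regulator(s): ",
         paste(rule$regulators$gene[is.na(bits)], collapse = ", "), call. = FALSE)
  }
  inputs <- ifelse(rule$regulators$sign > 0, bits, 1L - bits)
  as.integer(any(vapply(rule$clauses, function(cl) all(inputs[cl] == 1L), TRUE)))
}

# Truth table of a rule over the raw (un-negated) states of its k regulators,
# indexed by 1 + sum_r state_r * 2^(r-1). Used by the compiled simulator.
rule_truth_table <- function(rule) {
  k <- nrow(rule$regulators)
  vapply(0:(2L^k - 1L), function(idx) {
    raw <- bitwAnd(bitwShiftR(idx, seq_len(k) - 1L), 1L)
    evaluate_rule(rule, setNames(raw, rule$regulators$gene))
  }, 0L)
}

#' Assemble an executable network model
#'
#' Pairs a prepared network with one rule per rule-bearing node. Nodes with
#' in-degree 0 have no rule and hold their (sample-derived) state, acting as
#' inputs.
#'
#' @param network A [signed_network()] with in-degree at most 3 everywhere
#'   (see [prepare_network()]).
#' @param rules Named list of [boolean_rule()] covering every node with
#'   in-degree >= 1.
#' @return A `network_model`.
#' @export
network_model <- function(network, rules) {
  indeg <- node_indegree(network)
  need <- names(indeg)[indeg >= 1L]
  missing <- setdiff(need, names(rules))
  if (length(missing)) {
    stop("no rule supplied for node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (node in need) {
    regs <- node_regulators(network, node)
    if (!all(rules[[node]]$regulators$gene %in% regs$gene)) {
      stop("rule for ", node, " uses genes that are not its network regulators",
           call. = FALSE)
    }
  }
  structure(list(network = network, rules = rules[need]), class = "network_model")
}

# Flatten a model into index/truth-table form for the C++ simulator.
compile_model <- function(model) {
  nodes <- model$network$nodes
  reg_idx <- vector("list", length(nodes))
  truth <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    rule <- model$rules[[nodes[i]]]
    if (is.null(rule)) {
      reg_idx[[i]] <- integer()
      truth[[i]] <- integer()
    } else {
      reg_idx[[i]] <- match(rule$regulators$gene, nodes) - 1L   # 0-based
      truth[[i]] <- rule_truth_table(rule)
    }
  }
  list(nodes = nodes, reg_idx = reg_idx, truth = truth)
}

#' Synchronous Boolean simulation
#'
#' All nodes update simultaneously each step; in-degree-0 nodes are constant.
#' The trajectory is deterministic and, being a walk on a finite state space,
#' always enters a fixed point or limit cycle.
#'
#' @param model A [network_model()].
#' @param init Named 0/1 vector over all network nodes.
#' @param steps Number of update steps (>= 1).
#' @return Integer matrix of `steps + 1` rows (trajectory, including the
#'   initial state) with one column per node.
#' @export
simulate_synchronous <- function(model, init, steps = 100L) {
  stopifnot(steps >= 1L)
  cm <- compile_model(model)
  n <- length(cm$nodes)
  cur <- init[cm$nodes]
  if (anyNA(cur)) stop("init must define every network node", call. = FALSE)
  traj <- matrix(0L, nrow = steps + 1L, ncol = n, dimnames = list(NULL, cm$nodes))
  traj[1L, ] <- as.integer(cur)
  for (t in seq_len(steps)) {
    prev <- traj[t, ]
    nxt <- prev
    for (i in seq_len(n)) {
      ri <- cm$reg_idx[[i]]
      if (length(ri)) {
        idx <- sum(prev[ri + 1L] * 2L^(seq_along(ri) - 1L)) + 1L
        nxt[i] <- cm$truth[[i]][idx]
      }
    }
    traj[t + 1L, ] <- nxt
  }
  traj
}

#' Steady-state summary of a trajectory
#'
#' Per node, the mean bit over the final `window` states: a fixed point gives
#' 0 or 1, a limit cycle its cycle average (once the window covers whole
#' periods).
#'
#' @param trajectory Matrix as returned by [simulate_synchronous()].
#' @param window Number of final states to average (>= 1, at most the number
#'   of trajectory rows).
#' @return Named numeric vector in `[0, 1]`.
#' @export
steady_state <- function(trajectory, window = 20L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > nrow(trajectory)) stop("window exceeds trajectory length", call. = FALSE)
  colMeans(trajectory[(nrow(trajectory) - window + 1L):nrow(trajectory), , drop = FALSE])
}

# Fast path: steady-state vector straight from a compiled model, optionally
# clamping one node (by 1-based index) to a fixed value every step.
steady_from_compiled <- function(cm, init_bits, steps = 100L, window = 20L,
                                 clamp_idx = -1L, clamp_val = 0L) {
  steady_sim_cpp(cm$reg_idx, cm$truth, as.integer(init_bits),
                 as.integer(steps), as.integer(window),
                 as.integer(clamp_idx) - 1L, as.integer(clamp_val))
}

#' Cap node in-degree at 3 by binarized-state correlation
#'
#' Nodes with more than 3 incoming edges keep the 3 regulators whose
#' binarized states correlate most strongly (absolute Pearson) with the
#' target's binarized state across all (layer, sample) states where both are
#' measured; ties break alphabetically. Regulators never co-measured with the
#' target rank last.
#'
#' @param network A [signed_network()].
#' @param states A [binarize()] result.
#' @return A [signed_network()] with all in-degrees at most 3.
#' @export
prepare_network <- function(network, states) {
  indeg <- node_indegree(network)
  if (all(indeg <= 3L)) return(network)
  gene_bits <- function(g) {
    vapply(states$states, function(st) {
      b <- st$bits[g]
      if (is.na(b)) NA_real_ else as.numeric(b)
    }, 0)
  }
  keep_rows <- logical(nrow(network$edges))
  for (node in network$nodes) {
    rows <- which(network$edges$target == node)
    if (length(rows) <= 3L) {
      keep_rows[rows] <- TRUE
      next
    }
    tb <- gene_bits(node)
    score <- vapply(network$edges$source[rows], function(reg) {
      rb <- gene_bits(reg)
      ok <- !is.na(tb) & !is.na(rb)
      if (sum(ok) < 2L || sd(tb[ok]) == 0 || sd(rb[ok]) == 0) return(0)
      abs(cor(tb[ok], rb[ok]))
    }, 0)
    ord <- order(-score, network$edges$source[rows])
    keep_rows[rows[ord[1:3]]] <- TRUE
  }
  signed_network(network$name, network$nodes,
                 network$edges[keep_rows, , drop = FALSE])
}
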
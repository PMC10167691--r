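# Independent oracles and small builders used across the test files. The
# oracles deliberately avoid the package's internal representations: rules are
# re-evaluated by parsing a textual logic formula, and attractors come from an
# exhaustive walk of the full state-transition graph.

# Evaluate an OR-of-AND rule by constructing the R logical expression from its
# clause structure and eval()ing it on the state, independent of
# evaluate_rule()'s index arithmetic.
oracle_eval_rule <- function(rule, state) {
  lit <- function(i) {
    g <- rule$regulators$gene[i]
    if (rule$regulators$sign[i] < 0) sprintf("(!`%s`)", g) else sprintf("`%s`", g)
  }
  clause_txt <- vapply(rule$clauses, function(cl)
    paste0("(", paste(vapply(cl, lit, ""), collapse = " & "), ")"), "")
  expr <- paste(clause_txt, collapse = " | ")
  env <- as.list(setNames(as.logical(state), names(state)))
  as.integer(eval(parse(text = expr), envir = env))
}

# Exhaustive attractor analysis of a synchronous Boolean model: follow the
# deterministic walk through the full 2^n state graph from `init`, detect the
# first revisited state, and average the states on the cycle.
oracle_attractor_mean <- function(model, init) {
  nodes <- model$network$nodes
  step <- function(state) {
    out <- state
    for (node in nodes) {
      rule <- model$rules[[node]]
      if (!is.null(rule)) out[node] <- oracle_eval_rule(rule, state)
    }
    out
  }
  seen <- list()
  key <- function(s) paste(s, collapse = "")
  state <- init[nodes]
  path <- list(state)
  seen[[key(state)]] <- 1L
  repeat {
    state <- step(state)
    k <- key(state)
    if (!is.null(seen[[k]])) {
      cycle <- path[seq(seen[[k]], length(path))]
      return(colMeans(do.call(rbind, cycle)))
    }
    path[[length(path) + 1L]] <- state
    seen[[k]] <- length(path)
  }
}

# Hand-written Benjamini-Hochberg step-up (monotonicity enforced), kept
# independent of stats::p.adjust.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Tiny builders ---------------------------------------------------------

make_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(source = r[[1]], target = r[[2]], sign = as.integer(r[[3]]),
               stringsAsFactors = FALSE)))
}

# Two-node activation chain A -> B with its only k=1 rule assigned.
chain_model <- function() {
  nw <- signed_network("chain", c("A", "B"), make_edges(list("A", "B", 1)))
  rule_b <- enumerate_rule_space(data.frame(gene = "A", sign = 1L), target = "B")[[1]]
  network_model(nw, list(B = rule_b))
}

# Minimal binarized_states object from a named-bit-vector list; each entry is
# one (layer, sample) training state.
states_from_bits <- function(bit_list, layer = "layer1") {
  states <- lapply(seq_along(bit_list), function(i)
    list(layer = layer, sample = paste0("s", i), bits = bit_list[[i]]))
  structure(list(bits = NULL, states = states, design = NULL),
            class = "binarized_states")
}

# In-memory graphml text for a small signed network (uses the package writer
# via a temp file when a file is needed; this builds the raw XML directly for
# reader tests).
toy_graphml <- function(path, sign_attr = "signal", b_sign = "a",
                        include_sign = TRUE) {
  sign_line <- if (include_sign)
    sprintf('<data key="d1">%s</data>', b_sign) else ""
  writeLines(sprintf('<?xml version="1.0" encoding="UTF-8"?>
<graphml xmlns="http://graphml.graphdrawing.org/xmlns">
  <key id="d1" for="edge" attr.name="%s" attr.type="string"/>
  <graph id="G" edgedefault="directed">
    <node id="A"/>
    <node id="B"/>
    <edge source="A" target="B">%s</edge>
  </graph>
</graphml>', sign_attr, sign_line), path)
  path
}

# Toy KGML with two gene entries, one relation, an activating gene -> group,
# and a compound bridge; used by the parser tests.
toy_kgml <- function(path, relation_subtype = "activation") {
  writeLines(sprintf('<?xml version="1.0"?>
<pathway name="path:toy" org="toy" number="1" title="ToyPathway">
  <entry id="1" name="toy:1" type="gene">
    <graphics name="GA"/>
  </entry>
  <entry id="2" name="toy:2" type="gene">
    <graphics name="GB"/>
  </entry>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="%s" value="--&gt;"/>
  </relation>
</pathway>', relation_subtype), path)
  path
}

kgml_with_group <- function(path) {
  writeLines('<?xml version="1.0"?>
<pathway name="path:toy2" org="toy" number="2" title="GroupPathway">
  <entry id="1" name="toy:x" type="gene"><graphics name="GX"/></entry>
  <entry id="2" name="toy:m1" type="gene"><graphics name="GM1"/></entry>
  <entry id="3" name="toy:m2" type="gene"><graphics name="GM2"/></entry>
  <entry id="4" name="undefined" type="group">
    <component id="2"/>
    <component id="3"/>
  </entry>
  <relation entry1="1" entry2="4" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
</pathway>', path)
  path
}

kgml_with_compound <- function(path) {
  writeLines('<?xml version="1.0"?>
<pathway name="path:toy3" org="toy" number="3" title="CompoundPathway">
  <entry id="1" name="toy:a" type="gene"><graphics name="GA"/></entry>
  <entry id="2" name="cpd:C1" type="compound"><graphics name="C1"/></entry>
  <entry id="3" name="toy:b" type="gene"><graphics name="GB"/></entry>
  <relation entry1="1" entry2="2" type="PCrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PCrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
</pathway>', path)
  path
}

# Small combined dataset built in code: two layers, two conditions, two
# samples each. Values chosen so gene bits and fold-changes are easy to state.
tiny_dataset <- function() {
  m1 <- matrix(c(2, 2, 8, 8,    # GA: low in c1, high in c2
                 8, 8, 2, 2,    # GB: high in c1, low in c2
                 5, 5, 5, 5),   # GC: constant
               nrow = 3, byrow = TRUE,
               dimnames = list(c("GA", "GB", "GC"),
                               c("c1_r1", "c1_r2", "c2_r1", "c2_r2")))
  m2 <- matrix(c(1, 3, 5, 7,
                 4, 4, 4, 4),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("GA", "GD"),
                               c("c1_r1", "c1_r2", "c2_r1", "c2_r2")))
  design <- data.frame(sample = c("c1_r1", "c1_r2", "c2_r1", "c2_r2"),
                       condition = c("c1", "c1", "c2", "c2"),
                       stringsAsFactors = FALSE)
  combined_dataset(list(omics_layer(m1, "layerA", transform = "none"),
                        omics_layer(m2, "layerB", transform = "none")),
                   design)
}

tiny_contrast <- function() {
  data.frame(name = "c1_vs_c2", condition_a = "c1", condition_b = "c2",
             stringsAsFactors = FALSE)
}
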
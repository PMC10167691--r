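# Ground-truthed synthetic fixtures: signed networks with known Boolean
# rules, and multiomics datasets generated from their attractors.

#' Generate a random signed network with in-degree at most 3
#'
#' Nodes are created in a random topological order; every node after the
#' first draws 1-3 regulators from the nodes before it, which guarantees a
#' weakly connected acyclic graph, no self-loops, and in-degree at most 3 by
#' construction (so every true rule lies in the enumerable space and
#' synchronous dynamics reach fixed points).
#'
#' @param n_nodes Number of genes (>= 2).
#' @param edge_density In `[0, 1]`; expected extra in-edges beyond the first
#'   (in-degree is `1 + Binomial(2, edge_density)`, capped by the available
#'   upstream nodes).
#' @param inhibition_fraction Probability an edge is inhibitory.
#' @param seed Integer seed.
#' @param name Pathway name.
#' @return A [signed_network()].
#' @export
generate_network <- function(n_nodes, edge_density = 0.3,
                             inhibition_fraction = 0.25, seed = 1L,
                             name = paste0("synthetic_", seed)) {
  stopifnot(n_nodes >= 2L, edge_density >= 0, edge_density <= 1)
  with_seed(seed, {
    nodes <- sprintf("G%02d", seq_len(n_nodes))
    src <- character()
    dst <- character()
    for (t in 2:n_nodes) {
      k <- min(t - 1L, 1L + rbinom(1L, 2L, edge_density))
      parents <- sample(nodes[seq_len(t - 1L)], k)
      src <- c(src, parents)
      dst <- c(dst, rep(nodes[t], k))
    }
    sgn <- ifelse(runif(length(src)) < inhibition_fraction, -1L, 1L)
    signed_network(name, nodes,
                   data.frame(source = src, target = dst, sign = sgn,
                              stringsAsFactors = FALSE))
  })
}

#' Generate a ground truth: network plus true rules
#'
#' Draws one rule uniformly from each rule-bearing node's enumerated space,
#' resampling the rule set (bounded retries) until no gene is constitutively
#' high under both the all-low and all-high input clamps. Constitutively-high
#' genes carry no between-condition signal, so data-driven binarization maps
#' them to 0 and their logic is unidentifiable from expression data; the
#' fixture excludes them by construction so that noiseless data determine the
#' true attractor bits exactly.
#'
#' @inheritParams generate_network
#' @return A `ground_truth` list: `network`, `rules` (named list of
#'   [boolean_rule()]), `model` (the executable [network_model()]), `seed`.
#' @export
generate_ground_truth <- function(n_nodes, edge_density = 0.3,
                                  inhibition_fraction = 0.25, seed = 1L,
                                  name = paste0("synthetic_", seed)) {
  network <- generate_network(n_nodes, edge_density, inhibition_fraction,
                              seed, name)
  indeg <- node_indegree(network)
  rule_nodes <- names(indeg)[indeg >= 1L]
  inputs <- names(indeg)[indeg == 0L]
  spaces <- lapply(rule_nodes, function(node)
    enumerate_rule_space(node_regulators(network, node), target = node))
  names(spaces) <- rule_nodes

  truth <- with_seed(derive_seed(seed, "true_rules"), {
    for (attempt in seq_len(100L)) {
      rules <- lapply(spaces, function(sp) sp[[sample.int(length(sp), 1L)]])
      model <- network_model(network, rules)
      cand <- structure(list(network = network, rules = rules, model = model,
                             seed = seed), class = "ground_truth")
      low <- condition_attractor(cand, setNames(rep(0L, length(inputs)), inputs))
      high <- condition_attractor(cand, setNames(rep(1L, length(inputs)), inputs))
      if (!any(low == 1L & high == 1L)) return(cand)
    }
    stop("could not draw a rule set without constitutively-high genes",
         call. = FALSE)
  })
  truth
}

# Attractor bits of the true model under a condition-specific clamping of the
# input (in-degree-0) nodes; remaining nodes start at 0. Acyclic networks
# reach a fixed point, so the steady state is exactly 0/1.
condition_attractor <- function(truth, input_bits, steps = 100L, window = 20L) {
  nodes <- truth$network$nodes
  init <- setNames(rep(0L, length(nodes)), nodes)
  init[names(input_bits)] <- as.integer(input_bits)
  cm <- compile_model(truth$model)
  ss <- steady_from_compiled(cm, init[cm$nodes], steps, window)
  setNames(as.integer(ss >= 0.5), cm$nodes)
}

#' Generate a synthetic multiomics dataset from a ground truth
#'
#' Conditions are defined by clamping the network's input (in-degree-0)
#' nodes, mirroring how signaling stimuli enter pathway models: condition 1
#' clamps all inputs to 0, condition 2 to 1, further conditions alternate
#' input bits. The true model's attractor under each condition becomes the
#' mean log2 abundance (bit 0 -> 4, bit 1 -> 8, placing the binarization
#' midpoint between classes), with additive Gaussian noise per sample and
#' per-layer gene dropout emulating partial layer overlap. Input nodes are
#' exempt from dropout so every layer's samples remain attributable to their
#' condition.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param n_layers Number of omics layers (default 3).
#' @param samples_per_condition Samples per condition per layer (default 4).
#' @param noise_sd Gaussian noise standard deviation on log2 abundance
#'   (default 0; noiseless).
#' @param dropout_per_layer Numeric vector (recycled to `n_layers`) of
#'   per-layer gene dropout fractions; default `c(0, 0.25, 0.25)` keeps one
#'   complete layer.
#' @param n_conditions Number of conditions (default 2).
#' @param null_mode If `TRUE`, generate a calibration-null dataset: the
#'   condition labels are arbitrary (no clamping difference) and every gene
#'   sits at a common baseline of 6 on the log2 scale, so genes are
#'   exchangeable and each gene's true per-layer (fold-change, CV) pair is a
#'   draw from the same distribution the permutation scheme pools over. This
#'   is the setting in which pooled-resampling p-values are calibrated; with
#'   gene-specific baselines the pool mixes heterogeneous CV scales (a known
#'   limitation of pooled nulls, discussed in the vignette).
#' @param seed Integer seed.
#' @return List with `dataset` ([combined_dataset()]), `states`
#'   ([binarize()] result), `design`, `contrasts`, `attractors` (bit matrix
#'   condition x gene), and `truth`.
#' @export
generate_multiomics <- function(truth, n_layers = 3L, samples_per_condition = 4L,
                                noise_sd = 0, dropout_per_layer = c(0, 0.25, 0.25),
                                n_conditions = 2L, null_mode = FALSE, seed = 1L) {
  stopifnot(n_conditions >= 2L, n_layers >= 1L)
  if (null_mode && noise_sd <= 0) {
    stop("null_mode requires noise_sd > 0 (a constant dataset has no pool)",
         call. = FALSE)
  }
  dropout_per_layer <- rep_len(dropout_per_layer, n_layers)
  if (all(dropout_per_layer >= 1)) stop("all layers fully dropped out", call. = FALSE)
  nodes <- truth$network$nodes
  indeg <- node_indegree(truth$network)
  inputs <- names(indeg)[indeg == 0L]

  conditions <- paste0("cond", seq_len(n_conditions))
  input_patterns <- lapply(seq_len(n_conditions), function(c) {
    # condition 1: all inputs low; condition 2: all high; beyond that,
    # alternate bits with a condition-specific phase. In null mode the
    # conditions are indistinguishable: all use the all-low clamp.
    bits <- if (null_mode) rep(0L, length(inputs)) else switch(as.character(c),
      "1" = rep(0L, length(inputs)),
      "2" = rep(1L, length(inputs)),
      (seq_along(inputs) + c) %% 2L)
    setNames(as.integer(bits), inputs)
  })
  attract <- t(vapply(input_patterns, function(p)
    condition_attractor(truth, p), setNames(integer(length(nodes)), nodes)))
  rownames(attract) <- conditions

  layer_names <- paste0("layer", seq_len(n_layers))
  with_seed(derive_seed(seed, "multiomics"), {
    layers <- list()
    for (d in seq_len(n_layers)) {
      droppable <- setdiff(nodes, inputs)
      dropped <- droppable[runif(length(droppable)) < dropout_per_layer[d]]
      genes <- setdiff(nodes, dropped)
      if (!length(genes)) genes <- inputs
      sample_ids <- character()
      cols <- list()
      for (c in seq_len(n_conditions)) {
        for (s in seq_len(samples_per_condition)) {
          sid <- sprintf("%s_r%d", conditions[c], s)
          mu <- if (null_mode) rep(6, length(genes)) else
            ifelse(attract[c, genes] == 1L, 8, 4)
          cols[[sid]] <- pmax(0, mu + rnorm(length(genes), sd = noise_sd))
          sample_ids <- c(sample_ids, sid)
        }
      }
      mat <- do.call(cbind, cols)
      rownames(mat) <- genes
      colnames(mat) <- sample_ids
      layers[[d]] <- omics_layer(mat, layer_names[d], transform = "none")
    }
    design <- data.frame(
      sample = unlist(lapply(conditions, function(c)
        sprintf("%s_r%d", c, seq_len(samples_per_condition)))),
      condition = rep(conditions, each = samples_per_condition),
      stringsAsFactors = FALSE)
    dataset <- combined_dataset(layers, design)
    pairs <- utils::combn(conditions, 2L)
    contrasts <- data.frame(
      name = apply(pairs, 2L, paste, collapse = "_vs_"),
      condition_a = pairs[1L, ], condition_b = pairs[2L, ],
      stringsAsFactors = FALSE)
    list(dataset = dataset, states = binarize(dataset), design = design,
         contrasts = contrasts, attractors = attract, truth = truth)
  })
}

#' Write a synthetic fixture bundle to disk in pipeline input formats
#'
#' Emits the network(s) as graphml, each layer as a TSV expression matrix,
#' the design and contrast matrices, and a ground-truth sidecar file listing
#' the true rules — the exact file set [run_pipeline()] consumes.
#'
#' @param fixture A [generate_multiomics()] result (or a list of them sharing
#'   design/contrasts; the first one's design is used).
#' @param dir Output directory.
#' @return Invisibly, a list of the written paths.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  fixtures <- if (!is.null(fixture$dataset)) list(fixture) else fixture
  dir.create(file.path(dir, "networks"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(networks = character(), layers = character())
  for (fx in fixtures) {
    p <- file.path(dir, "networks", paste0(fx$truth$network$name, ".graphml"))
    write_graphml(fx$truth$network, p)
    paths$networks <- c(paths$networks, p)
    writeLines(vapply(fx$truth$rules, format_rule, ""),
               file.path(dir, paste0(fx$truth$network$name,
                                     "_true_rules.txt")))
  }
  fx1 <- fixtures[[1L]]
  for (layer in names(fx1$dataset$layers)) {
    ly <- fx1$dataset$layers[[layer]]
    p <- file.path(dir, paste0(layer, ".tsv"))
    df <- data.frame(gene = rownames(ly$abundance), ly$abundance,
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths$layers[layer] <- p
  }
  utils::write.table(fx1$design, file.path(dir, "design.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fx1$contrasts, file.path(dir, "contrasts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths$design <- file.path(dir, "design.tsv")
  paths$contrasts <- file.path(dir, "contrasts.tsv")
  invisible(paths)
}
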
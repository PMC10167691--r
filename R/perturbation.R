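# In-silico perturbation importance scores, evidence/modulation scores, and
# permutation-derived pathway p-values.

#' Node importance by in-silico knock-in vs knockout
#'
#' For each of `n_rule_samples` concrete rule assignments (one rule drawn
#' uniformly per node from its equivalent rule set, seeded), every node g is
#' perturbed in every training state: the network is simulated once with g
#' clamped to 0 (knockout) and once clamped to 1 (knock-in). The importance
#' of g is the mean over rule samples of the summed absolute steady-state
#' differences between the two perturbations, over all samples and all nodes
#' other than g itself, so the score quantifies g's influence over the rest
#' of the network. Scores depend only on topology and rules, never on a
#' contrast.
#'
#' @param network A prepared [signed_network()].
#' @param ers Named list of equivalent rule sets (see [local_search()]); a
#'   plain named list of [boolean_rule()] is also accepted (singleton ERSs).
#' @param states A [binarize()] result (the training states).
#' @param n_rule_samples Number of ERS draws to average over (default 10).
#' @param seed Integer seed for the ERS draws.
#' @param steps,window Simulation settings.
#' @return Object of class `importance_scores`: named nonnegative numeric
#'   vector over network nodes, with attributes `n_rule_samples`, `steps`,
#'   `window`.
#' @export
importance_scores <- function(network, ers, states, n_rule_samples = 10L,
                              seed = 1L, steps = 100L, window = 20L) {
  if (n_rule_samples < 1L) stop("n_rule_samples must be >= 1", call. = FALSE)
  if (!length(states$states)) stop("no training states", call. = FALSE)
  nodes <- network$nodes
  n <- length(nodes)
  indeg <- node_indegree(network)
  rule_nodes <- names(indeg)[indeg >= 1L]

  candidates <- lapply(rule_nodes, function(node) {
    e <- ers[[node]]
    if (is.null(e)) stop("no ERS for node ", node, call. = FALSE)
    if (inherits(e, "boolean_rule")) list(e) else e$rules
  })
  names(candidates) <- rule_nodes
  cand_tables <- lapply(candidates, function(rs) lapply(rs, rule_truth_table))

  inits <- lapply(states$states, function(st) {
    bits <- st$bits[nodes]
    bits[is.na(bits)] <- 0L
    as.integer(bits)
  })

  reg_idx <- rep(list(integer()), n)
  for (node in rule_nodes) {
    i <- match(node, nodes)
    reg_idx[[i]] <- match(node_regulators(network, node)$gene, nodes) - 1L
  }

  total <- setNames(numeric(n), nodes)
  with_seed(seed, {
    for (s in seq_len(n_rule_samples)) {
      truth <- rep(list(integer()), n)
      for (node in rule_nodes) {
        i <- match(node, nodes)
        picks <- cand_tables[[node]]
        truth[[i]] <- picks[[sample.int(length(picks), 1L)]]
      }
      for (g in seq_len(n)) {
        for (init in inits) {
          O <- steady_sim_cpp(reg_idx, truth, init, as.integer(steps),
                              as.integer(window), g - 1L, 0L)
          Z <- steady_sim_cpp(reg_idx, truth, init, as.integer(steps),
                              as.integer(window), g - 1L, 1L)
          total[g] <- total[g] + sum(abs(O[-g] - Z[-g]))
        }
      }
    }
  })
  structure(total / n_rule_samples, class = "importance_scores",
            n_rule_samples = as.integer(n_rule_samples),
            steps = as.integer(steps), window = as.integer(window))
}

#' Cross-layer evidence score of a gene
#'
#' The number of omics layers in which the gene is present with nonzero
#' measured abundance in at least one sample: 0 (unmeasured pathway node) up
#' to D, the number of layers.
#'
#' @param gene Gene symbol.
#' @param dataset A [combined_dataset()].
#' @return Integer in `[0, D]`.
#' @export
evidence_score <- function(gene, dataset) {
  gene <- normalize_gene_ids(gene)
  sum(vapply(dataset$layers, function(ly) {
    gene %in% rownames(ly$abundance) && any(ly$abundance[gene, ] != 0)
  }, TRUE))
}

#' Node modulation score for one gene and contrast
#'
#' Combines the topological importance of a gene with the data's evidence of
#' its condition-specific change:
#' `M_g = I_g * E_g * sum_d |FC_{C,d,g}| * CV_{d,g}`,
#' summing over omics layers d, where FC is the contrast log fold-change and
#' CV the coefficient of variation in layer d (layers not measuring g
#' contribute 0). Absolute fold-change is used so up- and down-regulation
#' both count as modulation.
#'
#' @param gene Gene symbol.
#' @param contrast Row/list with `condition_a`, `condition_b`.
#' @param importance An [importance_scores()] result covering `gene` (genes
#'   absent from it score importance 0).
#' @param dataset A [combined_dataset()].
#' @return A single nonnegative number.
#' @export
node_modulation <- function(gene, contrast, importance, dataset) {
  gene <- normalize_gene_ids(gene)
  I_g <- if (gene %in% names(importance)) unclass(importance)[[gene]] else 0
  E_g <- evidence_score(gene, dataset)
  if (I_g == 0 || E_g == 0) return(0)
  layer_sum <- 0
  for (layer in names(dataset$layers)) {
    if (!(gene %in% rownames(dataset$layers[[layer]]$abundance))) next
    fc <- fold_change(dataset, contrast, layer)[[gene]]
    cv <- variability(dataset, contrast, layer)[[gene]]
    layer_sum <- layer_sum + abs(fc) * cv
  }
  I_g * E_g * layer_sum
}

# Vectorized components table for a whole pathway (one fold_change /
# variability call per layer instead of per gene).
modulation_components <- function(network, contrast, importance, dataset) {
  genes <- network$nodes
  I_g <- setNames(numeric(length(genes)), genes)
  common <- intersect(genes, names(importance))
  I_g[common] <- unclass(importance)[common]
  E_g <- vapply(genes, evidence_score, 0, dataset = dataset)
  layer_sum <- setNames(numeric(length(genes)), genes)
  per_layer <- list()
  for (layer in names(dataset$layers)) {
    fc <- fold_change(dataset, contrast, layer)
    cv <- variability(dataset, contrast, layer)
    measured <- genes %in% rownames(dataset$layers[[layer]]$abundance)
    contrib <- numeric(length(genes))
    g_in <- intersect(genes, names(fc))
    contrib[match(g_in, genes)] <- abs(fc[g_in]) * cv[g_in]
    contrib[!measured] <- 0
    layer_sum <- layer_sum + contrib
    per_layer[[layer]] <- data.frame(gene = genes, measured = measured,
                                     fc = ifelse(measured, fc[genes], 0),
                                     cv = ifelse(measured, cv[genes], 0),
                                     stringsAsFactors = FALSE)
  }
  data.frame(gene = genes, importance = I_g, evidence = E_g,
             layer_term = layer_sum,
             modulation = I_g * E_g * layer_sum,
             row.names = NULL, stringsAsFactors = FALSE) ->
    tab
  attr(tab, "per_layer") <- per_layer
  tab
}

#' Modulation table for every node of a pathway
#'
#' @inheritParams pathway_modulation
#' @param importance An [importance_scores()] result.
#' @param dataset A [combined_dataset()].
#' @return Data frame (gene, importance, evidence, layer_term, modulation).
#' @export
modulation_table <- function(pathway, contrast, importance, dataset) {
  tab <- modulation_components(pathway, contrast, importance, dataset)
  attr(tab, "per_layer") <- NULL
  tab
}

#' Pathway modulation score
#'
#' The sum of node modulation scores over the pathway's nodes (genes absent
#' from the data contribute 0 through their evidence score).
#'
#' @param pathway A [signed_network()].
#' @param contrast Row/list with `condition_a`, `condition_b`.
#' @param modulation A [modulation_table()] for this pathway and contrast.
#' @return A single nonnegative number.
#' @export
pathway_modulation <- function(pathway, contrast, modulation) {
  sum(modulation$modulation[modulation$gene %in% pathway$nodes])
}

#' Permutation p-value for a pathway's modulation score
#'
#' The null keeps the pathway's importance and evidence scores fixed and
#' replaces each gene's per-layer (fold-change, coefficient-of-variation)
#' pair with a pair drawn uniformly with replacement from the gene-wise pool
#' of the same contrast and layer over the whole dataset; pairs are sampled
#' jointly to preserve their empirical dependence. Replicate pathway
#' modulation scores form the null distribution; the observed score is
#' converted to a z-score and a one-sided upper-tail p-value
#' `p = 1 - pnorm(z)`. A degenerate null (sd 0) gives p = 0.5 when the
#' observed score equals the null value, else 0 or 1 by sign.
#'
#' @param pathway A [signed_network()].
#' @param contrast Row/list with `name`, `condition_a`, `condition_b`.
#' @param importance An [importance_scores()] result for this pathway.
#' @param dataset A [combined_dataset()].
#' @param n_permutations Number of null replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @return A `pathway_result` list: `pathway`, `contrast`, `n_genes`,
#'   `modulation_score`, `null_mean`, `null_sd`, `z`, `p_value`, and the
#'   per-node `modulation` table.
#' @export
permutation_pvalue <- function(pathway, contrast, importance, dataset,
                               n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100L) stop("n_permutations must be >= 100", call. = FALSE)
  comp <- modulation_components(pathway, contrast, importance, dataset)
  per_layer <- attr(comp, "per_layer")
  M_p <- sum(comp$modulation)

  # sampling pools: per layer, the |FC|*CV products over all genes measured
  # in that layer (jointly sampled pairs enter only through this product)
  pools <- lapply(names(dataset$layers), function(layer) {
    fc <- fold_change(dataset, contrast, layer)
    cv <- variability(dataset, contrast, layer)
    measured <- rownames(dataset$layers[[layer]]$abundance)
    abs(fc[measured]) * cv[measured]
  })
  names(pools) <- names(dataset$layers)
  if (any(vapply(pools, length, 0L) == 0L)) {
    stop("empty sampling pool for a layer", call. = FALSE)
  }

  weights <- comp$importance * comp$evidence
  null_scores <- with_seed(seed, {
    reps <- numeric(n_permutations)
    for (layer in names(dataset$layers)) {
      measured <- per_layer[[layer]]$measured
      if (!any(measured)) next
      w <- weights[measured]
      pool <- pools[[layer]]
      draws <- matrix(pool[sample.int(length(pool), n_permutations * sum(measured),
                                      replace = TRUE)],
                      nrow = n_permutations)
      reps <- reps + as.numeric(draws %*% w)
    }
    reps
  })

  mu <- mean(null_scores)
  sdev <- sd(null_scores)
  if (sdev == 0) {
    z <- if (M_p == mu) 0 else sign(M_p - mu) * Inf
    p <- if (M_p == mu) 0.5 else if (M_p > mu) 0 else 1
  } else {
    z <- (M_p - mu) / sdev
    p <- 1 - pnorm(z)
  }
  structure(list(pathway = pathway$name, contrast = contrast$name %||% NA_character_,
                 n_genes = length(pathway$nodes), modulation_score = M_p,
                 null_mean = mu, null_sd = sdev, z = z, p_value = p,
                 modulation = modulation_table(pathway, contrast, importance,
                                               dataset)),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("pathway_result %s [%s]: M_p = %.4g, z = %.3f, p = %.4g\n",
              x$pathway, x$contrast, x$modulation_score, x$z, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with monotonicity enforcement),
#' preserving input order. Input p-values are validated to lie in `[0, 1]`.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, elementwise >= the raw ones.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}
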
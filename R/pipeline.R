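# End-to-end orchestration: prepare networks, infer rules, score
# perturbations, pathway statistics, and write run artifacts.

#' Pipeline run configuration
#'
#' @param networks_dir Directory containing pathway files (`.graphml`, and/or
#'   KGML `.xml`).
#' @param layers Named character vector: layer name -> expression matrix path.
#' @param design_path Path to the design matrix (sample, condition).
#' @param contrasts_path Path to the contrast matrix (name, condition_a,
#'   condition_b).
#' @param out_dir Output directory (created if needed).
#' @param transforms Named character vector of per-layer transforms (see
#'   [load_layer()]); layers not named default to `"none"`.
#' @param min_overlap Pathway filter: minimum genes shared with the data.
#' @param ga GA settings, a [ga_config()].
#' @param n_rule_samples ERS draws for importance scoring.
#' @param n_permutations Permutation null replicates.
#' @param steps,window Simulation settings.
#' @param seed Global seed, fanned out to each stochastic stage via
#'   [derive_seed()].
#' @return A `run_config` list.
#' @export
run_config <- function(networks_dir, layers, design_path, contrasts_path,
                       out_dir, transforms = NULL, min_overlap = 5L,
                       ga = ga_config(), n_rule_samples = 10L,
                       n_permutations = 1000L, steps = 100L, window = 20L,
                       seed = 1L) {
  for (p in c(networks_dir, unname(layers), design_path, contrasts_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("layers must be a named vector (layer name -> path)", call. = FALSE)
  }
  structure(list(networks_dir = networks_dir, layers = layers,
                 design_path = design_path, contrasts_path = contrasts_path,
                 out_dir = out_dir, transforms = transforms,
                 min_overlap = as.integer(min_overlap), ga = ga,
                 n_rule_samples = as.integer(n_rule_samples),
                 n_permutations = as.integer(n_permutations),
                 steps = as.integer(steps), window = as.integer(window),
                 seed = as.integer(seed)),
            class = "run_config")
}

load_config_dataset <- function(config) {
  design <- read_design(config$design_path)
  layers <- lapply(names(config$layers), function(nm) {
    tr <- config$transforms[[nm]] %||% "none"
    load_layer(config$layers[[nm]], nm, transform = tr)
  })
  combined_dataset(layers, design)
}

read_networks_dir <- function(dir) {
  gml <- list.files(dir, pattern = "\\.graphml$", full.names = TRUE)
  kgml <- list.files(dir, pattern = "\\.(kgml|xml)$", full.names = TRUE)
  c(lapply(gml, read_graphml), lapply(kgml, parse_kgml))
}

#' Run the full pipeline
#'
#' Three stages per retained pathway: (1) preparation — networks are read,
#' filtered by gene overlap with the data, and in-degree-capped; (2) rule
#' inference — genetic algorithm plus node-local exhaustive search yielding
#' equivalent rule sets; (3) scoring — in-silico perturbation importance,
#' per-contrast node modulation tables, pathway modulation scores and
#' permutation p-values with Benjamini-Hochberg adjustment within each
#' contrast. All outputs are written under `config$out_dir`; a rerun with the
#' same config and seed reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (the pathway results data frame),
#'   `ers` and `importance` per pathway, and the output `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- load_config_dataset(config)
  contrasts <- read_contrasts(config$contrasts_path)
  missing_cond <- setdiff(unique(c(contrasts$condition_a, contrasts$condition_b)),
                          unique(dataset$design$condition))
  if (length(missing_cond)) {
    stop("contrast condition(s) absent from design: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  networks <- read_networks_dir(config$networks_dir)
  networks <- filter_pathways(networks, dataset$gene_universe,
                              min_overlap = config$min_overlap)
  if (!length(networks)) {
    stop("no pathway passed the overlap filter (min_overlap = ",
         config$min_overlap, ")", call. = FALSE)
  }
  states <- binarize(dataset)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  all_ers <- list()
  all_importance <- list()
  rows <- list()
  for (nw in networks) {
    nw_prep <- prepare_network(nw, states)
    ga_cfg <- config$ga
    ga_cfg$seed <- derive_seed(config$seed, paste0("ga:", nw$name))
    inf <- infer_rules(nw_prep, states, ga_cfg,
                       steps = config$steps, window = config$window)
    all_ers[[nw$name]] <- inf$ers
    write_ers(inf$ers, file.path(config$out_dir,
                                 paste0(sanitize_name(nw$name), "_rules.txt")))
    imp <- importance_scores(nw_prep, inf$ers, states,
                             n_rule_samples = config$n_rule_samples,
                             seed = derive_seed(config$seed, paste0("imp:", nw$name)),
                             steps = config$steps, window = config$window)
    all_importance[[nw$name]] <- imp

    annotations <- list(importance = setNames(as.numeric(imp), names(imp)))
    for (ci in seq_len(nrow(contrasts))) {
      contrast <- contrasts[ci, ]
      res <- permutation_pvalue(nw_prep, contrast, imp, dataset,
                                n_permutations = config$n_permutations,
                                seed = derive_seed(config$seed,
                                                   paste0("perm:", nw$name, ":",
                                                          contrast$name)))
      mod_path <- file.path(config$out_dir,
                            sprintf("%s_%s_modulation.csv",
                                    sanitize_name(nw$name),
                                    sanitize_name(contrast$name)))
      write.csv(res$modulation, mod_path, row.names = FALSE)
      for (layer in names(dataset$layers)) {
        fc <- fold_change(dataset, contrast, layer)
        key <- sprintf("fc_%s_%s", sanitize_name(contrast$name), layer)
        annotations[[key]] <- fc[intersect(names(fc), nw_prep$nodes)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = nw$name, contrast = contrast$name, n_genes = res$n_genes,
        overlap = nw$overlap, modulation_score = res$modulation_score,
        null_mean = res$null_mean, null_sd = res$null_sd, z = res$z,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
    write_annotated_graphml(nw_prep, annotations,
                            file.path(config$out_dir,
                                      paste0(sanitize_name(nw$name),
                                             "_annotated.graphml")))
  }

  results <- do.call(rbind, rows)
  results$p_adjusted <- NA_real_
  for (cn in unique(results$contrast)) {
    sel <- results$contrast == cn
    results$p_adjusted[sel] <- bh_adjust(results$p_value[sel])
  }
  results_path <- file.path(config$out_dir, "pathway_results.csv")
  write.csv(results, results_path, row.names = FALSE)

  manifest <- list(
    inputs = list(networks_dir = config$networks_dir,
                  layers = as.list(config$layers),
                  design = config$design_path,
                  contrasts = config$contrasts_path),
    settings = list(min_overlap = config$min_overlap,
                    ga = unclass(config$ga),
                    n_rule_samples = config$n_rule_samples,
                    n_permutations = config$n_permutations,
                    steps = config$steps, window = config$window),
    seed = config$seed,
    pathways = vapply(networks, `[[`, "", "name"),
    versions = list(boolomics = as.character(utils::packageVersion("boolomics")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(results = results, ers = all_ers, importance = all_importance,
                 manifest = manifest, results_path = results_path))
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Download KEGG pathways as KGML (optional, needs network access)
#'
#' Fetches KGML files via the KEGG REST API and writes a listing manifest.
#' Never invoked by the test suite; all parsing operates on local files.
#'
#' @param pathway_ids Character vector of KEGG pathway ids (e.g.
#'   `"hsa04668"`); if `NULL`, the organism's full pathway list is fetched
#'   first.
#' @param organism Three-letter KEGG organism code (default `"hsa"`).
#' @param out_dir Output directory.
#' @param retries Download attempts per file before failing.
#' @return Invisibly, a data frame listing the written files.
#' @export
fetch_kegg <- function(pathway_ids = NULL, organism = "hsa", out_dir,
                       retries = 2L) {
  base <- "https://rest.kegg.jp"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  try_download <- function(url, dest) {
    for (i in seq_len(retries)) {
      ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0L,
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (ok) return(TRUE)
    }
    FALSE
  }
  if (is.null(pathway_ids)) {
    listing <- tempfile()
    if (!try_download(sprintf("%s/list/pathway/%s", base, organism), listing)) {
      stop("could not reach the KEGG API", call. = FALSE)
    }
    pathway_ids <- sub("^path:", "", read.delim(listing, header = FALSE)[[1L]])
  }
  written <- character()
  for (pid in pathway_ids) {
    dest <- file.path(out_dir, paste0(pid, ".xml"))
    if (!try_download(sprintf("%s/get/%s/kgml", base, pid), dest)) {
      unlink(dest)
      stop("download failed for pathway ", pid, call. = FALSE)
    }
    written <- c(written, dest)
  }
  manifest <- data.frame(pathway = pathway_ids, file = written,
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "kgml_manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
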
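# Multiomics expression layers: loading, transformation, binarization,
# contrast fold-changes and variability.

#' Load one omics layer from a delimited text matrix
#'
#' Expects genes in rows (first column = gene symbol) and samples in columns,
#' tab- or comma-separated. Gene rows whose raw median is 0 are discarded
#' before transformation (uninformative near-absent features). Supported
#' transforms: `log2p1` = log2(x + 1); `log2rpm` = log2(reads-per-million + 1)
#' computed per sample; `none` = values used as-is (must be nonnegative,
#' assumed already log-scale).
#'
#' @param path Delimited text file (TSV or CSV, auto-detected).
#' @param layer_name Label for the layer, e.g. `"transcriptomics"`.
#' @param transform One of `"log2p1"`, `"log2rpm"`, `"none"`.
#' @return An `omics_layer`: list with `layer_name`, `abundance` (gene x
#'   sample numeric matrix, log scale, values >= 0), `sample_ids`.
#' @export
load_layer <- function(path, layer_name, transform = c("log2p1", "log2rpm", "none")) {
  transform <- match.arg(transform)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- normalize_gene_ids(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(mat, 2L, function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    stop("non-numeric values in ", path, " (column ",
         paste(colnames(mat)[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene rows in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  rownames(mat) <- genes
  omics_layer(mat, layer_name, transform = transform)
}

#' Construct an omics layer from a numeric matrix
#'
#' Programmatic counterpart of [load_layer()]; applies the same median-zero
#' row filter and transform.
#'
#' @param abundance Numeric gene x sample matrix with rownames (gene symbols)
#'   and colnames (sample ids).
#' @inheritParams load_layer
#' @return An `omics_layer`.
#' @export
omics_layer <- function(abundance, layer_name,
                        transform = c("log2p1", "log2rpm", "none")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(abundance), is.numeric(abundance),
            !is.null(rownames(abundance)), !is.null(colnames(abundance)))
  if (anyDuplicated(colnames(abundance))) {
    stop("duplicate sample ids in layer ", layer_name, call. = FALSE)
  }
  keep <- apply(abundance, 1L, median) != 0
  abundance <- abundance[keep, , drop = FALSE]
  mat <- switch(transform,
    log2p1 = log2(abundance + 1),
    log2rpm = {
      rpm <- sweep(abundance, 2L, colSums(abundance), "/") * 1e6
      log2(rpm + 1)
    },
    none = abundance)
  if (any(mat < 0)) {
    stop("layer ", layer_name, ": negative abundances after transform; ",
         "log-scale values must be >= 0", call. = FALSE)
  }
  rownames(mat) <- normalize_gene_ids(rownames(mat))
  structure(list(layer_name = layer_name, abundance = mat,
                 sample_ids = colnames(mat)),
            class = "omics_layer")
}

#' Combine omics layers with a shared experimental design
#'
#' @param layers List of `omics_layer` objects (one per omics type).
#' @param design Data frame with columns `sample`, `condition`. Every sample
#'   id appearing in any layer must be present; conditions are matched across
#'   layers.
#' @return A `combined_dataset`: list with `layers` (named by layer_name),
#'   `design`, `gene_universe` (union of layer genes).
#' @export
combined_dataset <- function(layers, design) {
  stopifnot(length(layers) >= 1L, all(c("sample", "condition") %in% names(design)))
  names(layers) <- vapply(layers, `[[`, "", "layer_name")
  if (anyDuplicated(names(layers))) stop("duplicate layer names", call. = FALSE)
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  for (ly in layers) {
    missing <- setdiff(ly$sample_ids, design$sample)
    if (length(missing)) {
      stop("layer ", ly$layer_name, ": samples absent from design: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(layers = layers, design = design,
                 gene_universe = sort(unique(unlist(
                   lapply(layers, function(l) rownames(l$abundance)))))),
            class = "combined_dataset")
}

#' Binarize a combined multiomics dataset
#'
#' Per gene and per layer, the threshold is the midpoint of the gene's (min,
#' max) across that layer's samples; values strictly above the threshold
#' become 1, others 0 (constant genes are all-0). Midpoint thresholding is
#' scale-robust for log data and invariant to adding a constant. A
#' measured-mask records which genes each layer profiles; bits are only ever
#' defined for measured genes.
#'
#' @param dataset A [combined_dataset()].
#' @return A `binarized_states` object: list with `bits` (per layer, gene x
#'   sample 0/1 matrix over that layer's genes), `states` (flat list of
#'   per-(layer, sample) named bit vectors), and `design`.
#' @export
binarize <- function(dataset) {
  stopifnot(inherits(dataset, "combined_dataset"))
  bits <- lapply(dataset$layers, function(ly) {
    lo <- apply(ly$abundance, 1L, min)
    hi <- apply(ly$abundance, 1L, max)
    thr <- (lo + hi) / 2
    b <- (ly$abundance > thr) * 1L
    storage.mode(b) <- "integer"
    b
  })
  states <- list()
  for (layer_name in names(bits)) {
    b <- bits[[layer_name]]
    for (s in colnames(b)) {
      states[[length(states) + 1L]] <- list(
        layer = layer_name, sample = s,
        bits = setNames(b[, s], rownames(b)))
    }
  }
  structure(list(bits = bits, states = states, design = dataset$design),
            class = "binarized_states")
}

condition_samples <- function(dataset, condition) {
  dataset$design$sample[dataset$design$condition == condition]
}

#' Contrast fold-changes for one layer
#'
#' Log fold-change per gene: mean log-abundance over samples of
#' `condition_a` minus the mean over `condition_b`, within the given layer.
#' Genes not measured in the layer get 0.
#'
#' @param dataset A [combined_dataset()].
#' @param contrast List or row with `condition_a`, `condition_b`.
#' @param layer Layer name.
#' @return Named numeric vector over the dataset's gene universe.
#' @export
fold_change <- function(dataset, contrast, layer) {
  ly <- dataset$layers[[layer]]
  if (is.null(ly)) stop("unknown layer: ", layer, call. = FALSE)
  sa <- intersect(condition_samples(dataset, contrast$condition_a), ly$sample_ids)
  sb <- intersect(condition_samples(dataset, contrast$condition_b), ly$sample_ids)
  if (!length(sa) || !length(sb)) {
    stop("contrast condition with zero samples in layer ", layer, call. = FALSE)
  }
  fc <- rowMeans(ly$abundance[, sa, drop = FALSE]) -
    rowMeans(ly$abundance[, sb, drop = FALSE])
  out <- setNames(numeric(length(dataset$gene_universe)), dataset$gene_universe)
  out[names(fc)] <- fc
  out
}

#' Per-gene variability (coefficient of variation) for one layer
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of the
#' gene's log-abundance over the union of the two contrast conditions'
#' samples. Zero mean, constant genes, or genes unmeasured in the layer give
#' 0.
#'
#' @inheritParams fold_change
#' @return Named nonnegative numeric vector over the gene universe.
#' @export
variability <- function(dataset, contrast, layer) {
  ly <- dataset$layers[[layer]]
  if (is.null(ly)) stop("unknown layer: ", layer, call. = FALSE)
  sa <- intersect(condition_samples(dataset, contrast$condition_a), ly$sample_ids)
  sb <- intersect(condition_samples(dataset, contrast$condition_b), ly$sample_ids)
  if (!length(sa) || !length(sb)) {
    stop("contrast condition with zero samples in layer ", layer, call. = FALSE)
  }
  sub <- ly$abundance[, union(sa, sb), drop = FALSE]
  mu <- rowMeans(sub)
  sdev <- apply(sub, 1L, sd)
  cv <- ifelse(mu == 0, 0, sdev / mu)
  cv[is.na(cv)] <- 0
  out <- setNames(numeric(length(dataset$gene_universe)), dataset$gene_universe)
  out[names(cv)] <- abs(cv)
  out
}

#' Read a design matrix (sample, condition) from delimited text
#'
#' @param path Two-column TSV/CSV with a header row.
#' @return Data frame with columns `sample`, `condition`.
#' @export
read_design <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  data.frame(sample = as.character(df[[1L]]), condition = as.character(df[[2L]]),
             stringsAsFactors = FALSE)
}

#' Read a contrast matrix (name, condition_a, condition_b) from delimited text
#'
#' @param path Three-column TSV/CSV with a header row.
#' @return Data frame with columns `name`, `condition_a`, `condition_b`.
#' @export
read_contrasts <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 3L)
  out <- data.frame(name = as.character(df[[1L]]),
                    condition_a = as.character(df[[2L]]),
                    condition_b = as.character(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$name)) stop("duplicate contrast names", call. = FALSE)
  if (any(out$condition_a == out$condition_b)) {
    stop("a contrast must compare two distinct conditions", call. = FALSE)
  }
  out
}
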
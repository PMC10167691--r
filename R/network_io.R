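# Prior-knowledge network (PKN) input/output: signed directed gene graphs in
# graphml, and KEGG KGML conversion.

#' Construct a signed directed network
#'
#' A `signed_network` is the package's representation of a prior-knowledge
#' signaling pathway: a set of gene symbols plus directed edges, each carrying
#' a sign (+1 activation, -1 inhibition). Construction performs the standard
#' preparation steps: gene identifiers are uppercased and stripped of
#' whitespace, duplicate nodes are collapsed, self-loops are removed (they
#' would admit degenerate self-sustaining Boolean rules), and duplicate edges
#' are collapsed keeping the first-seen sign.
#'
#' @param name Pathway identifier.
#' @param nodes Character vector of gene symbols.
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (sign in `{-1, +1}`). May have zero rows.
#' @return An object of class `signed_network` with fields `name`, `nodes`,
#'   `edges` and an `overlap` slot filled by [filter_pathways()].
#' @export
signed_network <- function(name, nodes, edges = NULL) {
  nodes <- unique(normalize_gene_ids(nodes))
  if (length(nodes) == 0L) {
    stop("empty network: a signed_network needs at least one node", call. = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("source", "target", "sign") %in% names(edges)))
    edges$source <- normalize_gene_ids(edges$source)
    edges$target <- normalize_gene_ids(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge signs must be +1 (activation) or -1 (inhibition)", call. = FALSE)
    }
    missing <- setdiff(unique(c(edges$source, edges$target)), nodes)
    if (length(missing)) {
      stop("edge endpoints absent from node set: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    edges <- edges[edges$source != edges$target, , drop = FALSE]   # self-loops
    key <- paste(edges$source, edges$target, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]               # first-seen sign
    rownames(edges) <- NULL
  }
  structure(list(name = as.character(name), nodes = nodes,
                 edges = edges[, c("source", "target", "sign")],
                 overlap = NA_integer_),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network '%s': %d nodes, %d edges (%d inhibitory)\n",
              x$name, length(x$nodes), nrow(x$edges), sum(x$edges$sign < 0)))
  invisible(x)
}

#' In-degrees of network nodes
#'
#' @param network A [signed_network()].
#' @return Named integer vector over all nodes.
#' @export
node_indegree <- function(network) {
  deg <- table(factor(network$edges$target, levels = network$nodes))
  setNames(as.integer(deg), network$nodes)
}

# Regulators of a node as a data.frame(gene, sign), ordered as in the edge list.
node_regulators <- function(network, node) {
  e <- network$edges[network$edges$target == node, , drop = FALSE]
  data.frame(gene = e$source, sign = e$sign, stringsAsFactors = FALSE)
}

sign_from_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("a", "activation", "+", "1")] <- 1L
  out[x %in% c("i", "inhibition", "-", "-1")] <- -1L
  out
}

#' Read a signed network from a graphml file
#'
#' Edge signs are taken from an edge attribute named `signal` or
#' `interaction`, with values `a`/`activation`/`+` mapping to +1 and
#' `i`/`inhibition`/`-` mapping to -1. Edges without a recognizable sign
#' default to activation with a warning.
#'
#' @param path Path to a graphml file.
#' @param name Pathway name; defaults to the file name without extension.
#' @return A [signed_network()].
#' @export
read_graphml <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0L) {
    stop("empty network: graphml file has zero nodes: ", path, call. = FALSE)
  }
  vattrs <- igraph::vertex_attr_names(g)
  labels <- if ("name" %in% vattrs) {
    igraph::V(g)$name
  } else if ("id" %in% vattrs) {
    igraph::V(g)$id
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  eattrs <- igraph::edge_attr_names(g)
  sign_attr <- intersect(c("signal", "interaction"), eattrs)
  if (nrow(el) > 0L && length(sign_attr)) {
    signs <- sign_from_label(igraph::edge_attr(g, sign_attr[1L]))
  } else {
    signs <- rep(NA_integer_, nrow(el))
  }
  if (anyNA(signs) && nrow(el) > 0L) {
    warning(sum(is.na(signs)), " edge(s) without a recognized sign in ",
            basename(path), "; defaulting to activation (+1)", call. = FALSE)
    signs[is.na(signs)] <- 1L
  }
  edges <- data.frame(source = labels[el[, 1L]], target = labels[el[, 2L]],
                      sign = signs, stringsAsFactors = FALSE)
  signed_network(name %||% sub("\\.graphml$", "", basename(path)),
                 nodes = labels, edges = edges)
}

#' Write a signed network to graphml
#'
#' The edge sign is written as an edge attribute `signal` with values `"a"`
#' (activation) and `"i"` (inhibition), the dialect [read_graphml()] accepts,
#' so write/read round-trips preserve the network exactly.
#'
#' @param network A [signed_network()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  write_annotated_graphml(network, annotations = list(), path = path)
}

#' Write a graphml file annotated with per-node scores
#'
#' Each entry of `annotations` becomes a numeric node attribute in the output
#' graphml; nodes missing from a score vector receive 0. This is the export
#' format consumed by network visualization tools (Cytoscape, Gephi).
#'
#' @param network A [signed_network()].
#' @param annotations Named list; each element a named numeric vector of
#'   per-node scores. Names of each vector must be a subset of the network's
#'   nodes.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotated_graphml <- function(network, annotations, path) {
  stopifnot(inherits(network, "signed_network"), is.list(annotations))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(network$edges)) network$edges[, c("source", "target")] else
      data.frame(from = character(), to = character()),
    directed = TRUE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  if (nrow(network$edges)) {
    igraph::E(g)$signal <- ifelse(network$edges$sign > 0, "a", "i")
  }
  for (score_name in names(annotations)) {
    vals <- annotations[[score_name]]
    extra <- setdiff(names(vals), network$nodes)
    if (length(extra)) {
      stop("annotation '", score_name, "' refers to unknown nodes: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    full <- setNames(numeric(length(network$nodes)), network$nodes)
    full[names(vals)] <- as.numeric(vals)
    g <- igraph::set_vertex_attr(g, score_name, value = full[igraph::V(g)$name])
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Parse a KEGG KGML pathway document into a signed network
#'
#' Relation subtypes `activation`/`expression` map to +1 and
#' `inhibition`/`repression` to -1; relations with neither default to +1.
#' Entries of type `group` are expanded to their member genes with edges
#' replicated, and compound entries are collapsed through: an edge into a
#' compound and an edge out of it become a direct gene-gene edge whose sign is
#' the product of the two signs. Relations referencing unknown entry ids are
#' skipped with a warning.
#'
#' @param path Path to a KGML (`.xml`) file.
#' @param name Pathway name; defaults to the KGML `title` attribute, else the
#'   file name.
#' @return A [signed_network()].
#' @export
parse_kgml <- function(path, name = NULL) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document (no <pathway> root): ", path,
                        call. = FALSE)
  pw_name <- name %||% xml2::xml_attr(root, "title") %||%
    sub("\\.xml$", "", basename(path))
  if (is.na(pw_name)) pw_name <- sub("\\.xml$", "", basename(path))

  entries <- xml2::xml_find_all(doc, "//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")

  # Per entry: the gene symbols it stands for (possibly several), taken from
  # the graphics name ("SYM1, SYM2..." in KEGG exports), falling back to the
  # entry name tokens for synthetic/toy KGML.
  entry_genes <- lapply(seq_along(entries), function(i) {
    if (entry_type[i] %in% c("gene", "ortholog")) {
      gname <- xml2::xml_attr(xml2::xml_find_first(entries[[i]], "graphics"),
                              "name")
      if (!is.na(gname) && nzchar(gname)) {
        syms <- sub("\\.\\.\\.$", "", trimws(strsplit(gname, ",")[[1]]))
      } else {
        syms <- strsplit(xml2::xml_attr(entries[[i]], "name"), "\\s+")[[1]]
        syms <- sub("^[a-z]+:", "", syms)
      }
      normalize_gene_ids(syms[nzchar(syms)])
    } else if (entry_type[i] == "group") {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "component"), "id")
      attr_genes <- character()
      attr(attr_genes, "components") <- comp
      attr_genes
    } else {
      character()
    }
  })
  names(entry_genes) <- entry_id

  # Resolve group entries to the union of their members' genes.
  for (i in which(entry_type == "group")) {
    comp <- attr(entry_genes[[i]], "components")
    entry_genes[[i]] <- unique(unlist(entry_genes[match(comp, entry_id)]))
  }
  is_compound <- entry_type == "compound"

  relations <- xml2::xml_find_all(doc, "//relation")
  raw <- list()   # entry-level edges: (from_id, to_id, sign)
  for (rel in relations) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    if (!(e1 %in% entry_id) || !(e2 %in% entry_id)) {
      warning("relation references unknown entry id (", e1, " -> ", e2,
              "); skipped", call. = FALSE)
      next
    }
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "subtype"), "name")
    sgn <- if (any(subtypes %in% c("inhibition", "repression"))) -1L else 1L
    raw[[length(raw) + 1L]] <- data.frame(from = e1, to = e2, sign = sgn,
                                          stringsAsFactors = FALSE)
  }
  raw <- if (length(raw)) do.call(rbind, raw) else
    data.frame(from = character(), to = character(), sign = integer())

  # Collapse compound-mediated relations into direct gene-gene edges.
  compound_ids <- entry_id[is_compound]
  for (cid in compound_ids) {
    into <- raw[raw$to == cid & raw$from != cid, , drop = FALSE]
    outof <- raw[raw$from == cid & raw$to != cid, , drop = FALSE]
    bridged <- if (nrow(into) && nrow(outof)) {
      do.call(rbind, lapply(seq_len(nrow(into)), function(i)
        data.frame(from = into$from[i], to = outof$to,
                   sign = into$sign[i] * outof$sign, stringsAsFactors = FALSE)))
    } else NULL
    raw <- raw[raw$from != cid & raw$to != cid, , drop = FALSE]
    if (!is.null(bridged)) raw <- rbind(raw, bridged)
  }

  # Expand entry-level edges to gene-level edges (cartesian over the genes of
  # the two endpoints, which implements group replication).
  edge_rows <- lapply(seq_len(nrow(raw)), function(i) {
    src <- entry_genes[[raw$from[i]]]
    dst <- entry_genes[[raw$to[i]]]
    if (!length(src) || !length(dst)) return(NULL)
    expand.grid(source = src, target = dst, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE) |>
      transform(sign = raw$sign[i])
  })
  edges <- do.call(rbind, edge_rows)
  nodes <- unique(unlist(entry_genes[!is_compound]))
  if (!length(nodes)) stop("empty network: KGML contains no gene entries: ",
                           path, call. = FALSE)
  signed_network(pw_name, nodes = nodes, edges = edges)
}

#' Filter pathways by overlap with the measured gene universe
#'
#' Retains only pathways sharing at least `min_overlap` genes with the
#' training data, the standard pre-filter before rule inference. Each retained
#' network records its overlap count in the `overlap` field.
#'
#' @param networks List of [signed_network()] objects.
#' @param measured_genes Character vector of genes present in the training
#'   data (any omics layer).
#' @param min_overlap Minimum number of shared genes (default 5).
#' @return The retained networks (possibly an empty list).
#' @export
filter_pathways <- function(networks, measured_genes, min_overlap = 5L) {
  stopifnot(min_overlap >= 1L)
  measured_genes <- normalize_gene_ids(measured_genes)
  kept <- list()
  for (nw in networks) {
    ov <- length(intersect(nw$nodes, measured_genes))
    if (ov >= min_overlap) {
      nw$overlap <- as.integer(ov)
      kept[[length(kept) + 1L]] <- nw
    }
  }
  kept
}
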
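#' Assign genome-location indices to genes
#'
#' Genes are sorted by start coordinate within each chromosome; consecutive
#' genes closer than `gap` base pairs share a location index, otherwise the
#' index increments by one. Chromosome boundaries always increment the index
#' (regulatory regions do not span chromosomes). The first gene overall gets
#' index 0. The result is invariant to the row order of `gene_table`.
#'
#' @param gene_table data.frame with columns `gene_id`, `chromosome`, `start`.
#' @param gap distance threshold in base pairs (default 10000); genes strictly
#'   closer than this to the previous gene on the same chromosome share its
#'   index.
#' @return named integer vector, one location index per `gene_id`.
#' @export
assign_location_indices <- function(gene_table, gap = 10000) {
  req <- c("gene_id", "chromosome", "start")
  if (!all(req %in% names(gene_table)))
    stop("gene_table needs columns gene_id, chromosome, start")
  if (any(gene_table$start < 0)) stop("start coordinates must be nonnegative")
  key <- paste(gene_table$chromosome, gene_table$start, gene_table$gene_id)
  if (anyDuplicated(key)) stop("duplicate (chromosome, start, gene_id) rows")
  if (anyDuplicated(gene_table$gene_id)) stop("duplicate gene_id rows")
  ord <- order(gene_table$chromosome, gene_table$start, gene_table$gene_id)
  gt <- gene_table[ord, ]
  n <- nrow(gt)
  new_chrom <- c(TRUE, gt$chromosome[-1] != gt$chromosome[-n])
  gap_ge <- c(TRUE, diff(gt$start) >= gap)
  bump <- new_chrom | gap_ge
  bump[1] <- FALSE                      # first gene overall is index 0
  idx <- cumsum(as.integer(bump))
  names(idx) <- gt$gene_id
  idx[gene_table$gene_id]
}

#' Sinusoidal positional encoding
#'
#' Standard transformer positional encoding: component `2k` is
#' `sin(pos / 10000^(2k/d))` and component `2k+1` is `cos(pos / 10000^(2k/d))`.
#'
#' @param pos nonnegative integer position(s).
#' @param d even embedding dimension.
#' @return matrix with `length(pos)` rows and `d` columns.
#' @export
positional_encode <- function(pos, d) {
  if (d %% 2L != 0L) stop("embedding dimension d must be even")
  if (any(pos < 0)) stop("positions must be nonnegative")
  k <- seq_len(d / 2L) - 1L
  freq <- 1 / 10000^(2 * k / d)
  ang <- outer(pos, freq)
  out <- matrix(0, nrow = length(pos), ncol = d)
  out[, 2L * k + 1L] <- sin(ang)
  out[, 2L * k + 2L] <- cos(ang)
  out
}

#' Load or randomize per-gene identity embeddings
#'
#' Gene identity embeddings stand in for protein-language-model summaries of
#' each gene's product. Either load a precomputed table (rows keyed by gene id)
#' or draw a frozen random embedding per gene: unit-scale Gaussian vectors
#' (`sd = 1/sqrt(d)`), deterministic per `(gene_id, seed)` pair so the result
#' does not depend on gene order.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param table optional numeric matrix with rownames covering all `gene_ids`.
#' @param d embedding dimension (required in random mode; must match `table`).
#' @param seed integer seed for random mode.
#' @return numeric matrix `length(gene_ids)` x `d` with gene ids as rownames.
#' @export
gene_embeddings <- function(gene_ids, table = NULL, d = NULL, seed = 0L) {
  if (!is.null(table)) {
    missing <- setdiff(gene_ids, rownames(table))
    if (length(missing))
      stop("embedding table missing genes: ", paste(missing, collapse = ", "))
    if (!is.null(d) && ncol(table) != d)
      stop(sprintf("embedding table has dimension %d, expected %d",
                   ncol(table), d))
    out <- as.matrix(table[gene_ids, , drop = FALSE])
    storage.mode(out) <- "double"
    return(out)
  }
  if (is.null(d)) stop("d is required in random mode")
  out <- matrix(0, length(gene_ids), d, dimnames = list(gene_ids, NULL))
  for (g in gene_ids) {
    set.seed(sub_seed(seed, g))
    out[g, ] <- stats::rnorm(d, sd = 1 / sqrt(d))
  }
  out
}

#' Build a gene vocabulary
#'
#' Bundles gene identity embeddings, genome-location indices and their
#' sinusoidal encodings into the lookup object consumed by the encoder.
#'
#' @param gene_table data.frame with `gene_id`, `chromosome`, `start`.
#' @param d model dimension (even).
#' @param embeddings optional precomputed embedding matrix (see
#'   [gene_embeddings()]).
#' @param seed seed for random identity embeddings.
#' @return object of class `screg_vocab`.
#' @export
build_vocab <- function(gene_table, d, embeddings = NULL, seed = 0L) {
  loc <- assign_location_indices(gene_table)
  ids <- gene_table$gene_id
  G <- gene_embeddings(ids, table = embeddings, d = d, seed = seed)
  PE <- positional_encode(loc[ids], d)
  rownames(PE) <- ids
  structure(list(gene_ids = ids, d = d, id_embeddings = G,
                 chromosome = gene_table$chromosome,
                 start = gene_table$start,
                 location_index = loc[ids], pe = PE),
            class = "screg_vocab")
}

#' @export
print.screg_vocab <- function(x, ...) {
  cat(sprintf("screg vocabulary: %d genes, d = %d, %d genomic locations\n",
              length(x$gene_ids), x$d, length(unique(x$location_index))))
  invisible(x)
}

# ---- ontology -----------------------------------------------------------

#' Construct a label ontology from a parent-child edge table
#'
#' @param edges data.frame with columns `child`, `parent`. The graph must be
#'   acyclic; leaves are the nodes that never appear as a parent.
#' @return object of class `screg_ontology` with fields `nodes`, `edges`,
#'   `leaves` (stable order) and a cached leaf-descendant map.
#' @export
ontology <- function(edges) {
  if (!all(c("child", "parent") %in% names(edges)))
    stop("edges needs columns child, parent")
  edges <- unique(data.frame(child = as.character(edges$child),
                             parent = as.character(edges$parent),
                             stringsAsFactors = FALSE))
  nodes <- sort(unique(c(edges$child, edges$parent)))
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  leaves <- nodes[lengths(children) == 0L]
  # leaf-descendant closure by DFS with cycle detection
  desc <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  get_desc <- function(v) {
    if (!is.null(desc[[v]])) return(desc[[v]])
    if (isTRUE(visiting[[v]])) stop("ontology contains a cycle at node ", v)
    visiting[[v]] <- TRUE
    kids <- children[[v]]
    out <- if (length(kids) == 0L) v else
      sort(unique(unlist(lapply(kids, get_desc))))
    visiting[[v]] <- FALSE
    desc[[v]] <- out
    out
  }
  leaf_desc <- stats::setNames(lapply(nodes, get_desc), nodes)
  structure(list(nodes = nodes, edges = edges, leaves = leaves,
                 children = children, leaf_desc = leaf_desc),
            class = "screg_ontology")
}

#' Leaf descendants of an ontology node
#'
#' The set of leaf labels reachable from `node`; a leaf maps to itself. These
#' are the classification targets: only leaf labels carry logits, coarser
#' labels are handled by collapsing their descendant leaves.
#'
#' @param onto an [ontology()] object.
#' @param node node name.
#' @return character vector of leaf names (subset of `onto$leaves`).
#' @export
leaf_descendants <- function(onto, node) {
  stopifnot(inherits(onto, "screg_ontology"))
  if (!node %in% onto$nodes) stop("unknown ontology node: ", node)
  onto$leaf_desc[[node]]
}

#' Read / write an ontology as a two-column TSV (child, parent)
#' @param path file path.
#' @return [ontology()] object.
#' @export
read_ontology_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("child", "parent")
  ontology(df)
}

#' @rdname read_ontology_tsv
#' @param onto ontology object to write.
#' @export
write_ontology_tsv <- function(onto, path) {
  utils::write.table(onto$edges[, c("child", "parent")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.screg_ontology <- function(x, ...) {
  cat(sprintf("screg ontology: %d nodes, %d leaves\n",
              length(x$nodes), length(x$leaves)))
  invisible(x)
}
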
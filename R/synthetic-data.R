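# Synthetic single-cell data with a planted regulatory network.
#
# The generator is a one-step linear structural-equation model: group-specific
# latent log-expression is perturbed per cell, propagated one step through the
# planted directed network, squashed through softplus into relative expression,
# scaled to a log-normal library size and sampled as negative binomial counts,
# then hit with gene-wise complete dropout. This is the minimal mechanism that
# yields zero-inflated, network-structured, depth-varying counts.

#' Plant a random directed gene regulatory network
#'
#' Draws a directed network without self-loops over `n_genes` named genes, with
#' i.i.d. edge indicators and edge weights uniform on +/-[wmin, wmax].
#'
#' @param n_genes number of genes.
#' @param density probability of each ordered non-self gene pair being an edge.
#' @param seed integer seed.
#' @param wmin,wmax absolute edge-weight range.
#' @param frac_negative fraction of repressive (negative-weight) edges.
#' @return object of class `screg_grn`: list with `genes`, `edges`
#'   (data.frame source, target, weight) and the weighted adjacency matrix `A`
#'   (rows = targets, columns = sources).
#' @export
simulate_grn <- function(n_genes, density = 0.05, seed = 1L,
                         wmin = 0.5, wmax = 1.5, frac_negative = 0.2) {
  stopifnot(n_genes >= 2, density >= 0, density <= 1)
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  pairs <- expand.grid(target = genes, source = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target != pairs$source, ]
  keep <- stats::runif(nrow(pairs)) < density
  edges <- pairs[keep, c("source", "target")]
  w <- stats::runif(nrow(edges), wmin, wmax)
  sgn <- ifelse(stats::runif(nrow(edges)) < frac_negative, -1, 1)
  edges$weight <- w * sgn
  A <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  if (nrow(edges)) A[cbind(edges$target, edges$source)] <- edges$weight
  structure(list(genes = genes, edges = edges, A = A), class = "screg_grn")
}

#' @export
print.screg_grn <- function(x, ...) {
  cat(sprintf("planted GRN: %d genes, %d directed edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Configuration for the synthetic count generator
#'
#' @param n_cells,n_genes,n_groups dataset dimensions.
#' @param group_proportions simplex vector of group sizes; default is a
#'   geometric decay (imbalanced groups), normalized to sum to 1.
#' @param mean_depth expected transcripts per cell.
#' @param dispersion negative binomial inverse-dispersion (size); `Inf` gives
#'   Poisson counts.
#' @param dropout_logit logit of the per-(cell, gene) complete-dropout
#'   probability; `-Inf` disables dropout.
#' @param batch_count number of batches (0 = no batch structure).
#' @param lib_sigma log-normal sd of library size (depth variation).
#' @param cell_noise_sd sd of per-cell latent noise before network propagation;
#'   this is what induces network-shaped gene-gene covariance.
#' @param group_sd sd of group-specific latent shifts (group separability).
#' @param batch_sd log-scale sd of multiplicative per-(batch, gene) effects.
#' @param seed integer seed.
#' @return list of class `screg_synth_config`.
#' @export
synth_config <- function(n_cells = 1000, n_genes = 60, n_groups = 4,
                         group_proportions = NULL, mean_depth = 1500,
                         dispersion = 3, dropout_logit = -2,
                         batch_count = 2, lib_sigma = 0.3,
                         cell_noise_sd = 0.5, group_sd = 1,
                         batch_sd = 0.2, seed = 1L) {
  if (is.null(group_proportions)) {
    group_proportions <- 0.6^seq_len(n_groups)
    group_proportions <- group_proportions / sum(group_proportions)
  }
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_groups = as.integer(n_groups),
              group_proportions = group_proportions,
              mean_depth = mean_depth, dispersion = dispersion,
              dropout_logit = dropout_logit,
              batch_count = as.integer(batch_count),
              lib_sigma = lib_sigma, cell_noise_sd = cell_noise_sd,
              group_sd = group_sd, batch_sd = batch_sd,
              seed = as.integer(seed))
  stopifnot_scalar(cfg$mean_depth, "mean_depth")
  if (cfg$mean_depth < 0) stop("mean_depth must be >= 0")
  if (cfg$n_cells < 1 || cfg$n_genes < 1 || cfg$n_groups < 1)
    stop("n_cells, n_genes, n_groups must be positive")
  if (length(group_proportions) != cfg$n_groups)
    stop("group_proportions length must equal n_groups")
  if (any(group_proportions < 0) ||
      abs(sum(group_proportions) - 1) > 1e-8)
    stop("group_proportions must be a simplex vector")
  if (!(cfg$dispersion > 0)) stop("dispersion must be > 0")
  if (cfg$batch_count < 0) stop("batch_count must be >= 0")
  class(cfg) <- "screg_synth_config"
  cfg
}

#' Generate a synthetic count matrix with a planted network
#'
#' See the package vignette for the generative model. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param grn a [simulate_grn()] network over at most `cfg$n_genes` genes; by
#'   default a fresh network over all genes.
#' @param onto optional [ontology()]; if supplied, groups are labeled by its
#'   first `n_groups` leaves (in stable leaf order) instead of `"group<k>"`.
#' @return object of class `screg_counts`: `counts` (sparse cells x genes),
#'   `gene_ids`, `gene_table`, `cell_labels` (data.frame), `totals`, and
#'   `latent` (the group-level expected expression proportions, for tests).
#' @export
simulate_cells <- function(cfg, grn = NULL, onto = NULL) {
  stopifnot(inherits(cfg, "screg_synth_config"))
  if (is.null(grn)) grn <- simulate_grn(cfg$n_genes, seed = cfg$seed)
  if (length(grn$genes) > cfg$n_genes)
    stop("n_genes is smaller than the planted network's gene set")
  set.seed(cfg$seed)
  genes <- grn$genes
  if (length(genes) < cfg$n_genes)
    genes <- c(genes, sprintf("f%03d", seq_len(cfg$n_genes - length(genes))))
  p <- cfg$n_genes
  A <- matrix(0, p, p, dimnames = list(genes, genes))
  A[grn$genes, grn$genes] <- grn$A

  # group assignment (imbalanced, every group nonempty)
  g_of <- sample(rep.int(seq_len(cfg$n_groups),
                         pmax(1, round(cfg$group_proportions * cfg$n_cells)))[
                   seq_len(cfg$n_cells)])
  if (length(unique(g_of)) < cfg$n_groups) stop("a group came out empty")

  base <- stats::rnorm(p, 0, 1)
  M <- vapply(seq_len(cfg$n_groups),
              function(g) base + stats::rnorm(p, 0, cfg$group_sd),
              numeric(p))                       # p x n_groups latent means
  # expected proportions per group (cell noise integrated out at 0)
  V0 <- apply(M, 2L, function(m) softplus(m + A %*% m))
  P0 <- sweep(V0, 2L, colSums(V0), "/")
  rownames(P0) <- genes

  # library sizes with E[L] = mean_depth
  L <- if (cfg$mean_depth == 0) rep(0, cfg$n_cells) else
    stats::rlnorm(cfg$n_cells,
                  log(cfg$mean_depth) - cfg$lib_sigma^2 / 2, cfg$lib_sigma)

  batch <- if (cfg$batch_count >= 1)
    sample.int(cfg$batch_count, cfg$n_cells, replace = TRUE) else NULL
  B <- if (cfg$batch_count >= 1)
    matrix(stats::rnorm(cfg$batch_count * p, 0, cfg$batch_sd),
           cfg$batch_count, p) else NULL

  drop_p <- sigmoid(cfg$dropout_logit)
  poisson_limit <- !is.finite(cfg$dispersion) || cfg$dispersion > 1e8
  X <- matrix(0L, cfg$n_cells, p)
  for (i in seq_len(cfg$n_cells)) {
    if (L[i] == 0) next
    u <- M[, g_of[i]] + stats::rnorm(p, 0, cfg$cell_noise_sd)
    v <- softplus(u + A %*% u)
    pr <- as.numeric(v / sum(v))
    mu <- L[i] * pr
    if (!is.null(B)) {
      mu <- mu * exp(B[batch[i], ])
      mu <- mu * (L[i] / sum(mu))             # keep expected depth
    }
    xi <- if (poisson_limit) stats::rpois(p, mu) else
      stats::rnbinom(p, size = cfg$dispersion, mu = mu)
    if (drop_p > 0) xi[stats::runif(p) < drop_p] <- 0L
    X[i, ] <- xi
  }
  colnames(X) <- genes
  rownames(X) <- sprintf("c%05d", seq_len(cfg$n_cells))

  group_names <- if (!is.null(onto)) {
    if (length(onto$leaves) < cfg$n_groups)
      stop("ontology has fewer leaves than groups")
    onto$leaves[seq_len(cfg$n_groups)]
  } else paste0("group", seq_len(cfg$n_groups))
  labels <- data.frame(cell_type = group_names[g_of],
                       row.names = rownames(X),
                       stringsAsFactors = FALSE)
  if (!is.null(batch)) labels$batch <- paste0("batch", batch)

  gene_table <- simulate_gene_table(genes, seed = cfg$seed)
  new_counts(Matrix::Matrix(X, sparse = TRUE), gene_table, labels,
             latent = list(group_props = P0, groups = group_names,
                           grn = grn))
}

#' Simulate gene metadata (chromosome, start coordinate)
#'
#' Genes are laid out on a few chromosomes with exponential inter-gene gaps so
#' that some consecutive genes fall within the same 10 kb location bin and
#' others do not.
#'
#' @param gene_ids gene names.
#' @param seed integer seed.
#' @param n_chrom number of chromosomes.
#' @return data.frame with `gene_id`, `chromosome`, `start`.
#' @export
simulate_gene_table <- function(gene_ids, seed = 1L, n_chrom = 3L) {
  set.seed(sub_seed(seed, "gene_table"))
  n <- length(gene_ids)
  chrom <- paste0("chr", sort(rep_len(seq_len(n_chrom), n)))
  gaps <- round(stats::rexp(n, rate = 1 / 12000)) + 100
  start <- stats::ave(gaps, chrom, FUN = cumsum)
  data.frame(gene_id = gene_ids, chromosome = chrom, start = start,
             stringsAsFactors = FALSE)
}

# internal constructor for the count container
new_counts <- function(counts, gene_table, cell_labels, latent = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  structure(list(counts = counts,
                 gene_ids = colnames(counts),
                 gene_table = gene_table,
                 cell_labels = cell_labels,
                 totals = Matrix::rowSums(counts),
                 latent = latent),
            class = "screg_counts")
}

#' @export
print.screg_counts <- function(x, ...) {
  cat(sprintf("screg counts: %d cells x %d genes, median depth %.0f, %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$totals),
              100 * (1 - Matrix::nnzero(x$counts) / prod(dim(x$counts)))))
  invisible(x)
}

#' @export
dim.screg_counts <- function(x) dim(x$counts)

#' Subset cells of a count container
#' @param data `screg_counts`.
#' @param i cell index vector.
#' @return `screg_counts` restricted to cells `i`.
#' @export
subset_cells <- function(data, i) {
  new_counts(data$counts[i, , drop = FALSE], data$gene_table,
             data$cell_labels[i, , drop = FALSE], latent = data$latent)
}

#' Quality-control filter for a count dataset
#'
#' Removes cells expressing fewer than `min_genes_per_cell` genes, then rejects
#' the whole dataset if fewer than `min_cells` cells survive, the dataset has
#' fewer than `min_genes_total` genes, or more than `max_removed_frac` of cells
#' were removed. Rejection is a typed outcome, not an error.
#'
#' @param data `screg_counts`.
#' @param min_genes_per_cell minimum expressed genes per retained cell.
#' @param min_cells minimum surviving cells.
#' @param min_genes_total minimum number of genes in the dataset.
#' @param max_removed_frac maximal tolerated fraction of removed cells.
#' @return object of class `screg_qc`: `accepted` (logical), `data` (filtered
#'   `screg_counts` if accepted, else `NULL`), `reason`, `n_removed`,
#'   `frac_removed`.
#' @export
qc_filter <- function(data, min_genes_per_cell = 200, min_cells = 100,
                      min_genes_total = 10000, max_removed_frac = 0.95) {
  stopifnot(inherits(data, "screg_counts"),
            min_genes_per_cell >= 0, min_cells >= 0,
            min_genes_total >= 0, max_removed_frac >= 0)
  n_expr <- Matrix::rowSums(data$counts > 0)
  keep <- n_expr >= min_genes_per_cell
  n_removed <- sum(!keep)
  frac_removed <- n_removed / nrow(data$counts)
  out <- list(accepted = TRUE, data = NULL, reason = NULL,
              n_removed = n_removed, frac_removed = frac_removed)
  if (sum(keep) < min_cells) {
    out$accepted <- FALSE; out$reason <- "fewer surviving cells than min_cells"
  } else if (ncol(data$counts) < min_genes_total) {
    out$accepted <- FALSE; out$reason <- "fewer genes than min_genes_total"
  } else if (frac_removed > max_removed_frac) {
    out$accepted <- FALSE
    out$reason <- "removed cell fraction exceeds max_removed_frac"
  }
  if (out$accepted) out$data <- subset_cells(data, which(keep))
  class(out) <- "screg_qc"
  out
}

#' @export
print.screg_qc <- function(x, ...) {
  if (x$accepted)
    cat(sprintf("QC: accepted; removed %d cells (%.1f%%)\n",
                x$n_removed, 100 * x$frac_removed))
  else cat(sprintf("QC: REJECTED (%s)\n", x$reason))
  invisible(x)
}

#' Generate a random label ontology
#'
#' Builds a rooted tree of the requested depth over `n_leaves` leaf labels by
#' recursively partitioning the leaf set; every internal node therefore has at
#' least one leaf descendant. Leaves are named `leaf1..leafN` (stable order).
#'
#' @param n_leaves number of leaf labels (>= 2).
#' @param depth tree depth (>= 1); depth 1 is a root with all leaves as
#'   children.
#' @param seed integer seed.
#' @return [ontology()] object.
#' @export
make_ontology <- function(n_leaves, depth = 2L, seed = 1L) {
  stopifnot(n_leaves >= 2, depth >= 1)
  set.seed(seed)
  leaves <- paste0("leaf", seq_len(n_leaves))
  edges <- list()
  counter <- 0L
  build <- function(set, parent, level) {
    if (level >= depth || length(set) == 1L) {
      for (lf in set) edges[[length(edges) + 1L]] <<- c(lf, parent)
      return(invisible())
    }
    k <- min(length(set), sample(2:3, 1L))
    parts <- split(set, sort(rep_len(seq_len(k), length(set))))
    for (part in parts) {
      counter <<- counter + 1L
      node <- paste0("node", counter)
      edges[[length(edges) + 1L]] <<- c(node, parent)
      build(part, node, level + 1L)
    }
  }
  build(leaves, "root", 1L)
  ontology(data.frame(child = vapply(edges, `[`, "", 1L),
                      parent = vapply(edges, `[`, "", 2L),
                      stringsAsFactors = FALSE))
}

# ---- on-disk interchange (MTX triplets + TSV metadata) ------------------

#' Write / read a count dataset as MTX + TSV
#'
#' `write_counts_mtx` writes `matrix.mtx` (genes x cells, 1-based triplets),
#' `genes.tsv` (gene_id, chromosome, start) and `cells.tsv` (cell_id plus one
#' column per label class). `read_counts_mtx` reads the same layout back.
#'
#' @param data `screg_counts`.
#' @param dir output directory (created if missing).
#' @return the directory (write) or an `screg_counts` (read), invisibly.
#' @export
write_counts_mtx <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(data$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(data$gene_table, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- cbind(data.frame(cell_id = rownames(data$counts)),
                 data$cell_labels)
  utils::write.table(cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(m) <- list(cells$cell_id, genes$gene_id)
  labels <- cells[, setdiff(names(cells), "cell_id"), drop = FALSE]
  rownames(labels) <- cells$cell_id
  new_counts(m, genes, labels)
}
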
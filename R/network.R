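# Gene-network extraction from attention heads: meta-cell attention, all-head
# averaging, ground-truth-guided head selection, genome-wide assembly,
# orientation and TF subsetting.
#
# Orientation convention: attention is row-normalized over queries, so in the
# "as-computed" orientation rows are TARGETS and columns are REGULATORS; the
# score of a directed edge source -> target sits at [target, source].

new_network <- function(scores, orientation = "as-computed",
                        provenance = "all-heads-mean") {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  structure(list(gene_ids = rownames(scores), scores = scores,
                 orientation = orientation, provenance = provenance),
            class = "screg_network")
}

#' @export
print.screg_network <- function(x, ...) {
  cat(sprintf("screg network: %d genes, orientation %s, provenance %s (%d NA pairs)\n",
              length(x$gene_ids), x$orientation,
              paste(x$provenance, collapse = "+"), sum(is.na(x$scores))))
  invisible(x)
}

#' Meta-cell attention from per-cell query/key embeddings
#'
#' Queries and keys are averaged over the cell set before the softmax:
#' `softmax(mean(Q) mean(K)^T / sqrt(d_k))`, row-wise. With a single cell this
#' reduces exactly to that cell's attention matrix.
#'
#' @param Qs,Ks lists of per-cell matrices (n_genes x d_k), all cells sharing
#'   the same gene ordering (rownames checked when present).
#' @return row-stochastic n x n attention matrix.
#' @export
metacell_attention <- function(Qs, Ks) {
  if (is.matrix(Qs)) Qs <- list(Qs)
  if (is.matrix(Ks)) Ks <- list(Ks)
  stopifnot(length(Qs) == length(Ks), length(Qs) >= 1L)
  rn <- rownames(Qs[[1L]])
  for (M in c(Qs, Ks))
    if (!is.null(rn) && !is.null(rownames(M)) && !identical(rownames(M), rn))
      stop("cells do not share the same gene ordering")
  Qbar <- Reduce(`+`, Qs) / length(Qs)
  Kbar <- Reduce(`+`, Ks) / length(Ks)
  A <- softmax_rows(tcrossprod(Qbar, Kbar) / sqrt(ncol(Qbar)))
  dimnames(A) <- list(rn, rn)
  A
}

# Accumulate mean Q and K per (layer, head) at gene positions over a cell set.
# Returns list over layers of list(Qbar = [head -> n x d_k], Kbar = ...).
metacell_qk <- function(model, X, batch_size = 16L) {
  cfg <- model$config
  d <- cfg$d; nh <- cfg$n_heads; dk <- d / nh
  outs <- run_cells(model, X, batch_size = batch_size, cache_qk = TRUE)
  p <- ncol(X)
  acc <- lapply(seq_len(cfg$n_layers), function(l)
    list(Q = matrix(0, p, d), K = matrix(0, p, d)))
  n_cells <- 0L
  for (o in outs) {
    for (l in seq_len(cfg$n_layers)) {
      qk <- o$qk[[l]]
      for (ci in seq_len(o$b)) {
        rows <- o$gene_rows[((ci - 1L) * o$n_ctx + 1L):(ci * o$n_ctx)]
        acc[[l]]$Q <- acc[[l]]$Q + qk[rows, seq_len(d), drop = FALSE]
        acc[[l]]$K <- acc[[l]]$K + qk[rows, d + seq_len(d), drop = FALSE]
      }
    }
    n_cells <- n_cells + o$b
  }
  lapply(acc, function(a) {
    Qb <- a$Q / n_cells; Kb <- a$K / n_cells
    rownames(Qb) <- rownames(Kb) <- colnames(X)
    list(Qbar = lapply(seq_len(nh), function(h)
           Qb[, ((h - 1L) * dk + 1L):(h * dk), drop = FALSE]),
         Kbar = lapply(seq_len(nh), function(h)
           Kb[, ((h - 1L) * dk + 1L):(h * dk), drop = FALSE]))
  })
}

#' All per-head meta-cell attention matrices for a cell set
#'
#' Runs the model over the cells' full profiles (placeholder tokens are
#' dropped before assembly), averages queries/keys per head over the cell
#' set, and returns one gene x gene row-stochastic matrix per (layer, head).
#'
#' @param object `screg` fit or trained `screg_model`.
#' @param data counts (`screg_counts` or matrix); rows are the meta-cell set.
#' @param batch_size forward batch size.
#' @return named list of class `screg_heads` (`"L<l>H<h>"` matrices).
#' @export
attention_heads <- function(object, data, batch_size = 16L) {
  model <- as_model(object)
  X <- counts_matrix(data, model)
  qk <- metacell_qk(model, X, batch_size)
  heads <- list()
  for (l in seq_along(qk))
    for (h in seq_along(qk[[l]]$Qbar))
      heads[[sprintf("L%dH%d", l, h)]] <-
        metacell_attention(qk[[l]]$Qbar[[h]], qk[[l]]$Kbar[[h]])
  structure(heads, class = "screg_heads")
}

#' Average attention heads into a network
#'
#' Unweighted elementwise mean of all supplied head matrices (NA-aware: a
#' pair's mean is over the heads where it is observed).
#'
#' @param heads `screg_heads` or list of identically-shaped matrices.
#' @return `screg_network` (provenance `"all-heads-mean"`).
#' @export
mean_network <- function(heads) {
  heads <- unclass(heads)
  dims <- vapply(heads, dim, integer(2L))
  if (any(dims != dims[, 1L])) stop("head matrices differ in shape")
  S <- Reduce(`+`, lapply(heads, function(M) ifelse(is.na(M), 0, M)))
  Nobs <- Reduce(`+`, lapply(heads, function(M) !is.na(M)))
  out <- S / Nobs
  out[Nobs == 0L] <- NA_real_
  dimnames(out) <- dimnames(heads[[1L]])
  new_network(out, provenance = "all-heads-mean")
}

#' Select informative heads against a ground-truth network
#'
#' Half of the ground truth's positive and (subsampled) negative gene pairs
#' train a linear classifier (targets -1/+1, squared error, L2 penalty 1,
#' nonnegative coefficients, no intercept) on the per-head attention scores of
#' each pair. Heads with a positive coefficient are selected, and the returned
#' network is their unweighted mean; the coefficients only select, they do not
#' weight.
#'
#' @param heads `screg_heads` (gene x gene matrices, rows = targets).
#' @param truth a [ground_truth()] network.
#' @param train_fraction fraction of pairs used for fitting (default 0.5; the
#'   rest is returned as a held-out split).
#' @param neg_ratio negatives subsampled to at most this multiple of the
#'   positives.
#' @param seed integer seed (splits and subsampling).
#' @return list of class `screg_head_selection`: `selected` (head names),
#'   `coefficients`, `network` (`screg_network`, provenance = selected heads),
#'   `test_pairs` (held-out data.frame source, target, label).
#' @export
select_heads <- function(heads, truth, train_fraction = 0.5, neg_ratio = 10,
                         seed = 1L) {
  stopifnot(inherits(truth, "screg_truth"))
  hm <- unclass(heads)
  genes <- rownames(hm[[1L]])
  common <- intersect(genes, truth$universe)
  if (length(common) < 2L) stop("no common genes between heads and truth")
  pos <- truth$edges[truth$edges$source %in% common &
                       truth$edges$target %in% common, ]
  if (nrow(pos) == 0L) stop("degenerate truth: no positive pairs on the gene set")
  set.seed(seed)
  all_pairs <- expand.grid(target = common, source = common,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$target != all_pairs$source, ]
  pkey <- paste(pos$source, pos$target)
  akey <- paste(all_pairs$source, all_pairs$target)
  neg <- all_pairs[!(akey %in% pkey), c("source", "target")]
  if (nrow(neg) == 0L) stop("degenerate truth: no negative pairs on the gene set")
  if (nrow(neg) > neg_ratio * nrow(pos))
    neg <- neg[sample.int(nrow(neg), neg_ratio * nrow(pos)), ]
  pairs <- rbind(data.frame(neg, label = -1),
                 data.frame(pos[, c("source", "target")], label = 1))
  feat <- vapply(hm, function(M) M[cbind(pairs$target, pairs$source)],
                 numeric(nrow(pairs)))
  ok <- stats::complete.cases(feat)
  pairs <- pairs[ok, ]; feat <- feat[ok, , drop = FALSE]
  tr <- sort(sample.int(nrow(pairs), round(train_fraction * nrow(pairs))))
  if (length(unique(pairs$label[tr])) < 2L)
    stop("training split lacks a positive or a negative pair")
  # min ||F w - y||^2 + ||w||^2, w >= 0  via NNLS on the ridge-augmented system
  A <- rbind(feat[tr, , drop = FALSE], diag(sqrt(1), ncol(feat)))
  y <- c(pairs$label[tr], rep(0, ncol(feat)))
  coefs <- pracma::lsqnonneg(A, y)$x
  names(coefs) <- names(hm)
  selected <- names(coefs)[coefs > 0]
  if (length(selected) == 0L) {
    warning("no head received a positive coefficient; falling back to all heads")
    selected <- names(hm)
  }
  net <- mean_network(hm[selected])
  net$provenance <- selected
  structure(list(selected = selected, coefficients = coefs, network = net,
                 test_pairs = pairs[-tr, , drop = FALSE]),
            class = "screg_head_selection")
}

#' @export
print.screg_head_selection <- function(x, ...) {
  cat(sprintf("head selection: %d/%d heads (%s)\n", length(x$selected),
              length(x$coefficients), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Genome-wide network by blockwise attention assembly
#'
#' Repeated meta-cell forward passes over random gene blocks; per-head
#' attention entries are scattered into a vocabulary-sized matrix and averaged
#' over the number of times each ordered pair co-occurred in a block. Pairs
#' that never co-occurred are `NA` (absent), not zero.
#'
#' @param object `screg` fit or trained `screg_model`.
#' @param data counts for the meta-cell set.
#' @param block_size genes per forward pass (<= context capacity).
#' @param n_passes number of random blocks.
#' @param seed integer seed for block sampling.
#' @param max_absent_frac warn if more than this fraction of pairs was never
#'   co-sampled.
#' @param batch_size forward batch size.
#' @return list with `network` (`screg_network`, all-heads mean), `heads`
#'   (per-head vocabulary-sized matrices, `screg_heads`) and `cooccurrence`
#'   (pair counts).
#' @export
genome_wide_network <- function(object, data, block_size, n_passes = 20L,
                                seed = 1L, max_absent_frac = 0.5,
                                batch_size = 16L) {
  model <- as_model(object)
  X <- counts_matrix(data, model)
  p <- ncol(X)
  if (block_size > p) stop("block_size exceeds the number of genes")
  set.seed(seed)
  nh <- model$config$n_heads * model$config$n_layers
  sums <- NULL
  cooc <- matrix(0L, p, p, dimnames = list(colnames(X), colnames(X)))
  # genes are sampled preferring expression, like the training context:
  # a block is drawn from the pooled profile of the cell set
  pooled <- colSums(X)
  for (pass in seq_len(n_passes)) {
    block <- if (block_size == p) seq_len(p) else
      sample_context(pooled, block_size)$idx
    hb <- attention_heads(model, X[, block, drop = FALSE],
                          batch_size = batch_size)
    if (is.null(sums))
      sums <- stats::setNames(rep(list(matrix(0, p, p)), length(hb)),
                              names(hb))
    for (nm in names(hb))
      sums[[nm]][block, block] <- sums[[nm]][block, block] + hb[[nm]]
    cooc[block, block] <- cooc[block, block] + 1L
  }
  heads <- lapply(sums, function(S) {
    M <- S / cooc
    M[cooc == 0L] <- NA_real_
    dimnames(M) <- dimnames(cooc)
    M
  })
  class(heads) <- "screg_heads"
  absent <- mean(cooc[row(cooc) != col(cooc)] == 0L)
  if (absent > max_absent_frac)
    warning(sprintf("%.0f%% of gene pairs were never co-sampled", 100 * absent))
  list(network = mean_network(heads), heads = heads, cooccurrence = cooc)
}

#' Transpose a network's orientation
#'
#' Swaps the regulator and target axes (involutive). Use when comparing
#' against ground truths whose sources are sparsely connected.
#'
#' @param network `screg_network`.
#' @return `screg_network` with transposed scores and flipped orientation
#'   flag.
#' @export
orient <- function(network) {
  stopifnot(inherits(network, "screg_network"))
  network$scores <- t(network$scores)
  network$orientation <- if (network$orientation == "as-computed")
    "transposed" else "as-computed"
  network
}

#' Restrict a network to transcription-factor regulators
#'
#' Keeps only columns (regulators) in `tf_ids`; targets are unrestricted.
#'
#' @param network `screg_network`.
#' @param tf_ids transcription-factor gene ids (must intersect the gene set).
#' @return `screg_network` restricted to TF -> gene pairs (rectangular score
#'   block; `gene_ids` keeps the target axis).
#' @export
subset_to_tf <- function(network, tf_ids) {
  stopifnot(inherits(network, "screg_network"))
  keep <- intersect(colnames(network$scores), tf_ids)
  if (length(keep) == 0L) stop("no transcription factor in the gene set")
  network$scores <- network$scores[, keep, drop = FALSE]
  network$provenance <- c(network$provenance, "tf-subset")
  network
}

#' Write / read a network as a TSV edge list with a JSON sidecar
#'
#' Edges are written as (regulator, target, score) rows, gzip-compressed, with
#' orientation/provenance/gene set in `<path>.json`.
#'
#' @param network `screg_network`.
#' @param path output `.tsv.gz` path.
#' @return the path (write) / `screg_network` (read).
#' @export
write_network <- function(network, path) {
  sc <- network$scores
  df <- data.frame(regulator = rep(colnames(sc), each = nrow(sc)),
                   target = rep(rownames(sc), ncol(sc)),
                   score = as.numeric(sc))
  df <- df[!is.na(df$score), ]
  con <- gzfile(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(list(orientation = network$orientation,
                            provenance = network$provenance,
                            gene_ids = network$gene_ids),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- utils::read.delim(gzfile(path), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  genes <- meta$gene_ids
  sc <- matrix(NA_real_, length(genes), length(unique(df$regulator)),
               dimnames = list(genes, sort(unique(df$regulator))))
  sc[cbind(df$target, df$regulator)] <- df$score
  structure(list(gene_ids = genes, scores = sc,
                 orientation = meta$orientation,
                 provenance = meta$provenance),
            class = "screg_network")
}
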
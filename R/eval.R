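# Zero-shot task protocols: denoising (profile reconstruction at a requested
# depth), cell-label prediction with ontology lifting, embedding export.

# resolve an screg fit or raw model to the model
as_model <- function(object) {
  if (inherits(object, "screg")) object$model
  else if (inherits(object, "screg_model")) object
  else stop("expected an screg fit or screg_model")
}

# dense counts matrix aligned to the model vocabulary
counts_matrix <- function(data, model) {
  X <- if (inherits(data, "screg_counts")) as.matrix(data$counts) else
    as.matrix(data)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$vocab$gene_ids))
      stop("counts have no gene names and wrong dimension")
    colnames(X) <- model$vocab$gene_ids
  }
  missing <- setdiff(colnames(X), model$vocab$gene_ids)
  if (length(missing))
    stop("genes absent from the model vocabulary: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  X
}

# run the model over cells in evaluation mode, full-profile context
run_cells <- function(model, X, t = NULL, batch_size = 16L,
                      cache_qk = FALSE) {
  p <- ncol(X)
  gidx <- match(colnames(X), model$vocab$gene_ids)
  n <- nrow(X)
  if (is.null(t)) t <- rowSums(X)
  t <- rep_len(t, n)
  outs <- vector("list", ceiling(n / batch_size))
  for (k in seq_along(outs)) {
    rows <- ((k - 1L) * batch_size + 1L):min(k * batch_size, n)
    idx <- matrix(gidx, length(rows), p, byrow = TRUE)
    outs[[k]] <- forward(model, idx, X[rows, , drop = FALSE], t[rows],
                         train = FALSE, cache_qk = cache_qk)
  }
  outs
}

#' Denoise expression profiles at a requested sequencing depth
#'
#' Runs the model on each cell's full profile with the total-count token set
#' to `target_depth` (default: the cell's own depth) and returns the expected
#' counts `(1 - pi) * mu` of the decoded ZINB, i.e. a reconstructed profile at
#' the requested depth.
#'
#' @param object `screg` fit or `screg_model` (trained).
#' @param data `screg_counts` or a counts matrix (cells x genes).
#' @param target_depth requested total transcript count (scalar or per-cell);
#'   must be > 0 if given.
#' @param batch_size forward-pass batch size.
#' @return list with matrices `expected`, `mu`, `theta`, `pi` (cells x genes).
#' @export
denoise <- function(object, data, target_depth = NULL, batch_size = 16L) {
  model <- as_model(object)
  if (model$config$loss == "mse")
    stop("denoise() requires a ZINB or NB expression decoder")
  if (!is.null(target_depth) && any(target_depth <= 0))
    stop("target_depth must be > 0")
  X <- counts_matrix(data, model)
  outs <- run_cells(model, X, t = target_depth, batch_size = batch_size)
  p <- ncol(X)
  mu <- th <- pi_ <- matrix(0, nrow(X), p, dimnames = dimnames(X))
  at <- 0L
  for (o in outs) {
    dec <- decode_expression(model, o$e)
    rows <- at + seq_len(o$b)
    mu[rows, ] <- matrix(dec$mu, o$b, p, byrow = TRUE)
    th[rows, ] <- matrix(dec$theta, o$b, p, byrow = TRUE)
    pi_[rows, ] <- matrix(sigmoid(dec$rho), o$b, p, byrow = TRUE)
    at <- at + o$b
  }
  if (model$config$loss == "nb") pi_[] <- 0
  list(expected = (1 - pi_) * mu, mu = mu, theta = th, pi = pi_)
}

#' Score a denoising run
#'
#' Per cell, Spearman correlation with the true profile is computed over the
#' genes initially expressed in that cell (true count > 0; unexpressed genes
#' are excluded); the improvement is
#' `delta = cor(denoised, true) - cor(noisy, true)`. Cells with fewer than
#' `min_expressed` expressed genes are skipped and counted.
#'
#' @param true,noisy,denoised aligned cells x genes matrices.
#' @param subpopulation optional logical mask of cells; the summary delta is
#'   then averaged over that subpopulation only (per-cell values are
#'   unchanged).
#' @param min_expressed minimum expressed genes per scored cell.
#' @return object of class `screg_denoising_report`: per-cell data.frame
#'   (`cor_noisy`, `cor_denoised`, `delta`), `mean_delta`, `n_skipped`.
#' @export
evaluate_denoising <- function(true, noisy, denoised, subpopulation = NULL,
                               min_expressed = 3L) {
  stopifnot(all(dim(true) == dim(noisy)), all(dim(true) == dim(denoised)))
  n <- nrow(true)
  cn <- cd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    expr <- which(true[i, ] > 0)
    if (length(expr) < min_expressed) next
    cn[i] <- stats::cor(noisy[i, expr], true[i, expr], method = "spearman")
    cd[i] <- stats::cor(denoised[i, expr], true[i, expr], method = "spearman")
  }
  per_cell <- data.frame(cor_noisy = cn, cor_denoised = cd, delta = cd - cn)
  scored <- !is.na(per_cell$delta)
  keep <- if (is.null(subpopulation)) scored else scored & subpopulation
  structure(list(per_cell = per_cell,
                 mean_delta = mean(per_cell$delta[keep]),
                 mean_cor_noisy = mean(per_cell$cor_noisy[keep]),
                 mean_cor_denoised = mean(per_cell$cor_denoised[keep]),
                 n_skipped = sum(!scored)),
            class = "screg_denoising_report")
}

#' @export
print.screg_denoising_report <- function(x, ...) {
  cat(sprintf(paste0("denoising: mean Spearman %.3f (noisy) -> %.3f ",
                     "(denoised), delta %+.3f; %d cells skipped\n"),
              x$mean_cor_noisy, x$mean_cor_denoised, x$mean_delta,
              x$n_skipped))
  invisible(x)
}

#' Most variable genes on log-normalized counts
#' @param data `screg_counts` or counts matrix.
#' @param n number of genes to keep.
#' @return character vector of gene ids.
#' @export
highly_variable_genes <- function(data, n = 5000L) {
  X <- if (inherits(data, "screg_counts")) as.matrix(data$counts) else
    as.matrix(data)
  depth <- pmax(rowSums(X), 1)
  L <- log1p(X / depth * mean(depth))
  v <- apply(L, 2L, stats::var)
  colnames(X)[order(v, decreasing = TRUE)[seq_len(min(n, ncol(X)))]]
}

#' End-to-end denoising benchmark
#'
#' Downsamples each cell's profile (dropout fraction `r`), denoises the noisy
#' profile at the cell's true depth, and scores the improvement with
#' [evaluate_denoising()], optionally restricted to the `n_hvg` most variable
#' genes.
#'
#' @inheritParams denoise
#' @param r,s downsampling parameters (the benchmark default drops 70% of
#'   transcripts, r = 0.7).
#' @param n_hvg restrict scoring to this many most-variable genes (`Inf` for
#'   all).
#' @param subpopulation optional logical cell mask (rare-population variant).
#' @return `screg_denoising_report`.
#' @export
denoising_task <- function(object, data, r = 0.7, s = 0.55, n_hvg = 5000L,
                           subpopulation = NULL, batch_size = 16L) {
  model <- as_model(object)
  X <- counts_matrix(data, model)
  if (is.finite(n_hvg) && n_hvg < ncol(X))
    X <- X[, highly_variable_genes(X, n_hvg), drop = FALSE]
  noisy <- downsample(X, r = r, s = s)
  dn <- denoise(model, noisy, target_depth = pmax(rowSums(X), 1),
                batch_size = batch_size)
  evaluate_denoising(X, noisy, dn$expected, subpopulation = subpopulation)
}

#' Predict cell labels
#'
#' Per class, leaf probabilities are the softmax over leaf logits; `level` can
#' name a coarser ontology level: probabilities are then lifted by summing
#' descendant-leaf probabilities over a requested set of nodes.
#'
#' @param object `screg` fit or trained `screg_model`.
#' @param data counts (`screg_counts` or matrix).
#' @param classes which classes to predict (default all).
#' @param level optional named list: class -> character vector of ontology
#'   nodes to lift to.
#' @param top_k include the top-k leaf labels per cell.
#' @param batch_size forward batch size.
#' @return named list per class: `prob` (cells x leaves), `top1`, `prob_top1`,
#'   optional `lifted`, `topk`.
#' @export
predict_labels <- function(object, data, classes = NULL, level = NULL,
                           top_k = 3L, batch_size = 16L) {
  model <- as_model(object)
  if (is.null(classes)) classes <- names(model$classes)
  unknown <- setdiff(classes, names(model$classes))
  if (length(unknown)) stop("unknown class: ", paste(unknown, collapse = ", "))
  X <- counts_matrix(data, model)
  outs <- run_cells(model, X, batch_size = batch_size)
  res <- stats::setNames(vector("list", length(classes)), classes)
  for (A in classes) {
    prob <- do.call(rbind, lapply(outs, function(o)
      decode_classes(model, o$e_hat)[[A]]$prob))
    rownames(prob) <- rownames(X)
    top1_idx <- max.col(prob, ties.method = "first")
    top1 <- colnames(prob)[top1_idx]
    topk <- t(apply(prob, 1L, function(p)
      names(sort(p, decreasing = TRUE))[seq_len(min(top_k, length(p)))]))
    out <- list(prob = prob, top1 = top1,
                prob_top1 = prob[cbind(seq_len(nrow(prob)), top1_idx)],
                topk = topk)
    if (!is.null(level[[A]]))
      out$lifted <- lift_probabilities(prob, model$classes[[A]], level[[A]])
    res[[A]] <- out
  }
  res
}

#' Export cell embeddings
#'
#' @param object `screg` fit or trained `screg_model`.
#' @param data counts.
#' @param source `"default"` (the default cell token's output embedding, width
#'   d), a class name (that class's disentangled output embedding, width d),
#'   or `"logits:<class>"` (the class decoder's pre-sigmoid logits, width =
#'   number of leaf labels).
#' @param batch_size forward batch size.
#' @return numeric matrix (cells x width).
#' @export
embed_cells <- function(object, data, source = "default", batch_size = 16L) {
  model <- as_model(object)
  X <- counts_matrix(data, model)
  outs <- run_cells(model, X, batch_size = batch_size)
  ph <- model$placeholders
  n_ph <- length(ph)
  if (startsWith(source, "logits:")) {
    A <- sub("^logits:", "", source)
    if (!A %in% names(model$classes)) stop("invalid embedding source: ", source)
    E <- do.call(rbind, lapply(outs, function(o)
      logit_embedding(decode_classes(model, o$e_hat), A)))
  } else {
    if (!source %in% ph || source == "total_count")
      stop("invalid embedding source: ", source)
    pos <- which(ph == source)
    E <- do.call(rbind, lapply(outs, function(o)
      o$e_hat[(seq_len(o$b) - 1L) * n_ph + pos, , drop = FALSE]))
  }
  rownames(E) <- rownames(X)
  E
}
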
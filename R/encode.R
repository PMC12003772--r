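# User-facing encoding operations: expression/total-count embedding, context
# sampling, and token-batch assembly.

#' Embed expression counts
#'
#' Applies the two-layer expression encoder MLP to `log2(x + 1)`; evaluation
#' mode (dropout off), so the result is deterministic.
#'
#' @param model `screg_model`.
#' @param x nonnegative finite counts (vector).
#' @return matrix `length(x)` x `d` of expression embeddings.
#' @export
encode_expression <- function(model, x) {
  if (any(x < 0) || any(!is.finite(x)))
    stop("counts must be nonnegative and finite")
  encmlp_fwd(log2(x + 1), sub_par(model$params, "expr"), train = FALSE)$out
}

#' Embed a cell's total transcript count
#'
#' A separate MLP of the same structure applied to `log2(1 + t)`. The encoded
#' total count is the depth "request" the expression decoder conditions on.
#'
#' @param model `screg_model`.
#' @param t nonnegative totals (vector).
#' @return matrix `length(t)` x `d`.
#' @export
encode_total_count <- function(model, t) {
  if (any(t < 0)) stop("total counts must be nonnegative")
  encmlp_fwd(log2(1 + t), sub_par(model$params, "tc"), train = FALSE)$out
}

#' Sample a gene context for one cell
#'
#' If at least `context_size` genes are expressed, a uniform random subset of
#' the expressed genes is taken; otherwise all expressed genes are kept and
#' padded with uniformly sampled unexpressed genes (expression 0). No
#' duplicates. Uses the R RNG (seed for determinism).
#'
#' @param x count vector over the whole vocabulary.
#' @param context_size number of gene tokens.
#' @return list with `idx` (gene indices) and `x` (their counts).
#' @export
sample_context <- function(x, context_size) {
  n_vocab <- length(x)
  if (context_size > n_vocab)
    stop("context_size exceeds the vocabulary size")
  expressed <- which(x > 0)
  if (length(expressed) >= context_size) {
    idx <- if (length(expressed) == context_size) expressed else
      sample(expressed, context_size)
  } else {
    unexpr <- which(x == 0)
    pad <- if (length(unexpr) == context_size - length(expressed)) unexpr else
      sample(unexpr, context_size - length(expressed))
    idx <- c(expressed, pad)
  }
  list(idx = idx, x = as.numeric(x[idx]))
}

#' Build a token batch for a set of cells
#'
#' Each gene position carries the sum of three embedding streams: the frozen
#' gene identity embedding, the expression embedding of the (log) count, and
#' the sinusoidal encoding of the gene's genome-location index. Placeholder
#' tokens (total-count token first, then the default cell token and one per
#' label class) are appended in the model's fixed placeholder order; they are
#' identical across cells except the total-count token, which adds the encoded
#' per-cell total.
#'
#' @param model `screg_model`.
#' @param idx integer matrix (batch x context) of vocabulary gene indices.
#' @param xs count matrix aligned with `idx`.
#' @param t per-cell totals.
#' @return list of class `screg_tokens`: `token_matrix` (`(b*n) x d`,
#'   cell-major; gene rows then placeholder rows per cell), `gene_rows`,
#'   `ph_rows`, `placeholder_ids`, `b`, `n_ctx`.
#' @export
build_token_batch <- function(model, idx, xs, t) {
  tk <- build_tokens(model, idx, xs, t, train = FALSE)
  structure(list(token_matrix = tk$X, gene_rows = tk$gene_rows,
                 ph_rows = tk$ph_rows, placeholder_ids = model$placeholders,
                 b = tk$b, n_ctx = tk$n_ctx), class = "screg_tokens")
}
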
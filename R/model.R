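# Model assembly: a pre-norm bidirectional transformer over gene tokens plus
# placeholder class tokens, a ZINB expression decoder, and one hierarchical
# class decoder per label class.

#' Model configuration
#'
#' @param d model dimension (divisible by `n_heads`).
#' @param n_heads attention heads per layer.
#' @param n_layers transformer layers.
#' @param context_size default number of gene tokens during training (any
#'   context length >= 1 is accepted at inference).
#' @param dropout dropout rate used throughout.
#' @param stochastic_depth per-layer increment of the stochastic-depth drop
#'   rate (layer l is dropped with probability `stochastic_depth * l` during
#'   training).
#' @param mlp_ratio hidden-width multiplier of the transformer MLP.
#' @param loss expression reconstruction likelihood: zero-inflated negative
#'   binomial (`"zinb"`, default), negative binomial (`"nb"`) or mean squared
#'   error on log counts (`"mse"`).
#' @param contrastive_sign `"as_printed"` minimizes `1 - cos` over the per-cell
#'   class-embedding set; `"repel"` minimizes `1 + cos` (pushes embeddings
#'   apart).
#' @param trainable_gene_embeddings if `TRUE`, gene identity embeddings receive
#'   gradient updates (default `FALSE`: frozen).
#' @return list of class `screg_model_config`.
#' @export
screg_config <- function(d = 64L, n_heads = 2L, n_layers = 2L,
                         context_size = 2200L, dropout = 0.1,
                         stochastic_depth = 0.02, mlp_ratio = 4L,
                         loss = c("zinb", "nb", "mse"),
                         contrastive_sign = c("as_printed", "repel"),
                         trainable_gene_embeddings = FALSE) {
  loss <- match.arg(loss)
  contrastive_sign <- match.arg(contrastive_sign)
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  if (d %% 2L != 0L) stop("d must be even (positional encoding)")
  structure(list(d = as.integer(d), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 context_size = as.integer(context_size),
                 dropout = dropout, stochastic_depth = stochastic_depth,
                 mlp_ratio = as.integer(mlp_ratio), loss = loss,
                 contrastive_sign = contrastive_sign,
                 trainable_gene_embeddings = trainable_gene_embeddings),
            class = "screg_model_config")
}

# extract the "W1", "b1", ... sub-list of a flat parameter list under a prefix
sub_par <- function(params, prefix) {
  nms <- names(params)
  sel <- startsWith(nms, paste0(prefix, "."))
  stats::setNames(params[sel], substring(nms[sel], nchar(prefix) + 2L))
}

#' Initialize a model
#'
#' @param config a [screg_config()].
#' @param vocab a [build_vocab()] gene vocabulary (its `d` must match).
#' @param classes named list of label classes; each element is an
#'   [ontology()] (hierarchical class) or a character vector of labels (flat
#'   class, treated as an ontology whose leaves are all labels).
#' @param seed integer seed for weight initialization.
#' @return object of class `screg_model`.
#' @export
init_model <- function(config, vocab, classes = list(), seed = 0L) {
  stopifnot(inherits(config, "screg_model_config"),
            inherits(vocab, "screg_vocab"))
  if (vocab$d != config$d) stop("vocabulary dimension does not match config d")
  set.seed(seed)
  d <- config$d
  # normalize classes: every class gets an ontology + ordered leaf set
  classes <- lapply(classes, function(cl) {
    if (inherits(cl, "screg_ontology")) return(cl)
    if (is.character(cl)) {
      # flat label list: a root with every label as a leaf child
      return(ontology(data.frame(child = cl, parent = "root")))
    }
    stop("each class must be an ontology or a character label vector")
  })
  placeholders <- c("total_count", "default", names(classes))
  params <- list()
  add <- function(g, prefix) {
    for (nm in names(g)) params[[paste0(prefix, ".", nm)]] <<- g[[nm]]
  }
  add(encmlp_init(d), "expr")
  add(encmlp_init(d), "tc")
  params$ph <- matrix(stats::rnorm(length(placeholders) * d, 0, 0.02),
                      length(placeholders), d,
                      dimnames = list(placeholders, NULL))
  for (l in seq_len(config$n_layers)) {
    pre <- paste0("L", l)
    add(list(ln1.g = rep(1, d), ln1.b = numeric(d),
             Wqkv = matrix(stats::rnorm(3 * d * d, 0, 0.02), d, 3 * d),
             bqkv = numeric(3 * d),
             Wo = matrix(stats::rnorm(d * d, 0, 0.02), d, d),
             bo = numeric(d),
             ln2.g = rep(1, d), ln2.b = numeric(d),
             Wm1 = matrix(stats::rnorm(d * d * config$mlp_ratio, 0, 0.02),
                          d, d * config$mlp_ratio),
             bm1 = numeric(d * config$mlp_ratio),
             Wm2 = matrix(stats::rnorm(d * d * config$mlp_ratio, 0, 0.02),
                          d * config$mlp_ratio, d),
             bm2 = numeric(d)), pre)
  }
  params$lnf.g <- rep(1, d); params$lnf.b <- numeric(d)
  add(decmlp_init(d, if (config$loss == "mse") 1L else 3L), "dec")
  for (A in names(classes)) {
    dA <- length(classes[[A]]$leaves)
    add(decmlp_init(d, dA, final_w_mean = 1, final_b = -0.12),
        paste0("cls.", A))
  }
  structure(list(config = config, vocab = vocab, classes = classes,
                 placeholders = placeholders, params = params),
            class = "screg_model")
}

#' @export
print.screg_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("screg model: %d layers, %d heads, d = %d ",
                     "(%s loss; %d genes; classes: %s; %s parameters)\n"),
              cfg$n_layers, cfg$n_heads, cfg$d, cfg$loss,
              length(x$vocab$gene_ids),
              if (length(x$classes)) paste(names(x$classes), collapse = ", ")
              else "none", format(np, big.mark = ",")))
  invisible(x)
}

# ---- transformer --------------------------------------------------------

attn_layer_fwd <- function(Hn, Wqkv, bqkv, Wo, bo, nh, b, n) {
  d <- ncol(Hn)
  dk <- d / nh
  QKV <- lin_fwd(Hn, Wqkv, bqkv)
  Ct <- matrix(0, nrow(Hn), d)
  Alist <- vector("list", b * nh)
  scale <- 1 / sqrt(dk)
  for (ci in seq_len(b)) {
    rows <- ((ci - 1L) * n + 1L):(ci * n)
    for (h in seq_len(nh)) {
      qc <- ((h - 1L) * dk + 1L):(h * dk)
      A <- softmax_rows(tcrossprod(QKV[rows, qc, drop = FALSE],
                                   QKV[rows, d + qc, drop = FALSE]) * scale)
      Ct[rows, qc] <- A %*% QKV[rows, 2L * d + qc, drop = FALSE]
      Alist[[(ci - 1L) * nh + h]] <- A
    }
  }
  list(out = lin_fwd(Ct, Wo, bo), Hn = Hn, QKV = QKV, Ct = Ct, A = Alist)
}

attn_layer_bwd <- function(dO, cache, Wqkv, Wo, nh, b, n) {
  d <- ncol(dO)
  dk <- d / nh
  scale <- 1 / sqrt(dk)
  lo <- lin_bwd(dO, cache$Ct, Wo)
  dCt <- lo$dX
  QKV <- cache$QKV
  dQKV <- matrix(0, nrow(QKV), 3L * d)
  for (ci in seq_len(b)) {
    rows <- ((ci - 1L) * n + 1L):(ci * n)
    for (h in seq_len(nh)) {
      qc <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$A[[(ci - 1L) * nh + h]]
      Vh <- QKV[rows, 2L * d + qc, drop = FALSE]
      dOh <- dCt[rows, qc, drop = FALSE]
      dV <- crossprod(A, dOh)
      dA <- tcrossprod(dOh, Vh)
      dS <- A * (dA - rowSums(dA * A))
      dQKV[rows, qc] <- (dS %*% QKV[rows, d + qc, drop = FALSE]) * scale
      dQKV[rows, d + qc] <- crossprod(dS, QKV[rows, qc, drop = FALSE]) * scale
      dQKV[rows, 2L * d + qc] <- dV
    }
  }
  lq <- lin_bwd(dQKV, cache$Hn, Wqkv)
  list(dX = lq$dX, dWqkv = lq$dW, dbqkv = lq$db, dWo = lo$dW, dbo = lo$db)
}

# full transformer stack; rows are cell-major blocks of n tokens
tf_fwd <- function(X, params, cfg, b, n, train = FALSE) {
  H <- X
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, ".")
    p_sd <- if (train) cfg$stochastic_depth * l else 0
    k1 <- if (p_sd > 0) (stats::runif(b) >= p_sd) / (1 - p_sd) else rep(1, b)
    k2 <- if (p_sd > 0) (stats::runif(b) >= p_sd) / (1 - p_sd) else rep(1, b)
    r1 <- rep(k1, each = n)
    r2 <- rep(k2, each = n)
    LN1 <- ln_fwd(H, params[[paste0(pre, "ln1.g")]],
                  params[[paste0(pre, "ln1.b")]])
    At <- attn_layer_fwd(LN1$out, params[[paste0(pre, "Wqkv")]],
                         params[[paste0(pre, "bqkv")]],
                         params[[paste0(pre, "Wo")]],
                         params[[paste0(pre, "bo")]], cfg$n_heads, b, n)
    Ad <- dropout_fwd(At$out, cfg$dropout, train)
    H1 <- H + Ad$out * r1
    LN2 <- ln_fwd(H1, params[[paste0(pre, "ln2.g")]],
                  params[[paste0(pre, "ln2.b")]])
    Z1 <- lin_fwd(LN2$out, params[[paste0(pre, "Wm1")]],
                  params[[paste0(pre, "bm1")]])
    G1 <- gelu_fwd(Z1)
    Z2 <- lin_fwd(G1$out, params[[paste0(pre, "Wm2")]],
                  params[[paste0(pre, "bm2")]])
    Md <- dropout_fwd(Z2, cfg$dropout, train)
    H2 <- H1 + Md$out * r2
    caches[[l]] <- list(LN1 = LN1, At = At, Ad = Ad, r1 = r1,
                        LN2 = LN2, Z1 = Z1, G1 = G1, Md = Md, r2 = r2,
                        H1 = H1)
    H <- H2
  }
  LNf <- ln_fwd(H, params$lnf.g, params$lnf.b)
  list(out = LNf$out, LNf = LNf, layers = caches, b = b, n = n)
}

tf_bwd <- function(dY, fw, params, cfg) {
  grads <- list()
  lf <- ln_bwd(dY, fw$LNf, params$lnf.g)
  grads$lnf.g <- lf$dg; grads$lnf.b <- lf$db
  dH <- lf$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", l, ".")
    ca <- fw$layers[[l]]
    dS2 <- dH * ca$r2
    dZ2 <- dropout_bwd(dS2, ca$Md$mask)
    l2 <- lin_bwd(dZ2, ca$G1$out, params[[paste0(pre, "Wm2")]])
    dZ1 <- gelu_bwd(l2$dX, ca$Z1, ca$G1)
    l1 <- lin_bwd(dZ1, ca$LN2$out, params[[paste0(pre, "Wm1")]])
    ln2 <- ln_bwd(l1$dX, ca$LN2, params[[paste0(pre, "ln2.g")]])
    dH1 <- dH + ln2$dX
    dS1 <- dH1 * ca$r1
    dAt <- dropout_bwd(dS1, ca$Ad$mask)
    ab <- attn_layer_bwd(dAt, ca$At, params[[paste0(pre, "Wqkv")]],
                         params[[paste0(pre, "Wo")]], cfg$n_heads,
                         fw$b, fw$n)
    ln1 <- ln_bwd(ab$dX, ca$LN1, params[[paste0(pre, "ln1.g")]])
    grads[[paste0(pre, "Wm2")]] <- l2$dW
    grads[[paste0(pre, "bm2")]] <- l2$db
    grads[[paste0(pre, "Wm1")]] <- l1$dW
    grads[[paste0(pre, "bm1")]] <- l1$db
    grads[[paste0(pre, "ln2.g")]] <- ln2$dg
    grads[[paste0(pre, "ln2.b")]] <- ln2$db
    grads[[paste0(pre, "Wqkv")]] <- ab$dWqkv
    grads[[paste0(pre, "bqkv")]] <- ab$dbqkv
    grads[[paste0(pre, "Wo")]] <- ab$dWo
    grads[[paste0(pre, "bo")]] <- ab$dbo
    grads[[paste0(pre, "ln1.g")]] <- ln1$dg
    grads[[paste0(pre, "ln1.b")]] <- ln1$db
    dH <- dH1 + ln1$dX
  }
  list(dX = dH, grads = grads)
}

# ---- token assembly + full forward --------------------------------------

# Build the (b*n) x d input token matrix for a batch.
# idx: b x n_ctx gene indices into the vocabulary; xs: b x n_ctx counts;
# t: length-b totals. expr_stream = FALSE omits the expression embedding
# (bottleneck decoding); ph_inputs overrides placeholder token rows (a
# (b*n_ph) x d matrix, cell-major).
build_tokens <- function(model, idx, xs, t, train = FALSE,
                         expr_stream = TRUE, ph_inputs = NULL) {
  v <- model$vocab
  cfg <- model$config
  b <- nrow(idx)
  n_ctx <- ncol(idx)
  ph <- model$placeholders
  n_ph <- length(ph)
  n <- n_ctx + n_ph
  flat_idx <- as.integer(t(idx))             # cell-major
  base <- v$id_embeddings[flat_idx, , drop = FALSE] +
    v$pe[flat_idx, , drop = FALSE]
  ec <- NULL
  if (expr_stream) {
    if (any(xs < 0) || any(!is.finite(xs)))
      stop("expression counts must be nonnegative and finite")
    u <- log2(as.numeric(t(xs)) + 1)
    ec <- encmlp_fwd(u, sub_par(model$params, "expr"), cfg$dropout, train)
    base <- base + ec$out
  }
  tcc <- NULL
  if (is.null(ph_inputs)) {
    if (any(t < 0)) stop("total counts must be nonnegative")
    tcc <- encmlp_fwd(log2(1 + t), sub_par(model$params, "tc"),
                      cfg$dropout, train)
    ph_rows_mat <- model$params$ph[rep(seq_len(n_ph), b), , drop = FALSE]
    tc_pos <- which(ph == "total_count")
    ph_rows_mat[(seq_len(b) - 1L) * n_ph + tc_pos, ] <-
      ph_rows_mat[(seq_len(b) - 1L) * n_ph + tc_pos, , drop = FALSE] + tcc$out
  } else {
    stopifnot(nrow(ph_inputs) == b * n_ph, ncol(ph_inputs) == cfg$d)
    ph_rows_mat <- ph_inputs
  }
  X <- matrix(0, b * n, cfg$d)
  gene_rows <- as.integer(outer(seq_len(n_ctx), (seq_len(b) - 1L) * n, "+"))
  ph_rows <- as.integer(outer(n_ctx + seq_len(n_ph), (seq_len(b) - 1L) * n, "+"))
  X[gene_rows, ] <- base
  X[ph_rows, ] <- ph_rows_mat
  list(X = X, b = b, n = n, n_ctx = n_ctx, n_ph = n_ph,
       gene_rows = gene_rows, ph_rows = ph_rows, ec = ec, tcc = tcc,
       flat_idx = flat_idx, own_ph = is.null(ph_inputs))
}

#' Run the transformer on a token batch
#'
#' Full bidirectional attention (no mask), pre-norm residual blocks,
#' stochastic depth active only in training mode. With `cache_qk = TRUE` the
#' per-layer query/key projections are kept for network extraction; caching
#' changes no output value.
#'
#' @param model `screg_model`.
#' @param idx integer matrix (batch x context) of gene indices into the
#'   vocabulary.
#' @param xs count matrix aligned with `idx`.
#' @param t per-cell total counts (the requested output depth).
#' @param train enable dropout/stochastic depth.
#' @param cache_qk keep per-layer Q/K projections.
#' @return list with `e` (gene output embeddings, `(b*n_ctx) x d`, cell-major),
#'   `e_hat` (placeholder output embeddings, `(b*n_ph) x d`), `placeholders`,
#'   and (opt-in) `qk`.
#' @export
forward <- function(model, idx, xs, t, train = FALSE, cache_qk = FALSE) {
  stopifnot(inherits(model, "screg_model"))
  if (max(idx) > length(model$vocab$gene_ids) || min(idx) < 1)
    stop("gene index outside vocabulary")
  tk <- build_tokens(model, idx, xs, t, train = train)
  fw <- tf_fwd(tk$X, model$params, model$config, tk$b, tk$n, train = train)
  out <- list(e = fw$out[tk$gene_rows, , drop = FALSE],
              e_hat = fw$out[tk$ph_rows, , drop = FALSE],
              placeholders = model$placeholders,
              b = tk$b, n_ctx = tk$n_ctx, n_ph = tk$n_ph)
  if (cache_qk) {
    d <- model$config$d
    out$qk <- lapply(seq_len(model$config$n_layers), function(l)
      fw$layers[[l]]$At$QKV[, seq_len(2L * d), drop = FALSE])
    out$gene_rows <- tk$gene_rows
    out$flat_idx <- tk$flat_idx
  }
  out
}

# ---- decoders -----------------------------------------------------------

clamp <- function(x, lo = -15, hi = 15) pmin(pmax(x, lo), hi)

#' Decode ZINB expression parameters from gene output embeddings
#'
#' A two-layer MLP maps each gene embedding to three raw outputs `(a, b, c)`,
#' interpreted as `mu = exp(clamp(a))`, `theta = exp(clamp(b))` and the
#' zero-inflation logit `rho = c` (so `pi = sigmoid(rho)`). Clamping to
#' \[-15, 15\] prevents overflow.
#'
#' @param model `screg_model`.
#' @param e gene output embedding matrix (rows = gene positions).
#' @return list with vectors/matrices `mu`, `theta`, `rho` (same row layout as
#'   `e`).
#' @export
decode_expression <- function(model, e) {
  dd <- decmlp_fwd(e, sub_par(model$params, "dec"))
  raw <- dd$out
  if (any(!is.finite(raw)))
    stop("non-finite activation in the expression decoder output layer")
  if (model$config$loss == "mse")
    return(list(logcount = raw[, 1L]))
  list(mu = exp(clamp(raw[, 1L])), theta = exp(clamp(raw[, 2L])),
       rho = raw[, 3L])
}

#' Decode class-label predictions from placeholder output embeddings
#'
#' @param model `screg_model`.
#' @param e_hat placeholder output embeddings as returned by [forward()].
#' @return named list (one entry per class) with `logits` (b x d_A, leaf
#'   order = the class ontology's leaf order), `sigmoid` (elementwise sigmoid
#'   activation), `prob` (softmax over leaves) and `leaf` (argmax leaf label).
#' @export
decode_classes <- function(model, e_hat) {
  ph <- model$placeholders
  n_ph <- length(ph)
  b <- nrow(e_hat) / n_ph
  out <- list()
  for (A in names(model$classes)) {
    pos <- which(ph == A)
    rows <- (seq_len(b) - 1L) * n_ph + pos
    z <- decmlp_fwd(e_hat[rows, , drop = FALSE],
                    sub_par(model$params, paste0("cls.", A)))$out
    leaves <- model$classes[[A]]$leaves
    colnames(z) <- leaves
    pr <- t(apply(z, 1L, softmax_vec))
    if (length(leaves) == 1L) pr <- matrix(pr, ncol = 1L)
    colnames(pr) <- leaves
    out[[A]] <- list(logits = z, sigmoid = sigmoid(z), prob = pr,
                     leaf = leaves[max.col(z, ties.method = "first")])
  }
  out
}

#' Classifier logits as a cell embedding
#'
#' The pre-sigmoid leaf logits of one class, usable as a low-dimensional cell
#' embedding for visualization and clustering.
#'
#' @param prediction result of [decode_classes()].
#' @param class class name.
#' @return numeric matrix (cells x leaf labels).
#' @export
logit_embedding <- function(prediction, class) {
  if (!class %in% names(prediction)) stop("class not decoded: ", class)
  prediction[[class]]$logits
}

#' Lift leaf probabilities to a coarser ontology node
#'
#' The probability of an internal node is the sum of its descendant leaves'
#' probabilities; over any antichain covering all leaves the lifted
#' probabilities sum to 1.
#'
#' @param prob matrix of leaf probabilities (columns named by leaf).
#' @param onto the class [ontology()].
#' @param nodes nodes to lift to (default: all nodes).
#' @return matrix (cells x nodes) of lifted probabilities.
#' @export
lift_probabilities <- function(prob, onto, nodes = onto$nodes) {
  out <- vapply(nodes, function(v) {
    lv <- leaf_descendants(onto, v)
    rowSums(prob[, lv, drop = FALSE])
  }, numeric(nrow(prob)))
  if (nrow(prob) == 1L) out <- matrix(out, 1L, dimnames = list(NULL, nodes))
  out
}
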
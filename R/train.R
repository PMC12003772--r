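# Joint pretraining: denoising + classification + contrastive + bottleneck,
# summed without scaling, optimized with decoupled weight decay (AdamW),
# warmup, plateau LR decay, early stopping, optional stochastic weight
# averaging, and weighted random sampling over label groups.

# ---- total loss with gradients ------------------------------------------

# One training step's loss and parameter gradients.
# idx, xs_noisy, xs_true: b x n_ctx; t_true: length b; labels: named list of
# per-class label vectors (length b, NA = unknown).
loss_and_grads <- function(model, idx, xs_noisy, xs_true, t_true, labels,
                           train = TRUE,
                           tasks = c("denoising", "classification",
                                     "contrastive", "bottleneck"),
                           want_grads = TRUE) {
  cfg <- model$config
  params <- model$params
  b <- nrow(idx); n_ctx <- ncol(idx)
  ph <- model$placeholders; n_ph <- length(ph)
  tc_pos <- which(ph == "total_count")
  emb_pos <- which(ph != "total_count")      # disentangled embedding set
  N1 <- b * n_ctx

  grads <- list()
  add_grads <- function(g) grads <<- grads_add(grads, g)
  comp <- c(denoising = 0, classification = 0, contrastive = 0,
            bottleneck = 0)

  # ---- pass 1: encoder on the noisy profile
  tk1 <- build_tokens(model, idx, xs_noisy, t_true, train = train)
  fw1 <- tf_fwd(tk1$X, params, cfg, tk1$b, tk1$n, train = train)
  e1 <- fw1$out[tk1$gene_rows, , drop = FALSE]
  eh1 <- fw1$out[tk1$ph_rows, , drop = FALSE]
  dHf1 <- matrix(0, nrow(fw1$out), cfg$d)

  dec_par <- sub_par(params, "dec")
  recon <- function(e_rows, x_target) {
    dd <- decmlp_fwd(e_rows, dec_par)
    raw <- dd$out
    x <- as.numeric(t(x_target))
    if (cfg$loss == "mse") {
      target <- log2(x + 1)
      loss <- mean((raw[, 1L] - target)^2)
      dRaw <- matrix(2 * (raw[, 1L] - target) / length(x), ncol = 1L)
    } else {
      a <- clamp(raw[, 1L]); bb <- clamp(raw[, 2L])
      mu <- exp(a); th <- exp(bb); rho <- raw[, 3L]
      zi <- cfg$loss == "zinb"
      loss <- if (zi) zinb_nll(x, mu, th, rho) else nb_nll(x, mu, th)
      g <- zinb_nll_grad(x, mu, th, rho, zero_inflated = zi)
      dRaw <- cbind(g$dmu * mu * (abs(raw[, 1L]) < 15),
                    g$dtheta * th * (abs(raw[, 2L]) < 15),
                    g$drho) / length(x)
    }
    list(loss = loss, dd = dd, dRaw = dRaw)
  }

  if ("denoising" %in% tasks) {
    rc <- recon(e1, xs_true)
    comp["denoising"] <- rc$loss
    if (want_grads) {
      db <- decmlp_bwd(rc$dRaw, rc$dd$cache, dec_par)
      add_grads(grads_prefix(db$grads, "dec"))
      dHf1[tk1$gene_rows, ] <- dHf1[tk1$gene_rows, ] + db$dX
    }
  }

  if ("classification" %in% tasks && length(model$classes)) {
    for (A in names(model$classes)) {
      pos <- which(ph == A)
      rows <- (seq_len(b) - 1L) * n_ph + pos
      cpar <- sub_par(params, paste0("cls.", A))
      dd <- decmlp_fwd(eh1[rows, , drop = FALSE], cpar)
      hc <- hierarchical_ce_grad(dd$out, labels[[A]], model$classes[[A]])
      comp["classification"] <- comp["classification"] + hc$loss
      if (want_grads && hc$n > 0L) {
        db <- decmlp_bwd(hc$dZ, dd$cache, cpar)
        add_grads(grads_prefix(db$grads, paste0("cls.", A)))
        prows <- tk1$ph_rows[rows]
        dHf1[prows, ] <- dHf1[prows, ] + db$dX
      }
    }
  }

  if ("contrastive" %in% tasks && length(emb_pos) >= 2L) {
    closs <- 0
    for (i in seq_len(b)) {
      rows <- (i - 1L) * n_ph + emb_pos
      cg <- contrastive_grad(eh1[rows, , drop = FALSE],
                             cfg$contrastive_sign)
      closs <- closs + cg$loss / b
      if (want_grads) {
        prows <- tk1$ph_rows[rows]
        dHf1[prows, ] <- dHf1[prows, ] + cg$dE / b
      }
    }
    comp["contrastive"] <- closs
  }

  # ---- pass 2: bottleneck decode from the pass-1 cell embeddings
  tk2 <- fw2 <- tcc2 <- NULL
  if ("bottleneck" %in% tasks) {
    tcc2 <- encmlp_fwd(log2(1 + t_true), sub_par(params, "tc"),
                       cfg$dropout, train)
    ph_inputs <- eh1
    tc_rows_ph <- (seq_len(b) - 1L) * n_ph + tc_pos
    ph_inputs[tc_rows_ph, ] <-
      matrix(params$ph[tc_pos, ], b, cfg$d, byrow = TRUE) + tcc2$out
    tk2 <- build_tokens(model, idx, xs_noisy, t_true, train = train,
                        expr_stream = FALSE, ph_inputs = ph_inputs)
    fw2 <- tf_fwd(tk2$X, params, cfg, tk2$b, tk2$n, train = train)
    rc2 <- recon(fw2$out[tk2$gene_rows, , drop = FALSE], xs_true)
    comp["bottleneck"] <- rc2$loss
    if (want_grads) {
      db2 <- decmlp_bwd(rc2$dRaw, rc2$dd$cache, dec_par)
      add_grads(grads_prefix(db2$grads, "dec"))
      dHf2 <- matrix(0, nrow(fw2$out), cfg$d)
      dHf2[tk2$gene_rows, ] <- db2$dX
      tb2 <- tf_bwd(dHf2, fw2, params, cfg)
      add_grads(tb2$grads)
      dX2 <- tb2$dX
      # placeholder input rows of pass 2 came from pass-1 outputs (class and
      # default embeddings) or from ph + tc-encoder (total-count row)
      dPh2 <- dX2[tk2$ph_rows, , drop = FALSE]
      non_tc <- as.integer(outer(emb_pos, (seq_len(b) - 1L) * n_ph, "+"))
      dEh_from2 <- matrix(0, b * n_ph, cfg$d)
      dEh_from2[non_tc, ] <- dPh2[non_tc, , drop = FALSE]
      dHf1[tk1$ph_rows, ] <- dHf1[tk1$ph_rows, ] + dEh_from2
      dTc2 <- dPh2[tc_rows_ph, , drop = FALSE]
      eb2 <- encmlp_bwd(dTc2, tcc2$cache, sub_par(params, "tc"))
      add_grads(grads_prefix(eb2$grads, "tc"))
      gph <- matrix(0, n_ph, cfg$d, dimnames = dimnames(params$ph))
      gph[tc_pos, ] <- colSums(dTc2)
      add_grads(list(ph = gph))
      if (cfg$trainable_gene_embeddings) {
        dG <- dX2[tk2$gene_rows, , drop = FALSE]
        gG <- matrix(0, length(model$vocab$gene_ids), cfg$d)
        for (k in seq_along(tk2$flat_idx))
          gG[tk2$flat_idx[k], ] <- gG[tk2$flat_idx[k], ] + dG[k, ]
        add_grads(list(gene_emb = gG))
      }
    }
  }

  total <- sum(comp)
  if (!is.finite(total)) {
    bad <- names(comp)[!is.finite(comp)]
    stop("non-finite loss component: ", paste(bad, collapse = ", "))
  }
  if (!want_grads)
    return(list(total = total, components = comp, grads = NULL))

  # ---- backprop pass 1
  tb1 <- tf_bwd(dHf1, fw1, params, cfg)
  add_grads(tb1$grads)
  dX1 <- tb1$dX
  dGene1 <- dX1[tk1$gene_rows, , drop = FALSE]
  if (!is.null(tk1$ec)) {
    eb <- encmlp_bwd(dGene1, tk1$ec$cache, sub_par(params, "expr"))
    add_grads(grads_prefix(eb$grads, "expr"))
  }
  if (cfg$trainable_gene_embeddings) {
    gG <- grads$gene_emb %||% matrix(0, length(model$vocab$gene_ids), cfg$d)
    for (k in seq_along(tk1$flat_idx))
      gG[tk1$flat_idx[k], ] <- gG[tk1$flat_idx[k], ] + dGene1[k, ]
    grads$gene_emb <- gG
  }
  dPh1 <- dX1[tk1$ph_rows, , drop = FALSE]
  gph <- matrix(0, n_ph, cfg$d, dimnames = dimnames(params$ph))
  for (p in seq_len(n_ph)) {
    rows <- (seq_len(b) - 1L) * n_ph + p
    gph[p, ] <- colSums(dPh1[rows, , drop = FALSE])
  }
  add_grads(list(ph = gph))
  tc_rows1 <- (seq_len(b) - 1L) * n_ph + tc_pos
  eb_tc <- encmlp_bwd(dPh1[tc_rows1, , drop = FALSE], tk1$tcc$cache,
                      sub_par(params, "tc"))
  add_grads(grads_prefix(eb_tc$grads, "tc"))

  list(total = total, components = comp, grads = grads)
}

# ---- optimizer ----------------------------------------------------------

adamw_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, clip) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(nrm) && nrm > clip)
    grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

# ---- weighted random sampler --------------------------------------------

#' Weighted random sampler over label groups
#'
#' Cells are grouped by the joint tuple of their labels; each cell's sampling
#' weight is `factor / (count + factor)` where `count` is its group size, so
#' rare label combinations are oversampled but a group is never favored more
#' than `factor`-fold per cell.
#'
#' @param labels data.frame of per-cell labels (all columns define the group).
#' @param factor rescale factor (default 50).
#' @return list with `weights` (per cell, in (0, 1\]), `group` (per-cell group
#'   id) and `draw(n)` returning `n` cell indices sampled with replacement
#'   proportionally to the weights.
#' @export
group_sampler <- function(labels, factor = 50) {
  if (NROW(labels) == 0L) stop("empty dataset")
  grp <- if (is.data.frame(labels))
    interaction(labels, drop = TRUE, sep = "|") else factor(labels)
  cnt <- table(grp)
  w <- as.numeric(factor / (cnt[grp] + factor))
  list(weights = w, group = grp,
       draw = function(n) sample.int(length(w), n, replace = TRUE, prob = w))
}

# ---- training loop ------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the optimization recipe the model was designed with:
#' AdamW (decoupled weight decay 0.01), learning rate 1e-4 with 500 warmup
#' steps, gradient clipping at global norm 100, batch size 64, plateau LR
#' decay by 0.6 with patience 1, early stop after 3 consecutive validation
#' increases, 98/2 train/validation split, downsampling noise r = 0.6.
#'
#' @param steps total optimization steps.
#' @param batch_size cells per step.
#' @param lr peak learning rate.
#' @param weight_decay decoupled weight decay.
#' @param warmup linear warmup steps.
#' @param clip global gradient-norm clip.
#' @param r,s downsampling dropout fraction and scale.
#' @param context_size gene tokens per cell (default: model config).
#' @param val_frac held-out validation fraction.
#' @param val_every validation cadence in steps.
#' @param lr_decay,lr_patience plateau decay factor / patience (in validation
#'   rounds).
#' @param early_stop_patience consecutive validation increases before stopping.
#' @param swa enable stochastic weight averaging over the tail of training.
#' @param swa_start fraction of `steps` after which SWA averaging begins.
#' @param swa_lr constant learning rate during the SWA phase.
#' @param sampler_factor weighted-sampler rescale factor.
#' @param tasks which loss components to train.
#' @param seed integer seed.
#' @return list of class `screg_train_config`.
#' @export
train_config <- function(steps = 1000, batch_size = 64, lr = 1e-4,
                         weight_decay = 0.01, warmup = 500, clip = 100,
                         r = 0.6, s = 0.55, context_size = NULL,
                         val_frac = 0.02, val_every = 100,
                         lr_decay = 0.6, lr_patience = 1,
                         early_stop_patience = 3,
                         swa = FALSE, swa_start = 0.75, swa_lr = 0.03,
                         sampler_factor = 50,
                         tasks = c("denoising", "classification",
                                   "contrastive", "bottleneck"),
                         seed = 1L) {
  structure(as.list(environment()), class = "screg_train_config")
}

# Plateau LR decay + early stopping, driven by successive validation losses.
# Exposed as a closure so the mechanism is testable with mocked losses:
# update(loss) returns list(lr, stop).
plateau_scheduler <- function(lr, decay = 0.6, patience = 1L,
                              stop_patience = 3L) {
  best <- Inf; worse <- 0L; plateau <- 0L
  list(update = function(loss) {
    if (loss < best - 1e-12) {
      best <<- loss; worse <<- 0L; plateau <<- 0L
    } else {
      worse <<- worse + 1L; plateau <<- plateau + 1L
      if (plateau >= patience) {
        lr <<- lr * decay
        plateau <<- 0L
      }
    }
    list(lr = lr, stop = worse >= stop_patience)
  })
}

# assemble one minibatch: downsample full profiles, sample contexts
make_batch <- function(data, cells, context_size, r, s, class_names) {
  b <- length(cells)
  X <- as.matrix(data$counts[cells, , drop = FALSE])
  idx <- matrix(0L, b, context_size)
  xs_noisy <- xs_true <- matrix(0, b, context_size)
  for (i in seq_len(b)) {
    noisy <- downsample(X[i, ], r = r, s = s)
    ctx <- sample_context(noisy, context_size)
    idx[i, ] <- ctx$idx
    xs_noisy[i, ] <- ctx$x
    xs_true[i, ] <- X[i, ctx$idx]
  }
  labels <- lapply(class_names, function(A) {
    if (A %in% names(data$cell_labels))
      as.character(data$cell_labels[cells, A]) else rep(NA_character_, b)
  })
  names(labels) <- class_names
  list(idx = idx, xs_noisy = xs_noisy, xs_true = xs_true,
       t_true = rowSums(X), labels = labels)
}

#' Train a model
#'
#' @param model an [init_model()] model.
#' @param data `screg_counts` training data (QC is the caller's business; see
#'   [qc_filter()]).
#' @param control a [train_config()].
#' @param verbose print progress.
#' @return list with the trained `model`, a per-step `history` data.frame, a
#'   `validation` data.frame, and `val_cells` (indices held out).
#' @export
train_model <- function(model, data, control = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "screg_model"), inherits(data, "screg_counts"))
  ctl <- control
  set.seed(ctl$seed)
  n <- nrow(data$counts)
  n_ctx <- ctl$context_size %||% min(model$config$context_size,
                                     ncol(data$counts))
  n_val <- max(1L, floor(ctl$val_frac * n))
  val_cells <- sample.int(n, n_val)
  train_cells <- setdiff(seq_len(n), val_cells)
  smp <- group_sampler(data$cell_labels[train_cells, , drop = FALSE],
                       ctl$sampler_factor)
  class_names <- names(model$classes)

  # frozen validation batch: same noisy profiles/contexts at every evaluation
  val_batch <- make_batch(data, val_cells[seq_len(min(128L, n_val))],
                          n_ctx, ctl$r, ctl$s, class_names)

  opt <- adamw_init(model$params)
  hist <- vector("list", ctl$steps)
  vals <- list()
  lr_now <- ctl$lr
  sched <- plateau_scheduler(ctl$lr, ctl$lr_decay, ctl$lr_patience,
                             ctl$early_stop_patience)
  swa_sum <- NULL; swa_n <- 0L
  stopped_at <- NA_integer_

  for (step in seq_len(ctl$steps)) {
    in_swa <- ctl$swa && step > ctl$swa_start * ctl$steps
    lr_t <- if (in_swa) ctl$swa_lr else lr_now * min(1, step / ctl$warmup)
    bi <- train_cells[smp$draw(ctl$batch_size)]
    ba <- make_batch(data, bi, n_ctx, ctl$r, ctl$s, class_names)
    lg <- tryCatch(
      loss_and_grads(model, ba$idx, ba$xs_noisy, ba$xs_true, ba$t_true,
                     ba$labels, train = TRUE, tasks = ctl$tasks),
      error = function(e)
        stop(sprintf("training diverged at step %d: %s", step,
                     conditionMessage(e)), call. = FALSE))
    g <- clip_grads(lg$grads, ctl$clip)
    up <- adamw_step(model$params, g, opt, lr_t, ctl$weight_decay)
    model$params <- up$params
    opt <- up$state
    if (model$config$trainable_gene_embeddings && !is.null(g$gene_emb))
      model$vocab$id_embeddings <- model$vocab$id_embeddings -
        lr_t * g$gene_emb
    hist[[step]] <- c(step = step, total = lg$total, lg$components,
                      lr = lr_t)
    if (in_swa) {
      swa_sum <- if (is.null(swa_sum)) model$params else
        Map(`+`, swa_sum, model$params)
      swa_n <- swa_n + 1L
    }
    if (step %% ctl$val_every == 0L || step == ctl$steps) {
      vl <- loss_and_grads(model, val_batch$idx, val_batch$xs_noisy,
                           val_batch$xs_true, val_batch$t_true,
                           val_batch$labels, train = FALSE,
                           tasks = ctl$tasks, want_grads = FALSE)$total
      vals[[length(vals) + 1L]] <- c(step = step, val_loss = vl)
      if (verbose)
        message(sprintf("step %d: train %.4f val %.4f lr %.2e",
                        step, lg$total, vl, lr_t))
      act <- sched$update(vl)
      lr_now <- act$lr
      if (act$stop) {
        stopped_at <- step
        break
      }
    }
  }
  if (ctl$swa && swa_n > 0L)
    model$params <- lapply(swa_sum, function(p) p / swa_n)
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  vals <- as.data.frame(do.call(rbind, vals))
  list(model = model, history = hist, validation = vals,
       val_cells = val_cells, stopped_at = stopped_at)
}

# ---- the fitting front-end ----------------------------------------------

#' Fit a single-cell transformer
#'
#' The package's main entry point: builds a gene vocabulary from the dataset's
#' gene table, initializes a transformer with one placeholder token per label
#' class, and pretrains it jointly on denoising (ZINB reconstruction of the
#' true counts from a downsampled profile), bottleneck autoencoding,
#' hierarchical label classification and contrastive disentanglement.
#'
#' @param data `screg_counts` (see [simulate_cells()] / [read_counts_mtx()]).
#' @param classes named list of label classes to predict: each element an
#'   [ontology()] or character label vector; names must be columns of
#'   `data$cell_labels`. Default: every label column as a flat class.
#' @param config model architecture, a [screg_config()].
#' @param control optimization settings, a [train_config()].
#' @param embeddings optional precomputed gene identity embedding matrix.
#' @param seed integer seed (weights, sampling, dropout).
#' @param verbose print progress.
#' @return object of class `screg` with elements `model`, `history`,
#'   `validation`, `data` (the training data), `val_cells`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_cells = 300, n_genes = 40, n_groups = 3, seed = 1)
#' dat <- simulate_cells(cfg)
#' fit <- screg(dat, config = screg_config(d = 16, n_layers = 1),
#'              control = train_config(steps = 20, batch_size = 8,
#'                                     warmup = 10, context_size = 12))
#' print(fit)
#' }
#' @export
screg <- function(data, classes = NULL, config = screg_config(),
                  control = train_config(), embeddings = NULL,
                  seed = 1L, verbose = FALSE) {
  stopifnot(inherits(data, "screg_counts"))
  if (is.null(classes)) {
    classes <- lapply(data$cell_labels, function(col)
      sort(unique(as.character(col[!is.na(col)]))))
  }
  vocab <- build_vocab(data$gene_table, d = config$d,
                       embeddings = embeddings, seed = seed)
  model <- init_model(config, vocab, classes, seed = seed)
  tr <- train_model(model, data, control = control, verbose = verbose)
  structure(list(model = tr$model, history = tr$history,
                 validation = tr$validation, data = data,
                 val_cells = tr$val_cells, stopped_at = tr$stopped_at,
                 control = control, call = match.call()),
            class = "screg")
}
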
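# Shared fixtures, built in code.

# small labeled dataset with a planted network
tiny_data <- function(n_cells = 200, n_genes = 30, n_groups = 3, seed = 2,
                      onto = NULL, ...) {
  cfg <- synth_config(n_cells = n_cells, n_genes = n_genes,
                      n_groups = n_groups, seed = seed, ...)
  simulate_cells(cfg, onto = onto)
}

# a deterministic untrained model over a dataset's vocabulary
tiny_model <- function(dat, d = 16, n_heads = 2, n_layers = 1,
                       classes = list(), seed = 1, ...) {
  vocab <- build_vocab(dat$gene_table, d = d, seed = seed)
  init_model(screg_config(d = d, n_heads = n_heads, n_layers = n_layers, ...),
             vocab, classes = classes, seed = seed)
}

# hand-rolled counts container for constructed QC fixtures
counts_fixture <- function(X) {
  colnames(X) <- sprintf("g%02d", seq_len(ncol(X)))
  rownames(X) <- sprintf("c%02d", seq_len(nrow(X)))
  gt <- data.frame(gene_id = colnames(X), chromosome = "chr1",
                   start = seq_len(ncol(X)) * 20000)
  labels <- data.frame(cell_type = rep("a", nrow(X)), row.names = rownames(X))
  screg:::new_counts(Matrix::Matrix(X, sparse = TRUE), gt, labels)
}

# the 2-layer / 2-head / d = 64 smoke-test fits on 5k-cell synthetic data,
# one per seed, shared between the training-smoke checks and downstream
# property tests (memoized; ~2.5 min each)
smoke_fit <- function(seed) {
  key <- paste0("smoke", seed)
  if (is.null(.toy_env[[key]])) {
    onto <- make_ontology(4, depth = 2, seed = 3)
    cfg <- synth_config(n_cells = 5000, n_genes = 80, n_groups = 4,
                        mean_depth = 1500, seed = seed)
    dat <- simulate_cells(cfg, onto = onto)
    .toy_env[[key]] <- screg(
      dat, classes = list(cell_type = onto),
      config = screg_config(d = 64, n_heads = 2, n_layers = 2),
      control = train_config(steps = 2000, batch_size = 8, lr = 1e-3,
                             warmup = 100, context_size = 16,
                             val_every = 200, seed = seed),
      seed = seed)
  }
  .toy_env[[key]]
}

# one small trained fit, shared across mechanism tests (memoized)
.toy_env <- new.env()
toy_fit <- function() {
  if (is.null(.toy_env$fit)) {
    onto <- make_ontology(3, depth = 2, seed = 3)
    dat <- tiny_data(n_cells = 600, n_genes = 40, n_groups = 3, seed = 4,
                     onto = onto, mean_depth = 1200)
    .toy_env$fit <- screg(
      dat, classes = list(cell_type = onto),
      config = screg_config(d = 32, n_heads = 2, n_layers = 1),
      control = train_config(steps = 300, batch_size = 8, lr = 1e-3,
                             warmup = 50, context_size = 12, val_every = 150,
                             seed = 1),
      seed = 1)
  }
  .toy_env$fit
}
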
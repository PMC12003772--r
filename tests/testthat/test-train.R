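test_that("group sampler weights follow 50/(count+50) and cap rare-group boost", {
  labels <- data.frame(cell_type = c(rep("a", 50), rep("b", 2), "c"))
  smp <- group_sampler(labels, factor = 50)
  expect_equal(smp$weights[1], 50 / (50 + 50))        # size-50 group -> 0.5
  expect_equal(smp$weights[51], 50 / (2 + 50))
  expect_equal(smp$weights[53], 50 / (1 + 50))
  # strictly decreasing in group size
  sizes <- c(1, 5, 50, 1000, 1e6)
  w <- 50 / (sizes + 50)
  expect_true(all(diff(w) < 0))
  # a group's total expected draw mass is capped ~50x per cell:
  # expected draws ratio between a 1e6-cell group and a singleton <= 51
  expect_lte((1e6 * w[5]) / (1 * w[1]), 51)
  expect_error(group_sampler(data.frame(x = character(0))), "empty")
})

test_that("observed sampling frequencies match the weights", {
  labels <- data.frame(g = c(rep("big", 900), rep("small", 100)))
  smp <- group_sampler(labels)
  set.seed(5)
  draws <- smp$draw(40000)
  p_small_exp <- sum(smp$weights[901:1000]) / sum(smp$weights)
  p_small_obs <- mean(draws > 900)
  se <- sqrt(p_small_exp * (1 - p_small_exp) / 40000)
  expect_lt(abs(p_small_obs - p_small_exp), 3 * se + 1e-4)
})

test_that("plateau decay and early stopping follow the configured patience", {
  sched <- screg:::plateau_scheduler(lr = 1, decay = 0.6, patience = 1,
                                     stop_patience = 3)
  # improving losses: no decay, no stop
  expect_equal(sched$update(10), list(lr = 1, stop = FALSE))
  expect_equal(sched$update(9), list(lr = 1, stop = FALSE))
  # three consecutive increases: decay each round, stop exactly at the third
  s1 <- sched$update(9.5); expect_equal(s1$lr, 0.6); expect_false(s1$stop)
  s2 <- sched$update(9.6); expect_equal(s2$lr, 0.36); expect_false(s2$stop)
  s3 <- sched$update(9.7); expect_true(s3$stop)
  # an improvement resets the streak
  sched2 <- screg:::plateau_scheduler(1, 0.6, 1, 3)
  sched2$update(10); sched2$update(11); sched2$update(12)
  expect_false(sched2$update(5)$stop)
  expect_false(sched2$update(6)$stop)
})

test_that("dropping a task removes exactly its loss component", {
  dat <- tiny_data(seed = 2)
  onto <- make_ontology(3, depth = 2, seed = 3)
  model <- tiny_model(dat, d = 16, classes = list(cell_type = onto))
  X <- as.matrix(dat$counts[1:3, ])
  set.seed(1)
  idx <- t(vapply(1:3, function(i) sample_context(X[i, ], 6)$idx, integer(6)))
  xs <- t(vapply(1:3, function(i) X[i, idx[i, ]], numeric(6)))
  labels <- list(cell_type = c("leaf1", "leaf2", "leaf3"))
  all_tasks <- c("denoising", "classification", "contrastive", "bottleneck")
  full <- screg:::loss_and_grads(model, idx, xs, xs, rowSums(X), labels,
                                 train = FALSE, want_grads = FALSE)
  expect_equal(sum(full$components), full$total, tolerance = 1e-6)
  for (drop in all_tasks) {
    part <- screg:::loss_and_grads(model, idx, xs, xs, rowSums(X), labels,
                                   train = FALSE, want_grads = FALSE,
                                   tasks = setdiff(all_tasks, drop))
    expect_equal(part$components[[drop]], 0)
    kept <- setdiff(all_tasks, drop)
    expect_equal(part$components[kept], full$components[kept],
                 tolerance = 1e-10)
  }
})

test_that("bottleneck decoding reconstructs from embeddings alone", {
  dat <- tiny_data(seed = 2)
  model <- tiny_model(dat, d = 16)
  X <- as.matrix(dat$counts[1:2, ])
  idx <- rbind(1:5, 1:5)
  xs <- rbind(X[1, 1:5], X[2, 1:5])
  # structural: without the expression stream, gene tokens are identity +
  # location only
  tk <- screg:::build_tokens(model, idx, xs, rowSums(X), expr_stream = FALSE,
                             ph_inputs = matrix(0, 2 * length(model$placeholders), 16))
  flat <- as.integer(t(idx))
  expect_equal(tk$X[tk$gene_rows, ],
               model$vocab$id_embeddings[flat, ] + model$vocab$pe[flat, ],
               ignore_attr = TRUE)
  # swapping two cells' embedding sets swaps their reconstructions
  set.seed(3)
  ph_in <- matrix(rnorm(2 * length(model$placeholders) * 16),
                  2 * length(model$placeholders), 16)
  n_ph <- length(model$placeholders)
  swapped <- ph_in[c((n_ph + 1):(2 * n_ph), 1:n_ph), ]
  run <- function(ph) {
    tk <- screg:::build_tokens(model, idx, xs, rowSums(X),
                               expr_stream = FALSE, ph_inputs = ph)
    fw <- screg:::tf_fwd(tk$X, model$params, model$config, tk$b, tk$n)
    decode_expression(model, fw$out[tk$gene_rows, ])$mu
  }
  mu1 <- run(ph_in)
  mu2 <- run(swapped)
  expect_equal(mu1[1:5], mu2[6:10])
  expect_equal(mu1[6:10], mu2[1:5])
})

test_that("the bottleneck loss backpropagates into encoder weights", {
  dat <- tiny_data(seed = 2)
  model <- tiny_model(dat, d = 8, n_heads = 2)
  X <- as.matrix(dat$counts[1:2, ])
  idx <- rbind(1:4, 2:5)
  xs <- rbind(X[1, 1:4], X[2, 2:5])
  f <- function(m) screg:::loss_and_grads(m, idx, xs, xs, rowSums(X),
                                          list(), train = FALSE,
                                          want_grads = FALSE,
                                          tasks = "bottleneck")$total
  lg <- screg:::loss_and_grads(model, idx, xs, xs, rowSums(X), list(),
                               train = FALSE, tasks = "bottleneck")
  # encoder-side parameters get nonzero gradient only via the bottleneck's
  # dependence on the pass-1 embeddings
  expect_gt(sqrt(sum(lg$grads$expr.W2^2)), 0)
  eps <- 1e-5
  for (nm in c("expr.W2", "L1.Wqkv")) {
    i <- which.max(abs(lg$grads[[nm]]))
    up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    expect_equal(lg$grads[[nm]][i], (f(up) - f(dn)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("short training runs are deterministic and reduce the loss", {
  onto <- make_ontology(3, depth = 2, seed = 3)
  dat <- tiny_data(n_cells = 300, n_genes = 25, seed = 5, onto = onto)
  ctl <- train_config(steps = 40, batch_size = 4, lr = 1e-3, warmup = 10,
                      context_size = 8, val_every = 20, seed = 7)
  f1 <- screg(dat, classes = list(cell_type = onto),
              config = screg_config(d = 16, n_layers = 1), control = ctl)
  f2 <- screg(dat, classes = list(cell_type = onto),
              config = screg_config(d = 16, n_layers = 1), control = ctl)
  expect_equal(f1$history$total, f2$history$total)   # same seed, same path
  expect_identical(coef(f1), coef(f2))
  # 3-seed majority: a 200-step toy run ends below its first step
  wins <- vapply(1:3, function(s) {
    ctl_s <- train_config(steps = 200, batch_size = 4, lr = 1e-3,
                          warmup = 20, context_size = 8, val_every = 100,
                          seed = s)
    fs <- screg(dat, classes = list(cell_type = onto),
                config = screg_config(d = 16, n_layers = 1), control = ctl_s,
                seed = s)
    mean(tail(fs$history$total, 20)) < fs$history$total[1]
  }, TRUE)
  expect_gte(sum(wins), 2L)
})

test_that("2000-step training lowers held-out denoising likelihood vs untrained", {
  wins <- vapply(1:3, function(seed) {
    fit <- smoke_fit(seed)
    hold <- fit$val_cells[seq_len(min(60, length(fit$val_cells)))]
    untrained <- init_model(fit$model$config, fit$model$vocab,
                            classes = fit$model$classes, seed = seed)
    eval_nll <- function(model) {
      set.seed(41)
      ba <- screg:::make_batch(fit$data, hold, 16, r = 0.6, s = 0.55,
                               names(model$classes))
      screg:::loss_and_grads(model, ba$idx, ba$xs_noisy, ba$xs_true,
                             ba$t_true, ba$labels, train = FALSE,
                             want_grads = FALSE,
                             tasks = "denoising")$total
    }
    eval_nll(fit$model) < eval_nll(untrained)
  }, TRUE)
  expect_gte(sum(wins), 2L)
})

test_that("training reports divergence with the step number", {
  dat <- tiny_data(n_cells = 50, n_genes = 20, seed = 5)
  model <- tiny_model(dat, d = 16)
  model$params$dec.W2[] <- NaN           # force a non-finite decode
  expect_error(
    train_model(model, dat,
                train_config(steps = 5, batch_size = 4, context_size = 6,
                             warmup = 1, seed = 1)),
    "step 1")
})
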
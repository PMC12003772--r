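random_heads <- function(n_heads = 4, p = 8, seed = 1, genes = NULL) {
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(p))
  hs <- lapply(seq_len(n_heads), function(h) {
    M <- screg:::softmax_rows(matrix(rnorm(p * p), p, p))
    dimnames(M) <- list(genes, genes)
    M
  })
  names(hs) <- sprintf("L1H%d", seq_len(n_heads))
  structure(hs, class = "screg_heads")
}

test_that("meta-cell attention reduces to single-cell attention for |U| = 1", {
  set.seed(1)
  Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(12), 4, 3)
  rownames(Q) <- rownames(K) <- letters[1:4]
  A1 <- metacell_attention(Q, K)
  S <- Q %*% t(K) / sqrt(3)
  A_ref <- exp(S) / rowSums(exp(S))
  expect_equal(A1, A_ref, ignore_attr = TRUE)
  # constant queries/keys: every row uniform 1/n
  A_const <- metacell_attention(matrix(1, 4, 3), matrix(2, 4, 3))
  expect_equal(A_const, matrix(0.25, 4, 4), ignore_attr = TRUE)
  # 2-gene hand computation with two cells averaged first
  Q2 <- list(rbind(c(1, 0), c(0, 1)), rbind(c(3, 0), c(0, 1)))
  K2 <- list(rbind(c(1, 1), c(0, 1)), rbind(c(1, 1), c(2, 1)))
  Qb <- (Q2[[1]] + Q2[[2]]) / 2; Kb <- (K2[[1]] + K2[[2]]) / 2
  S2 <- Qb %*% t(Kb) / sqrt(2)
  expect_equal(metacell_attention(Q2, K2), exp(S2) / rowSums(exp(S2)),
               ignore_attr = TRUE)
  expect_error(metacell_attention(list(Q, Q), list(K, K[4:1, ])),
               "gene ordering")
})

test_that("meta-cell attention is permutation-equivariant in the gene order", {
  set.seed(2)
  Q <- matrix(rnorm(20), 5, 4); K <- matrix(rnorm(20), 5, 4)
  rownames(Q) <- rownames(K) <- paste0("g", 1:5)
  A <- metacell_attention(Q, K)
  perm <- c(3, 1, 5, 2, 4)
  Ap <- metacell_attention(Q[perm, ], K[perm, ])
  expect_equal(Ap, A[perm, perm])
})

test_that("mean_network averages heads and preserves row-stochasticity", {
  hs <- random_heads(4, p = 6)
  net <- mean_network(hs)
  expect_s3_class(net, "screg_network")
  expect_equal(net$scores, Reduce(`+`, hs) / 4, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(rowSums(net$scores), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical heads -> the head itself
  same <- structure(list(a = hs[[1]], b = hs[[1]]), class = "screg_heads")
  expect_equal(mean_network(same)$scores, hs[[1]])
  # NA-aware: absent pairs averaged over observed heads only
  h1 <- hs[[1]]; h1[1, 2] <- NA
  nav <- mean_network(structure(list(h1, hs[[2]]), class = "screg_heads"))
  expect_equal(nav$scores[1, 2], hs[[2]][1, 2])
})

test_that("head selection finds a planted informative head", {
  genes <- sprintf("g%02d", 1:30)
  set.seed(3)
  truth_edges <- data.frame(source = sample(genes, 40, replace = TRUE),
                            target = sample(genes, 40, replace = TRUE))
  truth_edges <- truth_edges[truth_edges$source != truth_edges$target, ]
  truth <- ground_truth(truth_edges, universe = genes)
  hs <- random_heads(4, p = 30, genes = genes, seed = 4)
  planted <- matrix(0.01, 30, 30, dimnames = list(genes, genes))
  planted[cbind(truth$edges$target, truth$edges$source)] <- 1
  planted <- planted / rowSums(planted)
  hs$planted <- planted
  sel <- select_heads(hs, truth, seed = 1)
  expect_true("planted" %in% sel$selected)
  expect_true(all(sel$coefficients >= 0))
  expect_s3_class(sel$network, "screg_network")
  # selected network lies in the convex hull of the heads
  lo <- pmin(hs[[1]], hs[[2]], hs[[3]], hs[[4]], hs$planted)
  hi <- pmax(hs[[1]], hs[[2]], hs[[3]], hs[[4]], hs$planted)
  expect_true(all(sel$network$scores >= lo - 1e-12 &
                    sel$network$scores <= hi + 1e-12))
  # a single available head is selected trivially
  one <- structure(list(planted = planted), class = "screg_heads")
  sel1 <- select_heads(one, truth, seed = 1)
  expect_equal(sel1$selected, "planted")
  expect_equal(sel1$network$scores, planted, ignore_attr = TRUE)
})

test_that("a selection transfers to head matrices from another cell set", {
  genes <- sprintf("g%02d", 1:20)
  truth <- ground_truth(data.frame(source = genes[1:5], target = genes[6:10]),
                        universe = genes)
  hs_a <- random_heads(3, p = 20, genes = genes, seed = 5)
  hs_b <- random_heads(3, p = 20, genes = genes, seed = 6)
  sel <- suppressWarnings(select_heads(hs_a, truth, seed = 2))
  reused <- mean_network(unclass(hs_b)[sel$selected])
  expect_s3_class(reused, "screg_network")
  expect_equal(dim(reused$scores), c(20L, 20L))
  expect_true(all(is.finite(reused$scores)))
})

test_that("select_heads rejects degenerate truths", {
  genes <- c("a", "b")
  hs <- random_heads(2, p = 2, genes = genes)
  # complete truth: no negative pair
  full <- ground_truth(data.frame(source = c("a", "b"), target = c("b", "a")),
                       universe = genes)
  expect_error(select_heads(hs, full, seed = 1), "no negative")
  empty <- ground_truth(data.frame(source = character(0),
                                   target = character(0)), universe = genes)
  expect_error(select_heads(hs, empty, seed = 1), "no positive")
})

test_that("genome-wide assembly matches per-block computation and the full pass", {
  fit <- toy_fit()
  cells <- subset_cells(fit$data, 1:10)
  # a single block covering all genes equals the direct meta-cell path
  p <- ncol(cells$counts)
  gw <- genome_wide_network(fit, cells, block_size = p, n_passes = 1, seed = 1)
  direct <- attention_heads(fit, cells)
  for (nm in names(direct))
    expect_equal(gw$heads[[nm]], direct[[nm]], tolerance = 1e-10)
  expect_equal(gw$network$scores, mean_network(direct)$scores,
               tolerance = 1e-10)
  # blockwise: reproduce the seeded blocks and average by co-occurrence
  gw2 <- genome_wide_network(fit, cells, block_size = 12, n_passes = 6,
                             seed = 9, max_absent_frac = 1)
  set.seed(9)
  pooled <- colSums(as.matrix(cells$counts))
  sums <- vector("list", 0); cooc <- matrix(0, p, p)
  for (k in 1:6) {
    block <- sample_context(pooled, 12)$idx
    hb <- attention_heads(fit, subset_counts <- {
      m <- as.matrix(cells$counts)[, block, drop = FALSE]; m })
    for (nm in names(hb)) {
      if (is.null(sums[[nm]])) sums[[nm]] <- matrix(0, p, p)
      sums[[nm]][block, block] <- sums[[nm]][block, block] + hb[[nm]]
    }
    cooc[block, block] <- cooc[block, block] + 1
  }
  want <- sums$L1H1 / cooc
  want[cooc == 0] <- NA
  expect_equal(unname(gw2$heads$L1H1), unname(want), tolerance = 1e-10)
  # co-occurrence counts symmetric per unordered pair
  expect_identical(gw2$cooccurrence, t(gw2$cooccurrence))
  expect_error(genome_wide_network(fit, cells, block_size = p + 1),
               "block_size")
})

test_that("orientation transposes scores involutively", {
  hs <- random_heads(1, p = 4)
  net <- mean_network(hs)
  t1 <- orient(net)
  expect_equal(t1$orientation, "transposed")
  expect_equal(t1$scores, t(net$scores))
  # edge score relocates from [target, source] to [source, target]
  expect_equal(t1$scores["g01", "g03"], net$scores["g03", "g01"])
  t2 <- orient(t1)
  expect_equal(t2$scores, net$scores)
  expect_equal(t2$orientation, "as-computed")
  sym <- net; sym$scores <- (net$scores + t(net$scores)) / 2
  expect_equal(orient(sym)$scores, sym$scores)
})

test_that("TF subsetting keeps regulator columns only", {
  net <- mean_network(random_heads(2, p = 3))
  all_tf <- subset_to_tf(net, net$gene_ids)
  expect_equal(all_tf$scores, net$scores, ignore_attr = TRUE)
  one <- subset_to_tf(net, "g02")
  expect_equal(dim(one$scores), c(3L, 1L))
  expect_equal(one$scores[, "g02"], net$scores[, "g02"])
  expect_error(subset_to_tf(net, "zzz"), "transcription factor")
})

test_that("network TSV round trip preserves scores and metadata", {
  net <- mean_network(random_heads(2, p = 5))
  net$scores[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$scores, net$scores[, colnames(back$scores)],
               tolerance = 1e-12)
  expect_equal(back$orientation, net$orientation)
})
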
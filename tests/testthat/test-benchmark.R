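score_net <- function(M, genes = sprintf("g%d", seq_len(nrow(M)))) {
  dimnames(M) <- list(genes, genes)
  screg:::new_network(M)
}

# exhaustive confusion-table oracle at the top-K cutoff (distinct scores)
oracle_epr <- function(M, edges, genes) {
  cand <- expand.grid(target = genes, source = genes,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$target != cand$source, ]
  cand$score <- M[cbind(cand$target, cand$source)]
  cand$lab <- paste(cand$source, cand$target) %in%
    paste(edges$source, edges$target)
  K <- sum(cand$lab)
  cand <- cand[order(-cand$score), ]
  TP <- sum(cand$lab[1:K]); FP <- K - TP
  FN <- sum(cand$lab[-(1:K)]); TN <- nrow(cand) - K - FN
  if (FP == 0 || FN == 0) Inf else (TP * TN) / (FP * FN)
}

oracle_auprc <- function(M, edges, genes) {
  cand <- expand.grid(target = genes, source = genes,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$target != cand$source, ]
  cand$score <- M[cbind(cand$target, cand$source)]
  cand$lab <- paste(cand$source, cand$target) %in%
    paste(edges$source, edges$target)
  cand <- cand[order(-cand$score), ]
  K <- sum(cand$lab); N <- nrow(cand)
  tp <- cumsum(cand$lab)
  rec <- c(0, tp / K); pr <- c(1, tp / seq_len(N))
  h <- pmax(pr - K / N, 0)
  sum(diff(rec) * (h[-1] + h[-length(h)]) / 2)
}

test_that("ground truths build, deduplicate and load from TSV", {
  tr <- ground_truth(data.frame(source = c("a", "a", "b"),
                                target = c("b", "b", "c")))
  expect_equal(nrow(tr$edges), 2L)
  expect_setequal(tr$universe, c("a", "b", "c"))
  expect_error(ground_truth(data.frame(source = "a", target = "z"),
                            universe = c("a", "b")), "outside")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "a\tb", "a\tb", "b\tc", "\tc"), path)
  expect_warning(tr2 <- load_truth_edgelist(path), "1 malformed")
  expect_equal(nrow(tr2$edges), 2L)
  writeLines("source\ttarget", path)
  expect_warning(load_truth_edgelist(path), "empty")
})

test_that("p-value matrices threshold into directed truths", {
  P <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_equal(nrow(truth_from_pvalues(P)$edges), 0L)      # all p = 1
  P["g1", "g2"] <- 0.01
  tr <- truth_from_pvalues(P)
  expect_equal(tr$edges, data.frame(source = "g1", target = "g2"),
               ignore_attr = TRUE)
  # cutoff 1 -> complete graph minus self-loops
  full <- truth_from_pvalues(P * 0 + 0.5, cutoff = 1)
  expect_equal(nrow(full$edges), 6L)
  expect_true(all(full$edges$source != full$edges$target))
  expect_error(truth_from_pvalues(P - 2), "\\[0, 1\\]")
})

test_that("EPR is infinite for perfect rankings and matches a hand example", {
  genes <- paste0("g", 1:4)
  edges <- data.frame(source = c("g1", "g2"), target = c("g2", "g3"))
  truth <- ground_truth(edges, universe = genes)
  M <- matrix(0.01, 4, 4, dimnames = list(genes, genes))
  M["g2", "g1"] <- 0.9; M["g3", "g2"] <- 0.8
  expect_equal(epr(score_net(M), truth), Inf)
  # top-2 containing exactly one true edge: (TP*TN)/(FP*FN) = (1*9)/(1*1)
  M2 <- matrix(0.01, 4, 4, dimnames = list(genes, genes))
  M2["g2", "g1"] <- 0.9           # true edge ranked 1st
  M2["g4", "g1"] <- 0.8           # false edge ranked 2nd
  M2["g3", "g2"] <- 0.5           # the other true edge below the cutoff
  set.seed(1)
  M2 <- M2 + matrix(runif(16, 0, 1e-4), 4, 4)   # break remaining ties
  expect_equal(epr(score_net(M2), truth), (1 * 9) / (1 * 1))
  # conventional precision@K / prevalence variant
  expect_equal(epr(score_net(M2), truth, mode = "precision_ratio"),
               (1 / 2) / (2 / 12))
})

test_that("epr and auprc match exhaustive enumeration on small universes", {
  for (seed in 1:6) {
    set.seed(seed)
    p <- sample(3:6, 1)
    genes <- paste0("g", seq_len(p))
    M <- matrix(runif(p * p), p, p, dimnames = list(genes, genes))
    pairs <- expand.grid(source = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    edges <- pairs[runif(nrow(pairs)) < 0.3, ]
    if (nrow(edges) == 0 || nrow(edges) == nrow(pairs)) next
    truth <- ground_truth(edges, universe = genes)
    expect_equal(epr(score_net(M), truth), oracle_epr(M, edges, genes))
    expect_equal(auprc(score_net(M), truth),
                 oracle_auprc(M, edges, genes), tolerance = 1e-12)
  }
})

test_that("both metrics are invariant to strictly monotone score transforms", {
  set.seed(2)
  genes <- paste0("g", 1:8)
  M <- matrix(runif(64), 8, 8, dimnames = list(genes, genes))
  edges <- data.frame(source = sample(genes, 10, TRUE),
                      target = sample(genes, 10, TRUE))
  edges <- unique(edges[edges$source != edges$target, ])
  truth <- ground_truth(edges, universe = genes)
  for (f in list(function(x) exp(3 * x), function(x) rank(x) / 100,
                 function(x) x^3)) {
    M2 <- matrix(f(as.numeric(M)), 8, 8, dimnames = dimnames(M))
    expect_equal(epr(score_net(M2), truth), epr(score_net(M), truth))
    expect_equal(auprc(score_net(M2), truth), auprc(score_net(M), truth),
                 tolerance = 1e-12)
  }
})

test_that("transposing the prediction swaps the roles of rows and columns", {
  set.seed(3)
  genes <- paste0("g", 1:6)
  M <- matrix(runif(36), 6, 6, dimnames = list(genes, genes))
  edges <- data.frame(source = c("g1", "g2", "g4"),
                      target = c("g3", "g5", "g6"))
  truth <- ground_truth(edges, universe = genes)
  flipped <- ground_truth(data.frame(source = edges$target,
                                     target = edges$source),
                          universe = genes)
  net <- score_net(M)
  expect_equal(epr(orient(net), truth), epr(net, flipped))
  expect_equal(auprc(orient(net), truth), auprc(net, flipped),
               tolerance = 1e-12)
})

test_that("auprc attains 1 - prevalence exactly for perfect rankings and 0 for inverted", {
  set.seed(4)
  genes <- paste0("g", 1:10)
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  edges <- pairs[sample(nrow(pairs), 12), ]
  truth <- ground_truth(edges, universe = genes)
  M <- matrix(0, 10, 10, dimnames = list(genes, genes))
  M[] <- runif(100, 0, 0.4)
  M[cbind(edges$target, edges$source)] <- runif(12, 0.6, 1)
  rho <- 12 / (100 - 10)
  expect_equal(auprc(score_net(M), truth), 1 - rho, tolerance = 1e-12)
  # anti-ranked scores: precision never beats prevalence -> 0
  expect_equal(auprc(score_net(1 - M), truth), 0, tolerance = 0.02)
  # the floor="none" variant is the plain trapezoidal AUPRC
  expect_equal(auprc(score_net(M), truth, floor = "none"), 1,
               tolerance = 1e-12)
  expect_lte(auprc(score_net(M), truth), 1 - rho + 1e-12)
})

test_that("the metric report bundles EPR, AUPRC and the problem size", {
  genes <- paste0("g", 1:5)
  set.seed(5)
  M <- matrix(runif(25), 5, 5, dimnames = list(genes, genes))
  truth <- ground_truth(data.frame(source = c("g1", "g2"),
                                   target = c("g2", "g4")), universe = genes)
  rep <- benchmark_network(score_net(M), truth)
  expect_equal(rep$n_positives, 2L)
  expect_equal(rep$universe_size, 5L)
  expect_equal(rep$prevalence, 2 / 20)
  expect_equal(rep$EPR, epr(score_net(M), truth))
})

test_that("prerank enrichment scores hubs and calibrates its null", {
  set.seed(6)
  genes <- paste0("g", 1:40)
  M <- matrix(runif(1600, 0, 0.1), 40, 40, dimnames = list(genes, genes))
  # top target-hubs: give g1..g5 heavy incoming rows
  M[1:5, ] <- M[1:5, ] + 1
  top <- prerank_enrichment(screg:::new_network(M),
                            list(top = genes[1:5], rand = genes[30:34]),
                            mode = "target_hub", n_perm = 200, seed = 1)
  expect_equal(top$p[1], 1 / 201, tolerance = 1e-12)
  expect_gt(top$es[1], 0.9)
  expect_gt(top$p[2], 0.05)
  expect_true(all(top$q >= top$p - 1e-12))
  # regulator-hub mode ranks by column sums
  Mc <- t(M)
  reg <- prerank_enrichment(screg:::new_network(Mc), list(top = genes[1:5]),
                            mode = "regulator_hub", n_perm = 200, seed = 1)
  expect_equal(reg$p[1], 1 / 201, tolerance = 1e-12)
  # empty intersection reported, not fatal
  none <- prerank_enrichment(screg:::new_network(M), list(x = c("zz1", "zz2")),
                             n_perm = 200, seed = 1)
  expect_true(is.na(none$es[1]))
  expect_equal(none$n_overlap[1], 0L)
})

test_that("eigenvector mode puts the hub of a star graph first", {
  genes <- c("hub", paste0("s", 1:6))
  M <- matrix(0, 7, 7, dimnames = list(genes, genes))
  M["hub", paste0("s", 1:6)] <- 1
  M[paste0("s", 1:6), "hub"] <- 1
  g <- igraph::graph_from_adjacency_matrix(M, mode = "directed",
                                           weighted = TRUE)
  cent <- igraph::eigen_centrality(g, directed = TRUE)$vector
  expect_equal(names(which.max(cent)), "hub")
  res <- prerank_enrichment(screg:::new_network(M), list(h = "hub"),
                            mode = "eigenvector", n_perm = 100, seed = 2)
  expect_gt(res$es[1], 0)
})

test_that("the permutation p-values are uniform under the null", {
  set.seed(7)
  genes <- paste0("g", 1:30)
  ps <- vapply(1:200, function(k) {
    M <- matrix(runif(900), 30, 30, dimnames = list(genes, genes))
    prerank_enrichment(screg:::new_network(M),
                       list(s = sample(genes, 8)),
                       mode = "target_hub", n_perm = 100,
                       seed = k)$p[1]
  }, 0)
  # the null p-values live on the k/(n_perm+1) grid; check the empirical CDF
  # at fixed quantiles within 3 binomial standard errors (+ grid slack)
  for (q in c(0.25, 0.5, 0.75)) {
    se <- sqrt(q * (1 - q) / length(ps))
    expect_lt(abs(mean(ps <= q) - q), 3 * se + 1 / 101)
  }
})

test_that("the running-sum statistic agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  s <- sort(rexp(50), decreasing = TRUE)
  names(s) <- paste0("g", 1:50)
  sel <- sort(sample(50, 10))
  mine <- screg:::es_stat(s, seq_along(s) %in% sel)
  ref <- fgsea::calcGseaStat(s, selectedStats = sel, gseaParam = 1)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("GMT gene-set files parse into named lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), path)
  gs <- read_gmt(path)
  expect_equal(gs, list(setA = c("g1", "g2", "g3"), setB = "g9"))
})
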
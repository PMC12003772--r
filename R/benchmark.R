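# Gene-network benchmarking: early precision ratio (diagnostic odds ratio at
# the top-K cutoff), prevalence-floored AUPRC, prerank hub enrichment, and
# ground-truth construction from edge lists / perturbation p-value matrices.

#' Construct a binary directed ground-truth network
#'
#' @param edges data.frame with columns `source`, `target` (duplicates
#'   dropped).
#' @param universe gene universe; default: union of edge endpoints.
#' @return object of class `screg_truth`.
#' @export
ground_truth <- function(edges, universe = NULL) {
  edges <- unique(data.frame(source = as.character(edges$source),
                             target = as.character(edges$target),
                             stringsAsFactors = FALSE))
  if (is.null(universe)) universe <- sort(unique(c(edges$source, edges$target)))
  out_of <- setdiff(c(edges$source, edges$target), universe)
  if (length(out_of))
    stop("edges outside the declared universe: ",
         paste(utils::head(out_of, 5L), collapse = ", "))
  structure(list(edges = edges, universe = universe), class = "screg_truth")
}

#' @export
print.screg_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d directed edges over %d genes\n",
              nrow(x$edges), length(x$universe)))
  invisible(x)
}

#' Load a ground-truth edge list from TSV
#'
#' Expects `source` and `target` columns (the first two columns are used if
#' unnamed). Malformed rows (missing endpoint) are counted and reported as a
#' warning. Filtering of small molecules / non-HGNC entries is the caller's
#' preprocessing.
#'
#' @param path TSV path.
#' @param universe optional gene universe.
#' @return `screg_truth`.
#' @export
load_truth_edgelist <- function(path, universe = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    names(df)[1:2] <- c("source", "target")
  bad <- is.na(df$source) | is.na(df$target) |
    df$source == "" | df$target == ""
  if (any(bad)) warning(sum(bad), " malformed rows dropped")
  df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0L) warning("empty ground-truth edge list")
  ground_truth(df, universe)
}

#' Ground truth from a perturbation p-value matrix
#'
#' Rows are knocked-out (source) genes, columns read-out (target) genes; an
#' edge source -> target exists iff `p[source, target] < cutoff`. Self-edges
#' are removed.
#'
#' @param pmatrix numeric matrix in \[0, 1\] with dimnames.
#' @param cutoff significance cutoff (default 0.05).
#' @return `screg_truth` with universe = union of row and column genes.
#' @export
truth_from_pvalues <- function(pmatrix, cutoff = 0.05) {
  if (any(pmatrix < 0 | pmatrix > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  hit <- which(pmatrix < cutoff, arr.ind = TRUE)
  edges <- data.frame(source = rownames(pmatrix)[hit[, 1L]],
                      target = colnames(pmatrix)[hit[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  ground_truth(edges, universe = sort(unique(c(rownames(pmatrix),
                                               colnames(pmatrix)))))
}

# Candidate ordered non-self pairs on the common universe, with prediction
# scores and truth labels. Score of edge (source -> target) is
# scores[target, source] in the "as-computed" orientation (rows = targets).
candidate_pairs <- function(pred, truth) {
  sc <- if (inherits(pred, "screg_network")) pred$scores else pred
  genes <- intersect(rownames(sc), truth$universe)
  genes <- intersect(genes, colnames(sc))
  if (length(genes) < 2L) stop("no common genes between prediction and truth")
  sc <- sc[genes, genes]
  tgt <- rep(seq_along(genes), times = length(genes))
  src <- rep(seq_along(genes), each = length(genes))
  keep <- tgt != src
  score <- as.numeric(sc)[keep]
  key <- paste(genes[src[keep]], genes[tgt[keep]])
  lab <- key %in% paste(truth$edges$source, truth$edges$target)
  ok <- !is.na(score)
  list(score = score[ok], label = lab[ok], n_genes = length(genes))
}

#' Early precision ratio
#'
#' The diagnostic odds ratio `(TP * TN) / (FP * FN)` at the score cutoff that
#' yields exactly `K` predicted positive pairs, `K` being the number of true
#' edges on the common gene universe. 1 is a random prediction; `Inf` (FP or
#' FN = 0) a perfect one; values below 1 mean the inverted predictor would do
#' better. Ties at the K-th score are broken by a seeded shuffle so exactly K
#' predictions are made.
#'
#' @param pred `screg_network` or score matrix (rows = targets, columns =
#'   regulators).
#' @param truth `screg_truth`.
#' @param seed tie-break seed.
#' @param mode `"odds_ratio"` (primary) or `"precision_ratio"`
#'   (precision@K / prevalence).
#' @return scalar (possibly `Inf`).
#' @export
epr <- function(pred, truth, seed = 1L, mode = c("odds_ratio",
                                                 "precision_ratio")) {
  mode <- match.arg(mode)
  cp <- candidate_pairs(pred, truth)
  K <- sum(cp$label)
  if (K < 1L) stop("empty truth on the common gene universe")
  N <- length(cp$score)
  set.seed(seed)
  ord <- order(cp$score, sample.int(N), decreasing = TRUE)
  predicted <- logical(N)
  predicted[ord[seq_len(K)]] <- TRUE
  TP <- sum(predicted & cp$label)
  FP <- sum(predicted & !cp$label)
  FN <- sum(!predicted & cp$label)
  TN <- N - TP - FP - FN
  if (mode == "precision_ratio") {
    prevalence <- K / N
    return((TP / K) / prevalence)
  }
  if (FP == 0L || FN == 0L) return(Inf)
  (TP * TN) / (FP * FN)
}

#' Prevalence-floored area under the precision-recall curve
#'
#' Precision-recall points are swept from 0 predicted positives to all
#' candidate pairs; the area is the composite-trapezoid integral over the
#' achieved recall values of `max(precision - prevalence, 0)` (the floor of
#' the area is the prevalence line, not precision = 0), with no extrapolation
#' beyond the last achieved recall. A perfect ranking scores `1 - prevalence`;
#' a ranking never beating prevalence scores 0.
#'
#' @inheritParams epr
#' @param floor `"prevalence"` (primary) or `"none"` (plain AUPRC; the random
#'   baseline `prevalence` is then reported separately by
#'   [benchmark_network()]).
#' @return scalar in \[0, 1\].
#' @export
auprc <- function(pred, truth, seed = 1L, floor = c("prevalence", "none")) {
  floor <- match.arg(floor)
  cp <- candidate_pairs(pred, truth)
  K <- sum(cp$label)
  if (K < 1L) stop("empty truth on the common gene universe")
  N <- length(cp$score)
  set.seed(seed)
  ord <- order(cp$score, sample.int(N), decreasing = TRUE)
  tp <- cumsum(cp$label[ord])
  recall <- c(0, tp / K)
  precision <- c(1, tp / seq_len(N))
  prevalence <- K / N
  h <- if (floor == "prevalence") pmax(precision - prevalence, 0) else
    precision
  sum(diff(recall) * (h[-1L] + h[-length(h)]) / 2)
}

#' Benchmark a predicted network against a ground truth
#'
#' @inheritParams epr
#' @return list of class `screg_metric_report`: `EPR`, `AUPRC`,
#'   `n_positives`, `universe_size`, `prevalence`, `orientation`.
#' @export
benchmark_network <- function(pred, truth, seed = 1L) {
  cp <- candidate_pairs(pred, truth)
  structure(list(EPR = epr(pred, truth, seed = seed),
                 AUPRC = auprc(pred, truth, seed = seed),
                 n_positives = sum(cp$label),
                 universe_size = cp$n_genes,
                 prevalence = mean(cp$label),
                 orientation = if (inherits(pred, "screg_network"))
                   pred$orientation else "as-computed"),
            class = "screg_metric_report")
}

#' @export
print.screg_metric_report <- function(x, ...) {
  cat(sprintf("EPR %.3g | AUPRC %.4f (prevalence %.4f) | K = %d over %d genes (%s)\n",
              x$EPR, x$AUPRC, x$prevalence, x$n_positives, x$universe_size,
              x$orientation))
  invisible(x)
}

# ---- prerank enrichment -------------------------------------------------

# weighted Kolmogorov-Smirnov running-sum enrichment score (weight exponent 1)
# s: scores sorted decreasing; inset: logical membership aligned with s.
es_stat <- function(s, inset) {
  N <- length(s)
  nh <- sum(inset)
  if (nh == 0L || nh == N) return(0)
  w <- abs(s) * inset
  tot <- sum(w)
  Ph <- if (tot > 0) cumsum(w) / tot else cumsum(inset) / nh
  Pm <- cumsum(!inset) / (N - nh)
  dev <- Ph - Pm
  unname(dev[which.max(abs(dev))])
}

#' Prerank gene-set enrichment on a network's hub ranking
#'
#' Genes are ranked by summing the network's edge scores row-wise (targets as
#' hubs), column-wise (regulators as hubs) or by eigenvector centrality of the
#' weighted graph; each gene set is scored with the weighted
#' Kolmogorov-Smirnov running-sum statistic (weight exponent 1) against a
#' gene-label permutation null. The background is all genes in the network.
#'
#' @param network `screg_network` (or score matrix).
#' @param gene_sets named list of character vectors.
#' @param mode ranking mode: `"target_hub"`, `"regulator_hub"` or
#'   `"eigenvector"`.
#' @param n_perm permutations for the null (>= 100).
#' @param seed integer seed.
#' @return data.frame of class `screg_enrichment`: one row per gene set with
#'   `es`, `p`, `q` (BH over the permutation p-values), `n_overlap`.
#' @export
prerank_enrichment <- function(network, gene_sets,
                               mode = c("target_hub", "regulator_hub",
                                        "eigenvector"),
                               n_perm = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  sc <- if (inherits(network, "screg_network")) network$scores else network
  sc0 <- ifelse(is.na(sc), 0, sc)
  stat <- switch(mode,
    target_hub = rowSums(sc0),
    regulator_hub = colSums(sc0),
    eigenvector = {
      g <- igraph::graph_from_adjacency_matrix(abs(sc0), mode = "directed",
                                               weighted = TRUE)
      igraph::eigen_centrality(g, directed = TRUE)$vector
    })
  names(stat) <- if (mode == "regulator_hub") colnames(sc) else rownames(sc)
  ord <- order(stat, decreasing = TRUE)
  s <- stat[ord]
  universe <- names(s)
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], universe)
    if (length(gs) == 0L)
      return(data.frame(gene_set = nm, es = NA_real_, p = NA_real_,
                        n_overlap = 0L))
    inset <- universe %in% gs
    es <- es_stat(s, inset)
    null <- vapply(seq_len(n_perm), function(k)
      es_stat(s, universe %in% sample(universe, length(gs))), 0)
    # two-sided on the magnitude: the running-sum statistic is sign-symmetric
    # under gene-label permutation, and this keeps the null p-values uniform
    p <- (1 + sum(abs(null) >= abs(es))) / (n_perm + 1)
    data.frame(gene_set = nm, es = es, p = p, n_overlap = length(gs))
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("screg_enrichment", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}
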
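# S3 methods for the fitted model object.

#' @export
print.screg <- function(x, ...) {
  cfg <- x$model$config
  cat("Single-cell transformer fit\n")
  cat(sprintf("  model: %d layers x %d heads, d = %d, %s loss\n",
              cfg$n_layers, cfg$n_heads, cfg$d, cfg$loss))
  cat(sprintf("  data: %d cells x %d genes\n", nrow(x$data$counts),
              ncol(x$data$counts)))
  n <- nrow(x$history)
  cat(sprintf("  training: %d steps, total loss %.4f -> %.4f%s\n", n,
              x$history$total[1L], x$history$total[n],
              if (!is.na(x$stopped_at))
                sprintf(" (early stop at %d)", x$stopped_at) else ""))
  invisible(x)
}

#' @export
summary.screg <- function(object, ...) {
  h <- object$history
  comp <- c("denoising", "classification", "contrastive", "bottleneck")
  comp <- comp[comp %in% names(h)]
  tail_n <- max(1L, nrow(h) - 49L)
  out <- list(fit = object,
              final = colMeans(h[tail_n:nrow(h), c("total", comp),
                                 drop = FALSE]),
              initial = unlist(h[1L, c("total", comp)]),
              validation = object$validation)
  class(out) <- "summary.screg"
  out
}

#' @export
print.summary.screg <- function(x, ...) {
  print(x$fit)
  cat("  loss components (first step -> mean of last 50 steps):\n")
  for (nm in names(x$final))
    cat(sprintf("    %-14s %8.4f -> %8.4f\n", nm, x$initial[[nm]],
                x$final[[nm]]))
  if (NROW(x$validation))
    cat(sprintf("  best validation loss: %.4f\n", min(x$validation$val_loss)))
  invisible(x)
}

#' @export
coef.screg <- function(object, ...) object$model$params

#' Plot training curves
#' @param x `screg` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.screg <- function(x, ...) {
  h <- x$history
  comp <- intersect(c("total", "denoising", "classification", "contrastive",
                      "bottleneck"), names(h))
  graphics::matplot(h$step, as.matrix(h[, comp]), type = "l", lty = 1,
                    xlab = "step", ylab = "loss", ...)
  if (NROW(x$validation))
    graphics::points(x$validation$step, x$validation$val_loss, pch = 16)
  graphics::legend("topright", legend = c(comp, "validation"),
                   col = c(seq_along(comp), 1), lty = c(rep(1, length(comp)),
                                                        NA),
                   pch = c(rep(NA, length(comp)), 16), bty = "n")
  invisible(x)
}

#' Predictions from a fitted model
#'
#' @param object `screg` fit.
#' @param newdata counts (`screg_counts` or matrix); default the training
#'   data's held-out validation cells.
#' @param type `"labels"` (per-class probabilities, see [predict_labels()]),
#'   `"denoise"` (expected counts at `target_depth`, see [denoise()]) or
#'   `"embedding"` (see [embed_cells()]).
#' @param ... passed to the task function (`target_depth`, `source`, `level`,
#'   ...).
#' @export
predict.screg <- function(object, newdata = NULL,
                          type = c("labels", "denoise", "embedding"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- subset_cells(object$data, object$val_cells)
  switch(type,
         labels = predict_labels(object, newdata, ...),
         denoise = denoise(object, newdata, ...),
         embedding = embed_cells(object, newdata, ...))
}

#' Simulate counts from the fitted observation model
#'
#' Draws counts from the per-cell decoded ZINB distribution (a parametric
#' posterior-predictive check of the expression decoder).
#'
#' @param object `screg` fit.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param newdata counts to condition on (default: validation cells).
#' @param ... unused.
#' @return list of `nsim` simulated count matrices.
#' @export
simulate.screg <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                           ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata))
    newdata <- subset_cells(object$data, object$val_cells)
  dn <- denoise(object, newdata)
  lapply(seq_len(nsim), function(k) {
    draw <- stats::rnbinom(length(dn$mu), size = as.numeric(dn$theta),
                           mu = as.numeric(dn$mu))
    draw[stats::runif(length(draw)) < as.numeric(dn$pi)] <- 0L
    matrix(draw, nrow(dn$mu), ncol(dn$mu), dimnames = dimnames(dn$mu))
  })
}
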